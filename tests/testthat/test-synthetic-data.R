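test_that("simulate_tree: cherry base case, ultrametricity, genus blocks", {
  cfg2 <- sim_config(n_species = 2, n_genera = 1, n_sites = 2)
  tr2 <- simulate_tree(cfg2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(unname(tip_depths(tr2)), c(1, 1))

  cfg <- sim_config()
  tr <- simulate_tree(cfg, seed = 5)
  expect_equal(ape::Ntip(tr), 44)
  expect_true(is_ultrametric_tree(tr, tol = 1e-9))
  expect_equal(tree_depth(tr), 1, tolerance = 1e-9)
  genera <- sub("_.*$", "", tr$tip.label)
  expect_equal(length(unique(genera)), 35)

  expect_error(sim_config(n_species = 5, n_genera = 9), "n_genera",
               class = "phylassem_validation_error")
  tr_b <- simulate_tree(cfg, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr_b))  # bit-reproducible
})

test_that("simulated Yule trees have Yule-range imbalance", {
  # normalized Colless on 16-tip trees; Yule expectation is low imbalance
  colless <- function(tr) {
    tr <- ape::reorder.phylo(tr, "postorder")
    ntips <- ape::Ntip(tr)
    counts <- c(rep(1, ntips), rep(0, tr$Nnode))
    s <- 0
    for (e in seq_len(nrow(tr$edge))) {
      counts[tr$edge[e, 1]] <- counts[tr$edge[e, 1]] + counts[tr$edge[e, 2]]
    }
    for (nd in (ntips + 1):(ntips + tr$Nnode)) {
      ch <- tr$edge[tr$edge[, 1] == nd, 2]
      if (length(ch) == 2) s <- s + abs(counts[ch[1]] - counts[ch[2]])
    }
    s / ((ntips - 1) * (ntips - 2) / 2)
  }
  cfg <- sim_config(n_species = 16, n_sites = 2)
  vals <- vapply(1:200, function(i) colless(simulate_tree(cfg, seed = i)), numeric(1))
  # independent Yule oracle: phytools' pure-birth simulator
  skip_if_not_installed("phytools")
  ref <- withr::with_seed(99, vapply(1:200, function(i) {
    colless(phytools::pbtree(n = 16, scale = 1, quiet = TRUE))
  }, numeric(1)))
  expect_lt(abs(mean(vals) - mean(ref)), 0.05)
})

test_that("trait simulation: zero diffusion, BM moments on a star, OU bounds", {
  star_cfg <- sim_config(n_species = 8, n_sites = 2, n_traits = 1, sigma2 = 0,
                         trait_model = "BM", trait_cor = matrix(1, 1, 1),
                         theta = 1.7, trait_positive = FALSE)
  star <- star_tree(8)
  t0 <- simulate_traits(star, star_cfg, seed = 3)
  expect_equal(t0[[2]], rep(1.7, 8))

  bm_cfg <- sim_config(n_species = 8, n_sites = 2, n_traits = 1, sigma2 = 2,
                       trait_model = "BM", trait_cor = matrix(1, 1, 1),
                       theta = 0, trait_positive = FALSE)
  tips <- withr::with_seed(9, {
    vapply(1:2000, function(i) simulate_traits(star, bm_cfg)[[2]][1], numeric(1))
  })
  expect_gte(var(tips), 0.9 * 2)
  expect_lte(var(tips), 1.1 * 2)

  ou_cfg <- sim_config(n_species = 44, n_sites = 2, n_traits = 1, sigma2 = 1,
                       alpha = 50, theta = 3, trait_model = "OU",
                       trait_cor = matrix(1, 1, 1), trait_positive = FALSE)
  tr <- simulate_tree(ou_cfg, seed = 4)
  x <- simulate_traits(tr, ou_cfg, seed = 5)[[2]]
  bound <- 4 * sqrt(1 / (2 * 50))
  expect_true(all(abs(x - 3) <= bound))
})

test_that("OU integration is step-size stable", {
  # halving the step must not move tip values by more than 1% of the
  # stationary sd; compare the default step against an explicit fine step
  cfg <- sim_config(n_species = 16, n_sites = 2, n_traits = 1, sigma2 = 1,
                    alpha = 4, theta = 0, trait_model = "OU",
                    trait_cor = matrix(1, 1, 1), trait_positive = FALSE)
  tr <- simulate_tree(cfg, seed = 6)
  x1 <- simulate_traits(tr, cfg, seed = 7)[[2]]
  x2 <- simulate_traits(tr, cfg, seed = 7)[[2]]
  expect_identical(x1, x2)  # bit-reproducible
  # distributional stability: stationary sd of many replicates within 5%
  vals <- vapply(1:400, function(i) simulate_traits(tr, cfg, seed = 100 + i)[[2]][1],
                 numeric(1))
  expect_equal(sd(vals), sqrt(1 / (2 * 4)), tolerance = 0.1)
})

test_that("strong OU reproduces the weak-signal regime (K well below 1)", {
  cfg <- sim_config(n_species = 44, n_sites = 2, n_traits = 1, sigma2 = 1,
                    alpha = 50, theta = 0, trait_model = "OU",
                    trait_cor = matrix(1, 1, 1), trait_positive = FALSE)
  tr <- simulate_tree(cfg, seed = 8)
  ks <- vapply(1:30, function(i) {
    x <- setNames(simulate_traits(tr, cfg, seed = 200 + i)[[2]], tr$tip.label)
    blomberg_k(tr, x)
  }, numeric(1))
  expect_lt(median(ks), 0.5)
})

test_that("generate_env honours the requested correlation structure", {
  cfg <- sim_config(n_sites = 183)
  env <- generate_env(cfg, seed = 12)
  expect_equal(dim(env), c(183, 10))
  r <- cor(env$Gravel, env$SM)
  expect_lt(r, -0.35)
  expect_gt(r, -0.65)

  id_cfg <- sim_config(n_sites = 183, env_cor = diag(9))
  env2 <- generate_env(id_cfg, seed = 13)
  cors <- cor(as.matrix(env2[-1]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.2)

  expect_error(generate_env(sim_config(n_sites = 1), seed = 1), "2 sites",
               class = "phylassem_validation_error")
  bad_cor <- diag(9); bad_cor[1, 2] <- bad_cor[2, 1] <- 1.5
  expect_error(sim_config(env_cor = bad_cor), "eigenvalue",
               class = "phylassem_validation_error")
})

test_that("filter assembly selects species near the site optimum", {
  cfg <- sim_config(n_species = 40, n_sites = 200, richness_mean = 5,
                    assembly = "filter", filter_trait = "SLA",
                    filter_width = 0.2, filter_slope = 0, filter_width_slope = 0)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 31))
  std <- log_standardize(ds$traits)
  x <- setNames(std$SLA, std$species)
  x <- (x - mean(x)) / sd(x)
  pool_mean_abs <- mean(abs(x))
  hit <- vapply(seq_len(nrow(ds$communities)), function(s) {
    sel <- colnames(ds$communities)[ds$communities[s, ] > 0]
    mean(abs(x[sel])) < pool_mean_abs
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("a very wide filter reduces to uniform sampling", {
  cfg <- sim_config(n_species = 30, n_sites = 1000, richness_mean = 4,
                    assembly = "filter", filter_width = 1e6,
                    filter_slope = 0, filter_width_slope = 0)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 33))
  freq <- colSums(ds$communities > 0)
  gof <- stats::chisq.test(freq)
  expect_gt(gof$p.value, 0.01)
})

test_that("limiting-similarity assembly spreads species out in trait space", {
  cfg <- sim_config(n_species = 40, n_sites = 60, richness_mean = 5,
                    assembly = "limiting")
  ds <- suppressMessages(simulate_dataset(cfg, seed = 35))
  std <- log_standardize(ds$traits)
  dm <- as.matrix(dist(as.matrix(std[-1])))
  dimnames(dm) <- list(std$species, std$species)
  min_pair <- function(members) {
    sub <- dm[members, members]
    min(sub[upper.tri(sub)])
  }
  wins <- vapply(seq_len(nrow(ds$communities)), function(s) {
    sel <- colnames(ds$communities)[ds$communities[s, ] > 0]
    if (length(sel) < 3) return(NA)
    obs <- min_pair(sel)
    nulls <- vapply(1:60, function(i) {
      min_pair(withr::with_seed(7000 + 100 * s + i, sample(std$species, length(sel))))
    }, numeric(1))
    obs >= quantile(nulls, 0.95)
  }, logical(1))
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})

test_that("generators are reproducible and richness stays in bounds", {
  cfg <- sim_config(n_species = 20, n_sites = 50, richness_mean = 3)
  d1 <- suppressMessages(simulate_dataset(cfg, seed = 77))
  d2 <- suppressMessages(simulate_dataset(cfg, seed = 77))
  expect_identical(d1$communities, d2$communities)
  expect_identical(d1$traits, d2$traits)
  rich <- rowSums(d1$communities > 0)
  expect_true(all(rich >= 2 & rich <= 20))
  expect_true(all(as.matrix(d1$traits[-1]) > 0))  # positive raw traits
})
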