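test_that("mpd matches hand values and brute-force enumeration", {
  d <- worked_pool()
  expect_equal(mpd(d, c("A", "B")), 2)
  tri <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tri["A", "B"] <- tri["B", "A"] <- 1
  tri["A", "C"] <- tri["C", "A"] <- 2
  tri["B", "C"] <- tri["C", "B"] <- 3
  expect_equal(mpd(tri, c("A", "B", "C")), 2)
  expect_true(is.na(mpd(d, "A")))

  for (case in 1:100) {
    n <- withr::with_seed(case, sample(4:12, 1))
    m <- withr::with_seed(case + 1, matrix(runif(n * n), n, n))
    m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
    k <- withr::with_seed(case + 2, sample(2:n, 1))
    mem <- withr::with_seed(case + 3, sample(rownames(m), k))
    acc <- 0; cnt <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      acc <- acc + m[mem[i], mem[j]]; cnt <- cnt + 1
    }
    expect_equal(mpd(m, mem), acc / cnt, tolerance = 1e-12)
  }
})

test_that("the 3-species worked case is exact under the enumerated null", {
  res <- suppressMessages(
    ses_mpd(worked_pool(), one_site(c("A", "B"), c("A", "B", "C")), exhaustive = TRUE))
  expect_equal(res$mpd_obs, 2)
  expect_equal(res$null_mean, 4)
  expect_equal(res$null_sd, 2)
  expect_equal(res$ses, -1)
  expect_false(res$degenerate)
})

test_that("ses formula, degenerate flags, and sample-sd convention hold", {
  cfg <- sim_config(n_species = 12, n_sites = 15, richness_mean = 4)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 3))
  d <- cophenetic_distances(ds$tree)
  res <- suppressMessages(ses_mpd(d, ds$communities, n_permutations = 99, seed = 5))
  ok <- !res$degenerate
  expect_true(any(ok))
  expect_lt(max(abs(res$ses[ok] - (res$mpd_obs[ok] - res$null_mean[ok]) / res$null_sd[ok])),
            1e-12)

  # a site containing the entire pool has a spread-free null
  full <- matrix(1, 1, 12, dimnames = list("all", colnames(ds$communities)))
  res_full <- ses_mpd(d, full, n_permutations = 99, seed = 5)
  expect_true(res_full$degenerate)
  expect_true(is.na(res_full$ses))

  # richness < 2 is degenerate, not an error
  lone <- one_site("A", c("A", "B", "C"))
  res_lone <- suppressMessages(ses_mpd(worked_pool(), lone, n_permutations = 99, seed = 1))
  expect_true(res_lone$degenerate)
})

test_that("ses_mpd is deterministic given a seed and presence-based", {
  cfg <- sim_config(n_species = 15, n_sites = 20, richness_mean = 4)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 8))
  d <- cophenetic_distances(ds$tree)
  r1 <- suppressMessages(ses_mpd(d, ds$communities, n_permutations = 99, seed = 21))
  r2 <- suppressMessages(ses_mpd(d, ds$communities, n_permutations = 99, seed = 21))
  expect_identical(r1, r2)
  r3 <- suppressMessages(ses_mpd(d, ds$communities * 2, n_permutations = 99, seed = 21))
  expect_identical(r1$ses, r3$ses)
})

test_that("SES is invariant to affine transforms of the distances", {
  cfg <- sim_config(n_species = 15, n_sites = 20, richness_mean = 4)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 13))
  d <- cophenetic_distances(ds$tree)
  r0 <- suppressMessages(ses_mpd(d, ds$communities, n_permutations = 99, seed = 33))
  for (case in 1:3) {
    a <- c(2.5, 0.3, 7)[case]; cc <- c(0, 1.2, 4)[case]
    d2 <- a * d + cc
    diag(d2) <- 0
    r2 <- suppressMessages(ses_mpd(d2, ds$communities, n_permutations = 99, seed = 33))
    ok <- !r0$degenerate
    expect_lt(max(abs(r2$ses[ok] - r0$ses[ok])), 1e-9)
  }
})

test_that("departure test: symmetry gives p = 1, extreme shift is convergent", {
  sym <- tibble::tibble(metric = "m", ses = c(-2, -1, 1, 2, -0.5, 0.5),
                        degenerate = FALSE)
  res <- departure_test(sym)
  expect_equal(res$p_value, 1)
  expect_identical(res$direction, "none")

  shifted <- tibble::tibble(metric = "m", ses = rep(-1.5, 100), degenerate = FALSE)
  res2 <- departure_test(shifted)
  expect_lt(res2$p_value, 0.001)
  expect_identical(res2$direction, "convergent")
  expect_identical(res2$method, "normal-approximation")
})

test_that("departure test detects a moderate negative shift with power", {
  x <- withr::with_seed(17, rnorm(200, mean = -0.3, sd = 1))
  res <- departure_test(tibble::tibble(metric = "m", ses = x, degenerate = FALSE))
  expect_lt(res$p_value, 0.05)
  expect_identical(res$direction, "convergent")
  rej <- vapply(1:100, function(i) {
    xi <- withr::with_seed(1000 + i, rnorm(200, -0.3, 1))
    departure_test(tibble::tibble(metric = "m", ses = xi, degenerate = FALSE))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.85)
})

test_that("degenerate sites are excluded from the departure test, not imputed", {
  df <- tibble::tibble(metric = "m",
                       ses = c(rnorm(20, -1), rep(NA_real_, 5)),
                       degenerate = c(rep(FALSE, 20), rep(TRUE, 5)))
  res <- suppressMessages(departure_test(df))
  expect_equal(res$n_sites, 20)
  expect_equal(res$n_degenerate, 5)
})

test_that("assembly_structure runs per-trait, combined and phylogenetic metrics", {
  cfg <- sim_config(n_species = 15, n_sites = 12, richness_mean = 4, n_traits = 3)
  ds <- suppressMessages(simulate_dataset(cfg, seed = 19))
  res <- suppressMessages(assembly_structure(ds$tree, ds$traits, ds$communities,
                                             n_permutations = 99, seed = 7))
  expect_setequal(unique(res$metric), c("SLA", "LA", "LNC", "ALL", "PHYLO"))
  expect_equal(nrow(res), 5 * 12)
  res2 <- suppressMessages(assembly_structure(ds$tree, ds$traits, ds$communities,
                                              n_permutations = 99, seed = 7))
  expect_identical(res$ses, res2$ses)
})
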