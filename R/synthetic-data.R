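#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' an arid-steppe community survey at the scale the analysis modules expect:
#' a pool of 44 species in 35 genera on an ultrametric unit-depth tree, 183
#' low-richness communities, eight leaf/root traits evolved under an
#' Ornstein-Uhlenbeck process strong enough to leave only weak phylogenetic
#' signal (K well below 1), and nine environmental variables whose gravel
#' coverage and soil moisture are negatively correlated.
#'
#' @param n_species Pool size (default 44).
#' @param n_genera Number of genera, assigned to contiguous clade blocks
#'   (default keeps the 35-genera / 44-species ratio: 35 at the default pool
#'   size).
#' @param n_sites Number of communities (default 183).
#' @param richness_mean Poisson mean of site richness, truncated to
#'   `[2, n_species]` (default 5).
#' @param trait_model `"OU"` (default) or `"BM"`.
#' @param n_traits Number of traits (default 8; the first eight get the
#'   conventional names SLA, LA, LNC, LPC, SRL, RL, RNC, RPC).
#' @param sigma2 Diffusion variance per unit branch length (default 1).
#' @param alpha OU pull strength toward the optimum (default 10; ignored for
#'   BM).
#' @param theta OU optimum / BM root value per trait, on the log scale.
#'   Default: log of typical magnitudes for the eight named traits, 0 beyond.
#' @param trait_cor Trait correlation matrix for the diffusion innovations.
#'   Default: leaf-trait and root-trait blocks with r = 0.6 within and 0.3
#'   between blocks, emulating the redundancy among leaf-economics and
#'   root-economics traits that motivates the PCA step.
#' @param trait_positive If `TRUE` (default) trait values are exponentiated
#'   so the emitted table holds positive raw traits ready for
#'   [log_standardize()]; `FALSE` emits the latent (log-scale) values.
#' @param assembly `"random"`, `"filter"` or `"limiting"`.
#' @param filter_trait Filtered dimension for `"filter"` assembly: `"PC1"`
#'   (default) or a trait name (used on the log-standardized scale).
#' @param filter_env Environmental variable the filter optimum tracks
#'   (default `"SM"`).
#' @param filter_width Baseline Gaussian filter width, in pool-SD units
#'   (default 0.5).
#' @param filter_intercept,filter_slope Site optimum =
#'   `filter_intercept + filter_slope * z(env)`, in pool-SD units (defaults
#'   0 and 0.5: the favoured trait value tracks the environment).
#' @param filter_width_slope Stress-gradient coefficient: the site filter
#'   width is `filter_width * exp(filter_width_slope * z(env))` (default
#'   0.75), so with `filter_env = "SM"` drier sites filter more tightly —
#'   abiotic filtering relaxes as water limitation eases — giving the
#'   SES-environment relationship a defined (positive) sign.
#' @param env_vars Names of the environmental variables.
#' @param env_mean,env_sd Per-variable means and SDs for the affine mapping
#'   onto plausible field ranges.
#' @param env_cor Correlation matrix for the environmental variables; the
#'   default is the identity except corr(Gravel, SM) = −0.5.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 44, n_genera = NULL, n_sites = 183,
                       richness_mean = 5,
                       trait_model = c("OU", "BM"), n_traits = 8,
                       sigma2 = 1, alpha = 10, theta = NULL,
                       trait_cor = NULL, trait_positive = TRUE,
                       assembly = c("random", "filter", "limiting"),
                       filter_trait = "PC1", filter_env = "SM",
                       filter_width = 0.5, filter_intercept = 0,
                       filter_slope = 0.5, filter_width_slope = 0.75,
                       env_vars = c("Gravel", "TSN", "TOC", "SM", "pH",
                                    "MAP", "PS", "MAT", "TS"),
                       env_mean = NULL, env_sd = NULL, env_cor = NULL,
                       abundance_meanlog = 1, abundance_sdlog = 1) {
  trait_model <- match.arg(trait_model)
  assembly <- match.arg(assembly)
  assert_number(n_species, "n_species", min = 2)
  # default genus count keeps the 35-genera-per-44-species ratio of the
  # emulated survey at any pool size
  if (is.null(n_genera)) n_genera <- max(1, round(n_species * 35 / 44))
  assert_number(n_genera, "n_genera", min = 1)
  assert_number(n_sites, "n_sites", min = 1)
  assert_number(richness_mean, "richness_mean", min = 2)
  assert_number(sigma2, "sigma2", min = 0)
  assert_number(filter_width, "filter_width", min = 1e-12)
  if (alpha < 0) stop_validation("`alpha` must be nonnegative")
  if (n_genera > n_species) stop_validation("n_genera cannot exceed n_species")

  trait_names <- default_trait_names(n_traits)
  if (is.null(theta)) {
    canon <- log(c(SLA = 60, LA = 4, LNC = 20, LPC = 1.5,
                   SRL = 30, RL = 15, RNC = 10, RPC = 1))
    theta <- setNames(rep(0, n_traits), trait_names)
    shared <- intersect(trait_names, names(canon))
    theta[shared] <- canon[shared]
  }
  if (is.null(trait_cor)) trait_cor <- default_trait_cor(trait_names)
  if (is.null(env_mean)) {
    env_mean <- c(Gravel = 60, TSN = 0.3, TOC = 2, SM = 4, pH = 8.5,
                  MAP = 80, PS = 60, MAT = 5, TS = 900)[env_vars]
    env_mean[is.na(env_mean)] <- 0
  }
  if (is.null(env_sd)) {
    env_sd <- c(Gravel = 15, TSN = 0.1, TOC = 0.8, SM = 1.5, pH = 0.4,
                MAP = 30, PS = 15, MAT = 2, TS = 100)[env_vars]
    env_sd[is.na(env_sd)] <- 1
  }
  if (is.null(env_cor)) {
    env_cor <- diag(length(env_vars))
    dimnames(env_cor) <- list(env_vars, env_vars)
    if (all(c("Gravel", "SM") %in% env_vars)) {
      env_cor["Gravel", "SM"] <- env_cor["SM", "Gravel"] <- -0.5
    }
  }
  check_correlation_matrix(trait_cor, "trait_cor")
  check_correlation_matrix(env_cor, "env_cor")
  structure(
    list(n_species = as.integer(n_species), n_genera = as.integer(n_genera),
         n_sites = as.integer(n_sites), richness_mean = richness_mean,
         trait_model = trait_model, n_traits = as.integer(n_traits),
         trait_names = trait_names, sigma2 = sigma2, alpha = alpha,
         theta = theta, trait_cor = trait_cor, trait_positive = trait_positive,
         assembly = assembly, filter_trait = filter_trait,
         filter_env = filter_env, filter_width = filter_width,
         filter_intercept = filter_intercept, filter_slope = filter_slope,
         filter_width_slope = filter_width_slope,
         env_vars = env_vars, env_mean = env_mean, env_sd = env_sd,
         env_cor = env_cor, abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog),
    class = "sim_config")
}

default_trait_names <- function(n_traits) {
  canonical <- c("SLA", "LA", "LNC", "LPC", "SRL", "RL", "RNC", "RPC")
  if (n_traits <= length(canonical)) canonical[seq_len(n_traits)]
  else c(canonical, paste0("trait", seq_len(n_traits - length(canonical))))
}

default_trait_cor <- function(trait_names) {
  p <- length(trait_names)
  leaf <- c("SLA", "LA", "LNC", "LPC")
  blk <- ifelse(trait_names %in% leaf, 1L, 2L)
  m <- matrix(0.3, p, p, dimnames = list(trait_names, trait_names))
  m[outer(blk, blk, "==")] <- 0.6
  diag(m) <- 1
  m
}

check_correlation_matrix <- function(m, name) {
  if (!isSymmetric(unname(m))) stop_validation(sprintf("`%s` must be symmetric", name))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_validation(sprintf("`%s` is not positive semidefinite (smallest eigenvalue %.3g)",
                            name, min(ev)))
  }
  invisible(m)
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Grows a Yule (pure-birth) tree to `n_species` tips, rescales it to unit
#' depth, and assigns tips to `n_genera` genera by contiguous blocks in the
#' ladderized tip order, so genera are compact clades suitable for grafting
#' tests. Tip labels have the form `genNN_spMM`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` object.
#' @export
simulate_tree <- function(config = sim_config(), seed = NULL) {
  n <- config$n_species
  tree <- with_seed_(seed, ape::rphylo(n, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length / tree_depth_raw(tree)
  tree <- ape::ladderize(tree)
  # contiguous blocks in plotted tip order -> compact (clade-ish) genera
  ord <- tip_plot_order(tree)
  sizes <- block_sizes(n, config$n_genera)
  genus_id <- rep(seq_along(sizes), sizes)
  labs <- character(n)
  counter <- 0L
  for (i in seq_len(n)) {
    counter <- counter + 1L
    labs[ord[i]] <- sprintf("gen%02d_sp%02d", genus_id[i], counter)
  }
  tree$tip.label <- labs
  validate_phylogeny(tree)
  tree
}

tree_depth_raw <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

# tip indices in the order they appear along the ladderized plot
tip_plot_order <- function(tree) {
  e <- tree$edge
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  walk <- function(node) {
    if (node <= ntip) {
      out[[length(out) + 1L]] <<- node
      return(invisible())
    }
    for (child in e[e[, 1L] == node, 2L]) walk(child)
  }
  walk(ntip + 1L)
  unlist(out)
}

block_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

#' Simulate trait evolution along a phylogeny
#'
#' Brownian motion draws tip values from a multivariate normal with
#' covariance `sigma2 * V` (V from [phylo_vcv()]); the Ornstein-Uhlenbeck
#' mode integrates \eqn{dx = \alpha(\theta - x)\,dt + \sigma\,dW} along each
#' branch by Euler-Maruyama with step
#' `min(0.01 * depth, 0.05 / alpha)` (the second term keeps the discretized
#' stationary variance within a few percent of \eqn{\sigma^2/(2\alpha)} for
#' stiff pulls). Traits share a correlation structure through their
#' innovations (`config$trait_cor`). The root starts at `theta`.
#'
#' With `config$trait_positive` the latent values are exponentiated, giving
#' strictly positive, log-normal-like raw traits.
#'
#' @param tree A rooted `phylo` object.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Trait table: tibble with `species` and one column per trait.
#' @export
simulate_traits <- function(tree, config = sim_config(), seed = NULL) {
  validate_phylogeny(tree)
  p <- config$n_traits
  theta <- rep_len(config$theta, p)
  lat <- with_seed_(seed, {
    if (config$trait_model == "BM") {
      simulate_bm(tree, config$sigma2, theta, config$trait_cor)
    } else {
      simulate_ou(tree, config$sigma2, config$alpha, theta, config$trait_cor)
    }
  })
  colnames(lat) <- config$trait_names
  vals <- if (config$trait_positive) exp(lat) else lat
  bind_cols(tibble(species = tree$tip.label), as_tibble(as.data.frame(vals)))
}

# matrix-normal BM: tips ~ MVN(theta, sigma2 * V) per trait, innovations
# correlated across traits
simulate_bm <- function(tree, sigma2, theta, trait_cor) {
  n <- ape::Ntip(tree)
  p <- length(theta)
  if (sigma2 == 0) return(matrix(theta, n, p, byrow = TRUE))
  v <- phylo_vcv(tree)
  lv <- t(chol(v + diag(1e-12, n)))
  lc <- t(chol(trait_cor + diag(1e-12, p)))
  z <- matrix(rnorm(n * p), n, p)
  sweep(sqrt(sigma2) * (lv %*% z %*% t(lc)), 2L, theta, "+")
}

simulate_ou <- function(tree, sigma2, alpha, theta, trait_cor) {
  n <- ape::Ntip(tree)
  p <- length(theta)
  depth <- tree_depth_raw(tree)
  dt_max <- if (alpha > 0) min(0.01 * depth, 0.05 / alpha) else 0.01 * depth
  lc <- t(chol(trait_cor + diag(1e-12, p)))
  e <- tree$edge
  root <- n + 1L
  state <- matrix(NA_real_, n + tree$Nnode, p)
  state[root, ] <- theta
  # preorder: ape's edge matrix from rphylo/ladderize is not guaranteed
  # preordered, so order edges by parent depth
  parent_depth <- ape::node.depth.edgelength(tree)
  edge_order <- order(parent_depth[e[, 1L]])
  for (row in edge_order) {
    from <- e[row, 1L]; to <- e[row, 2L]
    len <- tree$edge.length[row]
    x <- state[from, ]
    if (len > 0) {
      nstep <- max(1L, ceiling(len / dt_max))
      dt <- len / nstep
      sd_step <- sqrt(sigma2 * dt)
      for (s in seq_len(nstep)) {
        eps <- sd_step * drop(lc %*% rnorm(p))
        x <- x + alpha * (theta - x) * dt + eps
      }
    }
    state[to, ] <- x
  }
  state[seq_len(n), , drop = FALSE]
}

#' Generate correlated environmental gradients
#'
#' Site values are multivariate normal with the configured correlation
#' matrix, then affinely mapped to plausible field ranges via `env_mean` and
#' `env_sd`. With the default configuration gravel coverage and soil
#' moisture are negatively correlated (r = −0.5), the signature of
#' gravel-mediated water availability.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble: `site` plus one column per environmental variable.
#' @export
generate_env <- function(config = sim_config(), seed = NULL) {
  if (config$n_sites < 2) {
    stop_validation("generate_env needs at least 2 sites (correlations undefined for n = 1)")
  }
  check_correlation_matrix(config$env_cor, "env_cor")
  k <- length(config$env_vars)
  z <- with_seed_(seed, MASS::mvrnorm(config$n_sites, mu = rep(0, k),
                                      Sigma = config$env_cor))
  vals <- sweep(sweep(z, 2L, config$env_sd, "*"), 2L, config$env_mean, "+")
  colnames(vals) <- config$env_vars
  bind_cols(tibble(site = sprintf("site%03d", seq_len(config$n_sites))),
            as_tibble(as.data.frame(vals)))
}

#' Assemble communities from a species pool
#'
#' Draws each site's richness from a Poisson distribution (mean
#' `richness_mean`) truncated to `[2, pool size]`, then selects species by
#' the configured assembly process:
#'
#' * `random` — uniform sampling without replacement (the neutral
#'   benchmark);
#' * `filter` — abiotic filtering: sampling weights
#'   \eqn{\exp(-(x_s - opt)^2 / (2 w^2))} on the filtered trait dimension,
#'   with the site optimum a linear function of an environmental variable
#'   and the width following a stress gradient on the same variable
#'   (narrower — stronger filtering — at the harsh end);
#' * `limiting` — limiting similarity: greedy selection maximizing the
#'   minimum pairwise distance in the standardized trait space, seeded by a
#'   random first species.
#'
#' Abundances for selected species are drawn log-normal.
#'
#' @param traits Raw trait table from [simulate_traits()].
#' @param env Environment table from [generate_env()] (needed for `filter`
#'   assembly).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Site-by-species abundance matrix (sites in `env` order).
#' @export
simulate_communities <- function(traits, env = NULL, config = sim_config(), seed = NULL) {
  traits <- check_trait_table(traits)
  pool <- traits$species
  npool <- length(pool)
  n_sites <- config$n_sites
  if (config$assembly == "filter" && !config$filter_env %in% names(env)) {
    stop_validation(sprintf("filter_env '%s' not in environment table", config$filter_env))
  }
  std <- if (is.null(attr(traits, "transform_state"))) log_standardize(traits) else traits
  xmat <- as.matrix(std[setdiff(names(std), "species")])
  filter_x <- NULL
  if (config$assembly == "filter") {
    raw_fx <- if (identical(config$filter_trait, "PC1")) {
      pca_ordination(std)$scores$PC1
    } else {
      if (!config$filter_trait %in% colnames(xmat)) {
        stop_validation(sprintf("filter_trait '%s' not in trait table", config$filter_trait))
      }
      xmat[, config$filter_trait]
    }
    filter_x <- (raw_fx - mean(raw_fx)) / sd(raw_fx)  # pool-SD units
  }
  opt <- NULL
  width <- NULL
  if (config$assembly == "filter") {
    ev <- env[[config$filter_env]]
    z <- (ev - mean(ev)) / sd(ev)
    opt <- config$filter_intercept + config$filter_slope * z
    width <- config$filter_width * exp(config$filter_width_slope * z)
  }
  dmat <- if (config$assembly == "limiting") as.matrix(stats::dist(xmat)) else NULL

  with_seed_(seed, {
    m <- matrix(0, n_sites, npool, dimnames = list(
      if (!is.null(env$site)) as.character(env$site) else sprintf("site%03d", seq_len(n_sites)),
      pool))
    richness <- pmin(pmax(rpois(n_sites, config$richness_mean), 2L), npool)
    for (s in seq_len(n_sites)) {
      k <- richness[s]
      chosen <- switch(config$assembly,
        random = sample.int(npool, k),
        filter = {
          w <- exp(-(filter_x - opt[s])^2 / (2 * width[s]^2))
          w <- pmax(w, 1e-300)
          sample.int(npool, k, prob = w)
        },
        limiting = greedy_maxmin(dmat, k)
      )
      m[s, chosen] <- rlnorm(k, config$abundance_meanlog, config$abundance_sdlog)
    }
    m
  })
}

# greedy max-min spacing: random first species, then repeatedly add the
# species whose minimum distance to the selected set is largest
greedy_maxmin <- function(dmat, k) {
  npool <- nrow(dmat)
  sel <- sample.int(npool, 1L)
  mind <- dmat[, sel]
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, dmat[, nxt])
  }
  sel
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_tree()], [simulate_traits()], [generate_env()] and
#' [simulate_communities()] with sub-seeds derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with elements `tree`, `traits`, `env`, `communities`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  seeds <- derive_seeds(seed, 4L)
  tree <- simulate_tree(config, seed = if (is.null(seed)) NULL else seeds[1])
  traits <- simulate_traits(tree, config, seed = if (is.null(seed)) NULL else seeds[2])
  env <- generate_env(config, seed = if (is.null(seed)) NULL else seeds[3])
  communities <- simulate_communities(traits, env, config,
                                      seed = if (is.null(seed)) NULL else seeds[4])
  list(tree = tree, traits = traits, env = env, communities = communities,
       config = config)
}
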