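#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of trait variance among tips to the variance
#' after phylogenetic correction with the ratio expected under Brownian
#' motion on the same tree:
#' \deqn{K = \frac{MSE_0 / MSE}{E[MSE_0 / MSE]}}
#' with the phylogenetically corrected mean
#' \eqn{\hat a = (1^T V^{-1} 1)^{-1} (1^T V^{-1} x)},
#' \eqn{MSE_0 = (x-\hat a)^T (x-\hat a) / (n-1)},
#' \eqn{MSE = (x-\hat a)^T V^{-1} (x-\hat a) / (n-1)} and
#' \eqn{E[MSE_0/MSE] = [\mathrm{tr}(V) - n/(1^T V^{-1} 1)]/(n-1)},
#' where V is the phylogenetic covariance matrix from [phylo_vcv()].
#' K = 1 is the Brownian expectation; K well below 1 means close relatives
#' resemble each other less than Brownian motion predicts.
#'
#' K is invariant to affine transforms of the trait and to rescaling all
#' branch lengths, and equals 1 exactly on an equal-branch star phylogeny.
#'
#' @param tree A rooted `phylo` object.
#' @param trait_values Numeric vector, named by tip label (or in tip order).
#' @return A single nonnegative number.
#' @examples
#' star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
#' blomberg_k(star, c(A = 0.3, B = -1, C = 2, D = 0.1)) # exactly 1
#' @export
blomberg_k <- function(tree, trait_values) {
  pre <- k_precompute(tree)
  x <- align_trait(tree, trait_values)
  if (sd(x) == 0) stop_validation("zero trait variance: K is undefined for a constant trait")
  k_stat(pre, x)
}

# reusable pieces of the K formula: everything that depends on the tree only
k_precompute <- function(tree) {
  v <- phylo_vcv(tree)
  n <- nrow(v)
  vinv <- tryCatch(
    solve(v),
    error = function(e) stop_validation(paste0(
      "phylogenetic covariance matrix is singular (duplicate zero-length tips?); ",
      "add a minimal branch-length jitter: ", conditionMessage(e)))
  )
  w <- rowSums(vinv)           # V^{-1} 1
  s <- sum(w)                  # 1' V^{-1} 1
  list(n = n, vinv = vinv, w = w, s = s,
       expected_ratio = (sum(diag(v)) - n / s) / (n - 1))
}

align_trait <- function(tree, trait_values) {
  labs <- tree$tip.label
  if (!is.null(names(trait_values))) {
    missing <- setdiff(labs, names(trait_values))
    if (length(missing)) {
      stop_validation(sprintf("trait missing for tips: %s", paste(missing, collapse = ", ")))
    }
    trait_values <- trait_values[labs]
  } else if (length(trait_values) != length(labs)) {
    stop_validation("unnamed trait vector must have one value per tip")
  }
  if (anyNA(trait_values)) stop_validation("trait values contain NA")
  as.numeric(trait_values)
}

k_stat <- function(pre, x) {
  ahat <- sum(pre$w * x) / pre$s
  xc <- x - ahat
  mse0 <- sum(xc^2)
  mse <- sum(xc * (pre$vinv %*% xc))
  (mse0 / mse) / pre$expected_ratio
}

# K for every column of an n x m matrix of (permuted) trait vectors
k_stat_many <- function(pre, xmat) {
  ahat <- colSums(pre$w * xmat) / pre$s
  xc <- sweep(xmat, 2L, ahat)
  mse0 <- colSums(xc^2)
  mse <- colSums(xc * (pre$vinv %*% xc))
  (mse0 / mse) / pre$expected_ratio
}

#' Permutation test of phylogenetic signal
#'
#' The null distribution is built by shuffling species labels across the tips
#' of the phylogeny and recomputing the statistic; the one-tailed p-value
#' uses the add-one rule \eqn{p = (r + 1)/(n_{perm} + 1)} where r counts null
#' statistics at least as large as the observed one (for `statistic = "K"`;
#' for the PIC-variance alternative, at most as small, since low contrast
#' variance indicates signal).
#'
#' @inheritParams blomberg_k
#' @param n_permutations Number of tip shuffles (at least 99; 999 by default).
#' @param seed Integer seed making the shuffle stream reproducible.
#' @param statistic `"K"` (default: K itself, upper tail) or `"pic.var"`
#'   (variance of phylogenetically independent contrasts, lower tail).
#' @param trait Optional trait name recorded in the result.
#' @return One-row tibble: `trait`, `K`, `p_value`, `n_permutations`,
#'   `observed_rank`, `statistic`.
#' @export
signal_pvalue <- function(tree, trait_values, n_permutations = 999, seed = NULL,
                          statistic = c("K", "pic.var"), trait = NA_character_) {
  statistic <- match.arg(statistic)
  assert_number(n_permutations, "n_permutations", min = 99)
  x <- align_trait(tree, trait_values)
  if (sd(x) == 0) stop_validation("zero trait variance: signal test undefined")
  pre <- k_precompute(tree)
  k_obs <- k_stat(pre, x)
  n <- length(x)
  perm_idx <- with_seed_(seed, {
    vapply(seq_len(n_permutations), function(i) sample.int(n), integer(n))
  })
  if (statistic == "K") {
    xmat <- matrix(x[perm_idx], nrow = n)
    null_stats <- k_stat_many(pre, xmat)
    r <- sum(null_stats >= k_obs)
  } else {
    obs_stat <- var(ape::pic(x, tree))
    null_stats <- apply(perm_idx, 2L, function(p) var(ape::pic(x[p], tree)))
    r <- sum(null_stats <= obs_stat)
  }
  tibble(
    trait = trait,
    K = k_obs,
    p_value = (r + 1) / (n_permutations + 1),
    n_permutations = as.integer(n_permutations),
    observed_rank = as.integer(r + 1L),
    statistic = statistic
  )
}

#' Phylogenetic signal for every trait in a table
#'
#' Applies [signal_pvalue()] to each trait column. Raw trait tables are
#' log-standardized first (K itself is affine-invariant, so standardization
#' only serves the log transform's variance stabilization); tables already
#' carrying a `transform_state` attribute are used as-is.
#'
#' @param traits Trait table (`species` column + numeric traits).
#' @param tree A rooted `phylo` object whose tips match `traits$species`.
#' @inheritParams signal_pvalue
#' @return Tibble with one row per trait, mirroring a signal table
#'   (trait, K, p_value, ...).
#' @export
phylo_signal <- function(traits, tree, n_permutations = 999, seed = NULL,
                         statistic = c("K", "pic.var")) {
  statistic <- match.arg(statistic)
  traits <- check_trait_table(traits)
  msgs <- report_set_diff(tree$tip.label, traits$species, "tree", "trait table")
  if (length(msgs)) stop_validation(paste(c("tree/trait mismatch:", msgs), collapse = "\n"))
  if (is.null(attr(traits, "transform_state"))) traits <- log_standardize(traits)
  trait_cols <- setdiff(names(traits), "species")
  seeds <- derive_seeds(seed, length(trait_cols))
  out <- vector("list", length(trait_cols))
  for (i in seq_along(trait_cols)) {
    tc <- trait_cols[i]
    inform(sprintf("phylogenetic signal: %s (%d permutations)", tc, n_permutations))
    out[[i]] <- signal_pvalue(
      tree, setNames(traits[[tc]], traits$species),
      n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else seeds[i],
      statistic = statistic, trait = tc)
  }
  bind_rows(out)
}
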