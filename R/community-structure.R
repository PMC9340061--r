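#' Mean pairwise distance of a community
#'
#' Unweighted mean of the \eqn{k(k-1)/2} pairwise distances among the
#' distinct members of a community. Communities with fewer than two members
#' are degenerate and return `NA` rather than erroring, so that per-site
#' degeneracy can be propagated instead of aborting a run.
#'
#' @param distances Labelled symmetric distance matrix.
#' @param members Character vector of member species.
#' @return Mean pairwise distance, or `NA_real_` if fewer than two members.
#' @examples
#' d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' mpd(d, c("A", "B"))
#' @export
mpd <- function(distances, members) {
  validate_distance_matrix(distances, tol = 1e-9)
  members <- unique(as.character(members))
  missing <- setdiff(members, rownames(distances))
  if (length(missing)) {
    stop_validation(sprintf("members not in distance matrix: %s",
                            paste(missing, collapse = ", ")))
  }
  if (length(members) < 2L) return(NA_real_)
  sub <- distances[members, members]
  mean(sub[lower.tri(sub)])
}

#' Standardized effect size of MPD under the tip-shuffle null
#'
#' For each site, the observed MPD of its members (presence-based; abundances
#' only determine membership) is compared with a null distribution obtained
#' by relabelling the distance matrix with random permutations of the full
#' species pool — the regional pool formed by every label of the distance
#' matrix — while holding community membership fixed:
#' \deqn{SES.MPD = \frac{MPD_{obs} - \mathrm{mean}(MPD_{null})}{\mathrm{sd}(MPD_{null})}}
#' with the sample (n−1) standard deviation. Negative values indicate
#' convergence (co-occurring species closer than chance), positive values
#' divergence. One shared, seeded permutation stream is used for all sites.
#'
#' Sites with richness below two, or whose null distribution has zero spread
#' (e.g. a site containing the entire pool), are flagged `degenerate` and get
#' `NA` SES.
#'
#' @param distances Labelled distance matrix over the species pool.
#' @param communities Site-by-species abundance matrix (rownames = sites), or
#'   a data frame with a `site` column.
#' @param n_permutations Number of pool permutations (at least 99 unless
#'   `exhaustive`).
#' @param seed Integer seed for the permutation stream.
#' @param metric Label stored in the `metric` column (e.g. a trait name,
#'   `"ALL"`, `"PHYLO"`).
#' @param exhaustive If `TRUE`, enumerate the null exactly instead of
#'   sampling: MPD depends only on which k pool members a permutation maps
#'   into the site, and every k-subset is equally likely, so the exact null
#'   is the MPD of each of the `choose(pool, k)` subsets (capped at 1e5 per
#'   site); `n_permutations` is ignored and reports the subset count.
#' @return Tibble with one row per site: `site`, `metric`, `richness`,
#'   `mpd_obs`, `null_mean`, `null_sd`, `ses`, `n_permutations`,
#'   `degenerate`.
#' @export
ses_mpd <- function(distances, communities, n_permutations = 999, seed = NULL,
                    metric = "ALL", exhaustive = FALSE) {
  validate_distance_matrix(distances, tol = 1e-9)
  comm <- as_community_matrix(communities)
  pool <- rownames(distances)
  npool <- length(pool)
  extra <- setdiff(colnames(comm), pool)
  if (length(extra)) {
    stop_validation(sprintf("community species absent from distance matrix: %s",
                            paste(extra, collapse = ", ")))
  }
  if (exhaustive) {
    return(exhaustive_ses(distances, comm, pool, metric))
  }
  assert_number(n_permutations, "n_permutations", min = 99)
  perm_idx <- with_seed_(seed, {
    vapply(seq_len(n_permutations), function(i) sample.int(npool), integer(npool))
  })
  n_perm <- ncol(perm_idx)

  sites <- rownames(comm)
  col_pool_idx <- match(colnames(comm), pool)
  member_idx <- lapply(seq_along(sites), function(s) col_pool_idx[comm[s, ] > 0])
  richness <- lengths(member_idx)

  # flatten the within-site pair lists once; null replicates then reduce to
  # one big matrix lookup + grouped sums
  pair_i <- integer(0); pair_j <- integer(0); pair_site <- integer(0)
  for (s in seq_along(sites)) {
    k <- richness[s]
    if (k < 2L) next
    idx <- member_idx[[s]]
    cmb <- utils::combn(idx, 2L)
    pair_i <- c(pair_i, cmb[1L, ])
    pair_j <- c(pair_j, cmb[2L, ])
    pair_site <- c(pair_site, rep.int(s, ncol(cmb)))
  }
  n_pairs <- tabulate(pair_site, nbins = length(sites))

  mpd_obs <- rep(NA_real_, length(sites))
  null_mean <- rep(NA_real_, length(sites))
  null_sd <- rep(NA_real_, length(sites))
  if (length(pair_i)) {
    obs_sum <- rowsum_by(distances[cbind(pair_i, pair_j)], pair_site, length(sites))
    active <- which(n_pairs > 0)
    mpd_obs[active] <- obs_sum[active] / n_pairs[active]
    null_mat <- matrix(NA_real_, length(active), n_perm)
    for (r in seq_len(n_perm)) {
      p <- perm_idx[, r]
      vals <- distances[cbind(p[pair_i], p[pair_j])]
      null_mat[, r] <- rowsum_by(vals, pair_site, length(sites))[active] / n_pairs[active]
    }
    null_mean[active] <- rowMeans(null_mat)
    null_sd[active] <- sqrt(rowSums((null_mat - null_mean[active])^2) / (n_perm - 1))
  }

  # spread-free nulls (e.g. a site holding the whole pool) leave only
  # floating-point summation noise in null_sd; use a relative floor
  sd_floor <- 1e-10 * pmax(1, abs(null_mean))
  degenerate <- richness < 2L | !is.finite(null_sd) | null_sd <= sd_floor
  ses <- ifelse(degenerate, NA_real_, (mpd_obs - null_mean) / null_sd)
  tibble(
    site = sites,
    metric = metric,
    richness = as.integer(richness),
    mpd_obs = mpd_obs,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    n_permutations = as.integer(n_perm),
    degenerate = degenerate
  )
}

rowsum_by <- function(values, group, ngroups) {
  out <- numeric(ngroups)
  agg <- rowsum(values, group)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# exact null: MPD of every k-subset of the pool, each equally likely under a
# uniform tip-shuffle
exhaustive_ses <- function(distances, comm, pool, metric, cap = 1e5) {
  sites <- rownames(comm)
  rows <- vector("list", length(sites))
  for (s in seq_along(sites)) {
    members <- colnames(comm)[comm[s, ] > 0]
    k <- length(members)
    if (k < 2L) {
      rows[[s]] <- tibble(site = sites[s], metric = metric, richness = k,
                          mpd_obs = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, ses = NA_real_,
                          n_permutations = 0L, degenerate = TRUE)
      next
    }
    n_sub <- choose(length(pool), k)
    if (n_sub > cap) {
      stop_validation(sprintf(
        "exhaustive null for site '%s' needs %.0f subsets (cap %g); use sampling",
        sites[s], n_sub, cap))
    }
    subs <- utils::combn(length(pool), k)
    null_mpd <- apply(subs, 2L, function(idx) {
      sub <- distances[idx, idx]
      mean(sub[lower.tri(sub)])
    })
    obs <- mpd(distances, members)
    nm <- mean(null_mpd)
    ns <- sd(null_mpd)
    deg <- !is.finite(ns) || ns <= 0
    rows[[s]] <- tibble(site = sites[s], metric = metric, richness = k,
                        mpd_obs = obs, null_mean = nm, null_sd = ns,
                        ses = if (deg) NA_real_ else (obs - nm) / ns,
                        n_permutations = as.integer(n_sub), degenerate = deg)
  }
  bind_rows(rows)
}

#' Community-wide departure from the null expectation
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the non-degenerate SES
#' values against zero, run separately for each metric present. The exact
#' null distribution is used for 25 or fewer sites (when free of ties and
#' zeros), the normal approximation with continuity correction otherwise;
#' the `method` column records which. Degenerate sites are excluded and
#' counted.
#'
#' @param ses_results Tibble from [ses_mpd()] (possibly several metrics
#'   bound together).
#' @param alpha Significance threshold used to call a direction.
#' @return Tibble with one row per metric: `metric`, `n_sites`,
#'   `n_degenerate`, `mean_ses`, `ci_lower`, `ci_upper` (95% t-interval),
#'   `p_value`, `direction` (`convergent`/`divergent`/`none`), `method`.
#' @export
departure_test <- function(ses_results, alpha = 0.05) {
  if (!all(c("metric", "ses", "degenerate") %in% names(ses_results))) {
    stop_validation("`ses_results` must come from ses_mpd() (metric, ses, degenerate columns)")
  }
  ses_results |>
    group_by(.data$metric) |>
    group_modify(~ departure_one(.x, alpha)) |>
    ungroup()
}

departure_one <- function(df, alpha) {
  x <- df$ses[!df$degenerate & is.finite(df$ses)]
  n_deg <- sum(df$degenerate)
  if (n_deg > 0) inform(sprintf("departure test: excluded %d degenerate site(s)", n_deg))
  n <- length(x)
  if (n < 6L) {
    stop_validation(sprintf("departure test needs >= 6 non-degenerate SES values, got %d", n))
  }
  if (all(x == 0)) {
    p <- 1
    method <- "all-zero"
  } else {
    use_exact <- n <= 25 && !any(x == 0) && !anyDuplicated(abs(x))
    wt <- suppressWarnings(
      wilcox.test(x, mu = 0, alternative = "two.sided", exact = use_exact, correct = TRUE)
    )
    p <- wt$p.value
    method <- if (use_exact) "exact" else "normal-approximation"
  }
  m <- mean(x)
  se <- sd(x) / sqrt(n)
  tcrit <- stats::qt(0.975, n - 1)
  direction <- if (p < alpha && m < 0) "convergent"
    else if (p < alpha && m > 0) "divergent" else "none"
  tibble(
    n_sites = n,
    n_degenerate = as.integer(n_deg),
    mean_ses = m,
    ci_lower = m - tcrit * se,
    ci_upper = m + tcrit * se,
    p_value = p,
    direction = direction,
    method = method
  )
}

#' Functional and phylogenetic structure across all metrics
#'
#' Convenience wrapper running [ses_mpd()] for each single trait, for the
#' combined trait space (`"ALL"`, Euclidean over PCA axes) and for the
#' phylogeny (`"PHYLO"`, cophenetic distances). Raw trait tables are
#' log-standardized first. Each metric receives its own seeded permutation
#' stream derived from `seed`, so permutations are reproducible but not
#' shared across metrics.
#'
#' @param tree Rooted `phylo` object (pool = its tips).
#' @param traits Trait table whose species match the tree's tips.
#' @param communities Site-by-species matrix or data frame.
#' @param metrics Character vector of metrics; default every trait column
#'   plus `"ALL"` and `"PHYLO"`.
#' @inheritParams ses_mpd
#' @inheritParams trait_distance
#' @return Long tibble of [ses_mpd()] results over all metrics.
#' @export
assembly_structure <- function(tree, traits, communities, metrics = NULL,
                               n_permutations = 999, seed = NULL,
                               axis_rule = c("all", "cumvar"), cumvar = 0.8) {
  axis_rule <- match.arg(axis_rule)
  validate_phylogeny(tree)
  traits <- check_trait_table(traits)
  msgs <- report_set_diff(tree$tip.label, traits$species, "tree", "trait table")
  if (length(msgs)) stop_validation(paste(c("tree/trait mismatch:", msgs), collapse = "\n"))
  if (is.null(attr(traits, "transform_state"))) traits <- log_standardize(traits)
  trait_cols <- setdiff(names(traits), "species")
  if (is.null(metrics)) metrics <- c(trait_cols, "ALL", "PHYLO")
  unknown <- setdiff(metrics, c(trait_cols, "ALL", "PHYLO"))
  if (length(unknown)) {
    stop_validation(sprintf("unknown metric(s): %s", paste(unknown, collapse = ", ")))
  }
  seeds <- derive_seeds(seed, length(metrics))
  out <- vector("list", length(metrics))
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    d <- switch(m,
      ALL = trait_distance(traits, "ALL", axis_rule = axis_rule, cumvar = cumvar),
      PHYLO = cophenetic_distances(tree),
      trait_distance(traits, m)
    )
    out[[i]] <- ses_mpd(d, communities, n_permutations = n_permutations,
                        seed = if (is.null(seed)) NULL else seeds[i], metric = m)
  }
  bind_rows(out)
}
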