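#' Standardize environmental variables
#'
#' Z-scores every numeric column (mean 0, sd 1 with the n−1 denominator);
#' a `site` column, if present, is kept untouched. Idempotent on already
#' standardized input.
#'
#' @param env Data frame of site-level variables.
#' @return Tibble of the same shape with standardized numeric columns.
#' @export
standardize_env <- function(env) {
  env <- as_tibble(env)
  num_cols <- names(env)[vapply(env, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "site")
  if (!length(num_cols)) stop_validation("no numeric columns to standardize")
  for (nc in num_cols) {
    x <- env[[nc]]
    if (anyNA(x)) stop_validation(sprintf("missing values in variable '%s'", nc))
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop_validation(sprintf("constant column '%s' cannot be standardized", nc))
    }
    env[[nc]] <- (x - mean(x)) / s
  }
  env
}

# VIF_j = 1/(1 - R^2_j), predictor j regressed on all others; single
# predictor has VIF 1 by definition
vif_values <- function(x) {
  p <- ncol(x)
  if (p == 1L) return(setNames(1, colnames(x)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    r2 <- r_squared_fit(x[, j], x[, -j, drop = FALSE])
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  setNames(out, colnames(x))
}

# R^2 of an OLS fit with intercept, via qr on the centered design
r_squared_fit <- function(y, x) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  if (is.null(dim(x)) || ncol(x) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  max(0, 1 - rss / tss)
}

#' Collinearity screen by variance inflation factor
#'
#' Iteratively removes the predictor with the highest VIF while any VIF
#' exceeds `threshold`, recomputing after each removal. Ties (including
#' jointly infinite VIFs from exact collinearity) are broken by dropping the
#' later column in input order. The removal history is attached as attribute
#' `removal_log` and retrievable with [vif_removal_log()].
#'
#' @param env Data frame of predictors (a `site` column is carried through
#'   untouched).
#' @param threshold VIF threshold (default 3).
#' @return Tibble of retained predictors, with attribute `removal_log`.
#' @export
vif_filter <- function(env, threshold = 3) {
  env <- as_tibble(env)
  keep_site <- "site" %in% names(env)
  vars <- setdiff(names(env)[vapply(env, is.numeric, logical(1))], "site")
  if (length(vars) < 1L) stop_validation("vif_filter needs at least one numeric predictor")
  x <- as.matrix(env[vars])
  if (nrow(x) <= length(vars)) {
    stop_validation("vif_filter needs more sites than predictors")
  }
  log_rows <- list()
  step <- 0L
  repeat {
    v <- vif_values(x)
    if (ncol(x) == 1L || max(v) <= threshold) break
    step <- step + 1L
    worst <- max(v)
    # later column in input order among the tied worst
    drop_j <- max(which(v == worst))
    log_rows[[step]] <- tibble(step = step, variable = colnames(x)[drop_j],
                               vif_at_removal = worst)
    x <- x[, -drop_j, drop = FALSE]
  }
  out <- env[c(if (keep_site) "site", colnames(x))]
  attr(out, "removal_log") <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(step = integer(), variable = character(), vif_at_removal = numeric())
  attr(out, "vif") <- vif_values(x)
  out
}

#' @rdname vif_filter
#' @param filtered Result of [vif_filter()].
#' @export
vif_removal_log <- function(filtered) attr(filtered, "removal_log")

#' Univariate regressions of a response on each predictor
#'
#' Ordinary least squares of the response on one predictor at a time, with
#' the two-sided t-test p-value for the slope. A zero-variance response
#' yields slope 0, r² 0 and p 1 for every predictor.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Name of the response column.
#' @param predictors Predictor column names (default: every other numeric
#'   column except `site`).
#' @return Tibble: `variable`, `slope`, `r_squared`, `p_value`, `n`.
#' @export
univariate_fits <- function(data, response, predictors = NULL) {
  data <- as_tibble(data)
  if (!response %in% names(data)) stop_validation(sprintf("response '%s' not found", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c(response, "site"))
  }
  y <- data[[response]]
  ok <- stats::complete.cases(data[c(response, predictors)])
  if (sum(ok) < 3L) stop_validation("univariate fits need at least 3 complete sites")
  y <- y[ok]
  n <- length(y)
  purrr::map_dfr(predictors, function(v) {
    x <- data[[v]][ok]
    if (sd(y) == 0) {
      return(tibble(variable = v, slope = 0, r_squared = 0, p_value = 1, n = n))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    tibble(
      variable = v,
      slope = coef(fit)[["x"]],
      r_squared = sm$r.squared,
      p_value = sm$coefficients["x", "Pr(>|t|)"],
      n = n
    )
  })
}

#' Forward stepwise selection with a partial-F entry criterion
#'
#' Starts from the empty (intercept-only) model; at each step the candidate
#' with the smallest partial-F p-value (equivalently the added-term t-test)
#' enters if that p-value is below `alpha`; selection stops when no candidate
#' qualifies. After every addition, all included terms are re-checked and any
#' whose p-value has risen to `alpha` or above is dropped (the event is
#' logged), so the final model only contains terms significant at `alpha`.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Candidate predictor names (default as in
#'   [univariate_fits()]).
#' @param alpha Entry/stay threshold (default 0.05).
#' @return Object of class `driver_fit`: list with `selected` (in entry
#'   order), `coefficients`, `r_squared`, `model` (the final `lm`), `alpha`,
#'   `dropped` (log of removals), `response`. Supports `tidy()`/`glance()`.
#' @export
forward_select <- function(data, response, predictors = NULL, alpha = 0.05) {
  data <- as_tibble(data)
  if (!response %in% names(data)) stop_validation(sprintf("response '%s' not found", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c(response, "site"))
  }
  y <- data[[response]]
  selected <- character(0)
  dropped_log <- list()
  candidates <- predictors
  iter <- 0L
  while (length(candidates) && iter < 100L) {
    iter <- iter + 1L
    pvals <- vapply(candidates, function(v) {
      term_pvalue(data, y, c(selected, v), v)
    }, numeric(1))
    best <- which.min(pvals)
    if (!is.finite(pvals[best]) || pvals[best] >= alpha) break
    selected <- c(selected, candidates[best])
    candidates <- candidates[-best]
    # backward check: drop any included term no longer significant
    repeat {
      if (length(selected) < 2L) break
      ps <- vapply(selected, function(v) term_pvalue(data, y, selected, v), numeric(1))
      if (all(ps < alpha)) break
      worst <- which.max(ps)
      dropped_log[[length(dropped_log) + 1L]] <- tibble(
        variable = selected[worst], p_value = ps[worst],
        after_adding = selected[length(selected)])
      inform(sprintf("forward_select: dropped '%s' (p = %.3g) after adding '%s'",
                     selected[worst], ps[worst], selected[length(selected)]))
      candidates <- c(candidates, selected[worst])
      selected <- selected[-worst]
    }
  }
  if (length(selected)) {
    fml <- stats::reformulate(selected, response = response)
    model <- lm(fml, data = data)
    r2 <- summary(model)$r.squared
    coefs <- coef(model)[selected]
  } else {
    model <- lm(stats::reformulate("1", response = response), data = data)
    r2 <- 0
    coefs <- numeric(0)
  }
  structure(
    list(selected = selected, coefficients = coefs, r_squared = r2,
         model = model, alpha = alpha,
         dropped = if (length(dropped_log)) bind_rows(dropped_log) else NULL,
         response = response),
    class = "driver_fit"
  )
}

# two-sided t-test p-value of `term` in the OLS of y on `terms`
term_pvalue <- function(data, y, terms, term) {
  df <- as.data.frame(data[terms])
  df[[".response"]] <- y
  fml <- stats::reformulate(sprintf("`%s`", terms), response = ".response")
  fit <- lm(fml, data = df)
  cf <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(cf))
  if (!term %in% rn) return(NA_real_)  # aliased (collinear) term
  cf[match(term, rn), "Pr(>|t|)"]
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("Forward selection on '%s' (alpha = %g)\n", x$response, x$alpha))
  if (length(x$selected)) {
    cat("Selected:", paste(x$selected, collapse = " + "),
        sprintf("(R^2 = %.3f)\n", x$r_squared))
  } else cat("Empty model (no predictor reached alpha)\n")
  invisible(x)
}

#' @export
tidy.driver_fit <- function(x, ...) {
  if (!length(x$selected)) {
    return(tibble(variable = character(), estimate = numeric(), p_value = numeric()))
  }
  cf <- summary(x$model)$coefficients
  tibble(
    variable = x$selected,
    estimate = cf[x$selected, "Estimate"],
    p_value = cf[x$selected, "Pr(>|t|)"]
  )
}

#' @export
glance.driver_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_selected = length(x$selected), alpha = x$alpha)
}

#' Hierarchical partitioning of regression variance
#'
#' Exact decomposition of the full-model R² into per-predictor independent
#' effects by the classical averaging scheme: for predictor i and each
#' hierarchy level k, average the R² increment of adding i over all subsets
#' of the other predictors of size k, then average the level means. The
#' independent effects sum exactly to the full-model R²; the joint effect of
#' a predictor is its univariate R² minus its independent effect and may be
#' negative under suppression. All \eqn{2^p} subset models are fitted, so
#' `p` is capped at 12.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Predictor names (at least one).
#' @return Tibble of class `hier_part`: `variable`, `independent_effect`,
#'   `joint_effect`, `univariate_r2`, `independent_pct` (share of the full
#'   R², in %); attribute `r_squared_full` carries the full-model R².
#' @export
hierarchical_partition <- function(data, response, predictors) {
  data <- as_tibble(data)
  p <- length(predictors)
  if (p < 1L) stop_validation("hierarchical partitioning needs at least one predictor")
  if (p > 12L) {
    stop_validation(sprintf(
      "hierarchical partitioning over %d predictors needs 2^%d model fits; reduce to at most 12 (e.g. run forward_select() first)",
      p, p))
  }
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    stop_validation(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[response]]
  x <- as.matrix(data[predictors])
  nsub <- bitwShiftL(1L, p)
  r2 <- numeric(nsub)  # r2[mask + 1] = R^2 of the subset encoded by mask
  for (mask in seq_len(nsub - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0L)
    r2[mask + 1L] <- r_squared_fit(y, x[, cols, drop = FALSE])
  }
  indep <- numeric(p)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    others <- setdiff(seq_len(p), i)
    other_masks <- subset_masks(others, p)
    sizes <- vapply(other_masks, popcount, integer(1))
    inc <- vapply(other_masks, function(m) r2[bitwOr(m, bit_i) + 1L] - r2[m + 1L],
                  numeric(1))
    level_means <- tapply(inc, sizes, mean)
    indep[i] <- mean(level_means)
  }
  uni <- vapply(seq_len(p), function(i) r2[bitwShiftL(1L, i - 1L) + 1L], numeric(1))
  joint <- uni - indep
  if (any(indep < 0)) {
    warn(sprintf("negative independent effect(s) for: %s (collinearity pathology; reported as computed)",
                 paste(predictors[indep < 0], collapse = ", ")))
  }
  r2_full <- r2[nsub]
  out <- tibble(
    variable = predictors,
    independent_effect = indep,
    joint_effect = joint,
    univariate_r2 = uni,
    independent_pct = if (r2_full > 0) 100 * indep / r2_full else NA_real_
  )
  attr(out, "r_squared_full") <- r2_full
  class(out) <- c("hier_part", class(out))
  out
}

# all bitmasks over the positions in `others` (positions are 1..p)
subset_masks <- function(others, p) {
  masks <- 0L
  for (pos in others) {
    masks <- c(masks, bitwOr(masks, bitwShiftL(1L, pos - 1L)))
  }
  masks
}

popcount <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

#' Full driver attribution for one response metric
#'
#' The complete driver workflow: standardize response and predictors,
#' VIF-screen the predictors, fit univariate regressions, run forward
#' selection, and hierarchically partition the selected model's R².
#'
#' @param data Data frame with the response column, predictor columns and
#'   optionally `site`.
#' @param response Name of the response column (e.g. an SES metric).
#' @param predictors Predictor names (default: all other numeric columns).
#' @param vif_threshold VIF threshold for the collinearity screen.
#' @param alpha Forward-selection entry threshold.
#' @return Object of class `driver_result`: list with `response`,
#'   `retained_after_vif`, `vif_removed`, `univariate`, `fit` (the
#'   `driver_fit`), `partition` (the `hier_part` tibble, `NULL` for an empty
#'   model), `r_squared`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
driver_analysis <- function(data, response, predictors = NULL,
                            vif_threshold = 3, alpha = 0.05) {
  data <- as_tibble(data)
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c(response, "site"))
  }
  ok <- !is.na(data[[response]])
  if (any(!ok)) {
    inform(sprintf("driver_analysis: excluded %d site(s) with missing response", sum(!ok)))
    data <- data[ok, ]
  }
  data <- standardize_env(data[c(intersect("site", names(data)), response, predictors)])
  filtered <- vif_filter(data[predictors], threshold = vif_threshold)
  retained <- setdiff(names(filtered), "site")
  uni <- univariate_fits(data, response, retained)
  fit <- forward_select(data, response, retained, alpha = alpha)
  part <- if (length(fit$selected)) {
    hierarchical_partition(data, response, fit$selected)
  } else NULL
  structure(
    list(
      response = response,
      retained_after_vif = retained,
      vif_removed = vif_removal_log(filtered),
      univariate = uni,
      fit = fit,
      partition = part,
      r_squared = fit$r_squared
    ),
    class = "driver_result"
  )
}

#' @export
print.driver_result <- function(x, ...) {
  cat(sprintf("Driver analysis for '%s'\n", x$response))
  cat(sprintf("  retained after VIF screen: %s\n", paste(x$retained_after_vif, collapse = ", ")))
  print(x$fit)
  if (!is.null(x$partition)) {
    cat("  independent effects (% of model R^2):\n")
    pt <- x$partition
    for (i in seq_len(nrow(pt))) {
      cat(sprintf("    %-8s %6.3f (%5.1f%%)\n", pt$variable[i],
                  pt$independent_effect[i], pt$independent_pct[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.driver_result <- function(x, ...) {
  uni <- x$univariate |>
    select("variable", univariate_slope = "slope",
           univariate_r2 = "r_squared", univariate_p = "p_value")
  base <- tibble(variable = x$retained_after_vif) |>
    left_join(uni, by = "variable") |>
    mutate(selected = .data$variable %in% x$fit$selected)
  if (!is.null(x$partition)) {
    base <- left_join(
      base,
      select(as_tibble(x$partition), "variable", "independent_effect",
             "joint_effect", "independent_pct"),
      by = "variable")
  } else {
    base$independent_effect <- NA_real_
    base$joint_effect <- NA_real_
    base$independent_pct <- NA_real_
  }
  base
}

#' @export
glance.driver_result <- function(x, ...) {
  tibble(
    response = x$response,
    r_squared = x$r_squared,
    n_retained = length(x$retained_after_vif),
    n_selected = length(x$fit$selected),
    n_removed_vif = nrow(x$vif_removed)
  )
}
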