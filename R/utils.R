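#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats sd var cor lm pf pt prcomp rnorm rpois rlnorm runif
#'   wilcox.test setNames coef quantile
NULL

# validation errors get their own condition class so the CLI can map them to
# exit code 2
stop_validation <- function(msg, ...) {
  abort(msg, class = "phylassem_validation_error", ...)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()]: when `seed` is `NULL` the
#' expression runs against the current RNG stream, otherwise it runs under
#' `seed` and the caller's RNG state is restored afterwards.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# derive k reproducible sub-seeds from one master seed, each < 2^31
derive_seeds <- function(seed, k) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, k))
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop_validation(sprintf("`%s` must be a single number >= %s", name, min))
  }
  invisible(x)
}

#' Validate a labelled distance matrix
#'
#' Checks the contract every pairwise-distance consumer in the package relies
#' on: square numeric matrix, unique row/column labels in matching order,
#' symmetry within `tol`, an exactly zero diagonal and no negative entries.
#'
#' @param d Numeric matrix with dimnames.
#' @param tol Symmetry tolerance.
#' @return `d`, invisibly, after zeroing any sub-`tol` asymmetry.
#' @export
validate_distance_matrix <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || !is.numeric(d)) {
    stop_validation("distance matrix must be a numeric matrix")
  }
  if (nrow(d) != ncol(d)) stop_validation("distance matrix must be square")
  lab <- rownames(d)
  if (is.null(lab) || is.null(colnames(d)) || !identical(lab, colnames(d))) {
    stop_validation("distance matrix must carry identical row and column labels")
  }
  if (anyDuplicated(lab)) stop_validation("distance matrix labels must be unique")
  if (max(abs(d - t(d))) > tol) {
    stop_validation(sprintf("distance matrix asymmetric beyond tol = %g", tol))
  }
  if (any(diag(d) != 0)) stop_validation("distance matrix diagonal must be exactly zero")
  if (any(d < 0)) stop_validation("distance matrix entries must be nonnegative")
  invisible(d)
}

# coerce community input (matrix with dimnames, or data frame with a `site`
# column) to a sites x species numeric matrix
as_community_matrix <- function(communities) {
  if (is.data.frame(communities)) {
    cn <- names(communities)
    site_col <- if ("site" %in% cn) "site" else cn[1L]
    m <- as.matrix(communities[setdiff(cn, site_col)])
    rownames(m) <- as.character(communities[[site_col]])
    storage.mode(m) <- "double"
    communities <- m
  }
  if (!is.matrix(communities) || !is.numeric(communities)) {
    stop_validation("communities must be a numeric matrix or a data frame with a `site` column")
  }
  if (is.null(rownames(communities))) {
    rownames(communities) <- paste0("site", seq_len(nrow(communities)))
  }
  if (is.null(colnames(communities))) {
    stop_validation("community matrix must have species names as column names")
  }
  if (any(communities < 0)) stop_validation("abundances must be nonnegative")
  if (any(colSums(communities > 0) == 0)) {
    # harmless: the null pool is the distance matrix, not the occupancy
    inform("community matrix contains species that occur in no site")
  }
  communities
}

# set difference report used by the pipeline's cross-input validation
report_set_diff <- function(a, b, what_a, what_b) {
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  msgs <- character()
  if (length(only_a)) {
    msgs <- c(msgs, sprintf("in %s but not %s: %s", what_a, what_b,
                            paste(only_a, collapse = ", ")))
  }
  if (length(only_b)) {
    msgs <- c(msgs, sprintf("in %s but not %s: %s", what_b, what_a,
                            paste(only_b, collapse = ", ")))
  }
  msgs
}
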