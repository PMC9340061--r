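#' Log-transform and standardize a trait table
#'
#' Each trait column is natural-log transformed, then z-scored to mean 0 and
#' unit (n−1) standard deviation. Traits must be strictly positive — leaf and
#' root traits such as SLA or nutrient concentrations are ratios and
#' concentrations, so nonpositive values indicate a data problem and are
#' reported by species and trait.
#'
#' @param traits Data frame with a `species` column followed by numeric trait
#'   columns.
#' @return A tibble of the same shape with transformed columns; attribute
#'   `transform_state` is set to `"log-standardized"`.
#' @examples
#' tab <- tibble::tibble(species = c("a", "b", "c"), SLA = c(1, exp(1), exp(2)))
#' log_standardize(tab)
#' @export
log_standardize <- function(traits) {
  traits <- check_trait_table(traits)
  trait_cols <- setdiff(names(traits), "species")
  for (tc in trait_cols) {
    x <- traits[[tc]]
    bad <- which(x <= 0)
    if (length(bad)) {
      stop_validation(sprintf(
        "nonpositive value in trait '%s' for species: %s (log transform requires > 0)",
        tc, paste(traits$species[bad], collapse = ", ")))
    }
    lx <- log(x)
    s <- sd(lx)
    if (!is.finite(s) || s == 0) {
      stop_validation(sprintf("trait '%s' has zero variance after log transform", tc))
    }
    traits[[tc]] <- (lx - mean(lx)) / s
  }
  attr(traits, "transform_state") <- "log-standardized"
  traits
}

check_trait_table <- function(traits) {
  if (!is.data.frame(traits)) stop_validation("traits must be a data frame")
  if (!"species" %in% names(traits)) {
    stop_validation("trait table must have a `species` column")
  }
  traits <- as_tibble(traits)
  traits$species <- as.character(traits$species)
  if (anyDuplicated(traits$species)) stop_validation("duplicate species in trait table")
  trait_cols <- setdiff(names(traits), "species")
  if (!length(trait_cols)) stop_validation("trait table has no trait columns")
  for (tc in trait_cols) {
    if (!is.numeric(traits[[tc]])) {
      stop_validation(sprintf("trait column '%s' is not numeric", tc))
    }
    if (anyNA(traits[[tc]])) {
      stop_validation(sprintf("missing values in trait '%s'", tc))
    }
  }
  traits
}

#' Principal components ordination of a standardized trait table
#'
#' PCA on the (already standardized) trait columns, used to absorb redundancy
#' among correlated leaf and root traits before computing combined-trait
#' distances. Because the input columns have unit variance, the eigenvalues
#' sum to the number of traits and Euclidean distances over all axes equal
#' distances in the standardized trait space.
#'
#' @param traits A standardized trait table (see [log_standardize()]).
#' @return An object of class `trait_pca` with elements `scores` (tibble:
#'   species + PC columns), `eigenvalues`, `proportion_explained`, `rotation`
#'   and `n_traits`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
pca_ordination <- function(traits) {
  traits <- check_trait_table(traits)
  trait_cols <- setdiff(names(traits), "species")
  x <- as.matrix(traits[trait_cols])
  const <- trait_cols[apply(x, 2L, sd) == 0]
  if (length(const)) {
    stop_validation(sprintf("constant trait column(s): %s", paste(const, collapse = ", ")))
  }
  if (nrow(x) < length(trait_cols)) {
    warn(sprintf("fewer species (%d) than traits (%d): trailing axes are degenerate",
                 nrow(x), length(trait_cols)))
  }
  # columns arrive standardized; center defensively so scores are exact
  # projections even if the caller passed raw (but nonconstant) columns
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  scores <- as_tibble(as.data.frame(pc$x))
  scores <- bind_cols(tibble(species = traits$species), scores)
  structure(
    list(
      scores = scores,
      eigenvalues = eig,
      proportion_explained = eig / sum(eig),
      rotation = pc$rotation,
      n_traits = length(trait_cols)
    ),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Trait PCA: %d traits, %d species\n", x$n_traits, nrow(x$scores)))
  cat("Proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble(
    axis = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion_explained = x$proportion_explained,
    cumulative_explained = cumsum(x$proportion_explained)
  )
}

#' @importFrom generics glance
#' @export
glance.trait_pca <- function(x, ...) {
  tibble(
    n_species = nrow(x$scores),
    n_traits = x$n_traits,
    axis1_proportion = x$proportion_explained[1L]
  )
}

# which axes to keep under a retention policy
retained_axes <- function(ord, axis_rule = c("all", "cumvar"), cumvar = 0.8) {
  axis_rule <- match.arg(axis_rule)
  if (axis_rule == "all") return(seq_along(ord$eigenvalues))
  k <- which(cumsum(ord$proportion_explained) >= cumvar)[1L]
  seq_len(k)
}

#' Functional distance matrix from traits
#'
#' For a single trait, the distance between two species is the absolute
#' difference of their (standardized) values. For `traits_use = "ALL"`, a PCA
#' is run internally and the distance is Euclidean over the retained axes;
#' with `axis_rule = "all"` (the default) this equals Euclidean distance in
#' the standardized trait space.
#'
#' @param traits A standardized trait table.
#' @param traits_use `"ALL"` or a character vector of trait names (a single
#'   name gives the per-trait distance).
#' @param axis_rule `"all"` to keep every PCA axis, `"cumvar"` to keep the
#'   smallest leading set reaching `cumvar` cumulative variance.
#' @param cumvar Cumulative-variance cutoff used when `axis_rule = "cumvar"`.
#' @return A labelled symmetric distance matrix (species order of `traits`).
#' @export
trait_distance <- function(traits, traits_use = "ALL",
                           axis_rule = c("all", "cumvar"), cumvar = 0.8) {
  axis_rule <- match.arg(axis_rule)
  traits <- check_trait_table(traits)
  trait_cols <- setdiff(names(traits), "species")
  if (identical(traits_use, "ALL")) {
    ord <- pca_ordination(traits)
    keep <- retained_axes(ord, axis_rule, cumvar)
    sc <- as.matrix(ord$scores[paste0("PC", keep)])
    d <- as.matrix(stats::dist(sc))
  } else {
    unknown <- setdiff(traits_use, trait_cols)
    if (length(unknown)) {
      stop_validation(sprintf("unknown trait name(s): %s", paste(unknown, collapse = ", ")))
    }
    x <- as.matrix(traits[traits_use])
    d <- as.matrix(stats::dist(x))
  }
  dimnames(d) <- list(traits$species, traits$species)
  diag(d) <- 0
  validate_distance_matrix(d, tol = 1e-9)
  d
}
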