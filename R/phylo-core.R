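#' Read a rooted Newick phylogeny
#'
#' Parses a single rooted Newick string with branch lengths into an
#' [ape::phylo] object and validates the invariants the rest of the package
#' relies on: unique, nonempty tip labels; nonnegative edge lengths; a rooted
#' topology.
#'
#' @param path Path to a file containing one Newick string.
#' @return A rooted `phylo` object.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' tr <- read_newick(f)
#' ape::Ntip(tr)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("tree file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop_validation(sprintf("malformed Newick in %s: %s", path, conditionMessage(e)))
  )
  if (is.null(tree)) stop_validation(sprintf("malformed Newick in %s", path))
  validate_phylogeny(tree)
  tree
}

# cheap positional pre-check so syntax errors name the offending character
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_validation(sprintf("malformed Newick: unmatched ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop_validation(sprintf(
      "malformed Newick: %d unclosed '(' (string ends at position %d)",
      depth, length(chars)))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop_validation(sprintf("malformed Newick: missing ';' terminator at position %d", nchar(txt)))
  }
  invisible(txt)
}

#' Validate the phylogeny contract
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_validation("tree must be a `phylo` object")
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop_validation(sprintf("duplicate tip labels: %s",
                            paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  if (any(!nzchar(labs))) stop_validation("empty tip labels are not allowed")
  if (is.null(tree$edge.length)) stop_validation("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop_validation("negative branch lengths are not allowed")
  # a star (root is the only internal node) is rooted for our purposes even
  # though ape's convention flags basal polytomies as unrooted
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) stop_validation("tree must be rooted")
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths (default keeps
#'   round-trips distance-preserving to well below 1e-9 on unit-depth trees).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Root-to-tip depths
#'
#' @param tree A rooted `phylo` object.
#' @return Named numeric vector of root-to-tip path lengths, in tip order.
#' @export
tip_depths <- function(tree) {
  validate_phylogeny(tree)
  nd <- ape::node.depth.edgelength(tree)
  setNames(nd[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Tree depth and ultrametricity check
#'
#' A tree is treated as ultrametric when all root-to-tip depths agree within
#' `tol` relative to the maximum depth.
#'
#' @param tree A rooted `phylo` object.
#' @param tol Relative tolerance (default 1e-6).
#' @return `is_ultrametric_tree()`: logical; `tree_depth()`: the maximum
#'   root-to-tip depth.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

#' @rdname is_ultrametric_tree
#' @export
tree_depth <- function(tree) max(tip_depths(tree))

#' Cophenetic (patristic) distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the path between tips i
#' and j — the phylogenetic distance entering MPD.
#'
#' @param tree A rooted `phylo` object with at least two tips.
#' @return Symmetric numeric matrix with tips in `tree$tip.label` order.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' cophenetic_distances(tr)
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2) stop_validation("no pairs: tree has a single tip")
  d <- stats::cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  diag(d) <- 0
  validate_distance_matrix(d, tol = 1e-9)
  d
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA branch length of tips i and j;
#' the diagonal holds root-to-tip depths. This is the Brownian-motion
#' covariance structure used inside Blomberg's K.
#'
#' @param tree A rooted `phylo` object with at least two tips.
#' @return Symmetric positive-semidefinite matrix in tip order.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2) stop_validation("phylogenetic covariance needs >= 2 tips")
  v <- ape::vcv(tree)
  v[tree$tip.label, tree$tip.label]
}

#' Graft missing taxa onto a genus-level phylogeny
#'
#' Adds species absent from the tree by attaching each one inside its genus,
#' in the spirit of backbone-tree tools that place unsampled taxa among
#' congeners with known branch lengths:
#'
#' * genus with two or more tips: the new tip is attached to the genus crown
#'   node (the MRCA of its tips) as an extra child — a polytomy — with branch
#'   length equal to the crown node's depth-to-tip, so ultrametric trees stay
#'   ultrametric and all existing pairwise distances are untouched;
#' * monotypic genus: no crown node exists, so a node is inserted at the
#'   midpoint of the single tip's branch and the new tip forms a cherry with
#'   it.
#'
#' @param tree A rooted `phylo` object.
#' @param new_taxa Named character vector mapping new species labels to genus
#'   names, or a two-column data frame (species, genus).
#' @param genus_of_tip Named character vector mapping existing tip labels to
#'   genera. By default genera are parsed from tip labels of the form
#'   `Genus_epithet` (text before the first underscore).
#' @return The enlarged `phylo` object.
#' @examples
#' tr <- ape::read.tree(text = "((GenA_s1:1,GenA_s2:1):1,GenB_s1:2);")
#' grafted <- graft_missing_taxa(tr, c(GenA_s3 = "GenA"))
#' sort(grafted$tip.label)
#' @export
graft_missing_taxa <- function(tree, new_taxa, genus_of_tip = NULL) {
  validate_phylogeny(tree)
  if (is.data.frame(new_taxa)) {
    new_taxa <- setNames(as.character(new_taxa[[2L]]), as.character(new_taxa[[1L]]))
  }
  if (is.null(names(new_taxa)) || any(!nzchar(names(new_taxa)))) {
    stop_validation("`new_taxa` must map species names to genus names")
  }
  if (any(names(new_taxa) %in% tree$tip.label)) {
    stop_validation(sprintf("species already in tree: %s",
                            paste(intersect(names(new_taxa), tree$tip.label), collapse = ", ")))
  }
  if (is.null(genus_of_tip)) genus_of_tip <- genus_from_labels(tree$tip.label)
  missing_map <- setdiff(tree$tip.label, names(genus_of_tip))
  if (length(missing_map)) {
    stop_validation(sprintf("no genus assignment for tips: %s",
                            paste(missing_map, collapse = ", ")))
  }
  unplaceable <- names(new_taxa)[!(new_taxa %in% genus_of_tip)]
  if (length(unplaceable)) {
    stop_validation(sprintf(
      "genus absent from tree; cannot place species: %s",
      paste(sprintf("%s (%s)", unplaceable, new_taxa[unplaceable]), collapse = ", ")))
  }
  for (sp in names(new_taxa)) {
    tree <- graft_one(tree, sp, new_taxa[[sp]], genus_of_tip)
    genus_of_tip[sp] <- new_taxa[[sp]]
  }
  validate_phylogeny(tree)
  tree
}

graft_one <- function(tree, species, genus, genus_of_tip) {
  members <- names(genus_of_tip)[genus_of_tip == genus]
  members <- intersect(tree$tip.label, members)
  tip_idx <- match(members, tree$tip.label)
  if (length(members) >= 2L) {
    crown <- ape::getMRCA(tree, members)
    depths <- ape::node.depth.edgelength(tree)
    # crown depth-to-tip: mean tip depth below the crown minus crown depth
    # (all equal for an ultrametric tree)
    len <- mean(depths[tip_idx]) - depths[crown]
    phytools::bind.tip(tree, species, edge.length = len, where = crown, position = 0)
  } else {
    # monotypic genus: insert a node halfway down the tip's branch
    edge_row <- which(tree$edge[, 2L] == tip_idx)
    half <- tree$edge.length[edge_row] / 2
    phytools::bind.tip(tree, species, edge.length = half, where = tip_idx, position = half)
  }
}

#' Parse genus names from `Genus_epithet` tip labels
#'
#' @param labels Character vector of tip labels.
#' @return Named character vector mapping each label to its genus.
#' @export
genus_from_labels <- function(labels) {
  setNames(sub("_.*$", "", labels), labels)
}
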