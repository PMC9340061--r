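# in-code fixtures shared across test files

tree_3tip <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n = 4, len = 1) {
  labs <- paste0("t", seq_len(n))
  ape::read.tree(text = paste0("(", paste0(labs, ":", len, collapse = ","), ");"))
}

# worked 3-species pool: d(A,B)=2, d(A,C)=4, d(B,C)=6
worked_pool <- function() {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 6
  d
}

one_site <- function(members, pool) {
  m <- matrix(0, 1, length(pool), dimnames = list("s1", pool))
  m[1, members] <- 1
  m
}

random_yule <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  })
}

# independent brute-force patristic distance: sum edge lengths along the
# node path between each tip pair (never touches cophenetic_distances)
brute_force_cophenetic <- function(tree) {
  n <- ape::Ntip(tree)
  labs <- tree$tip.label
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  edge_len <- function(a, b) {
    row <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
                 (tree$edge[, 1] == b & tree$edge[, 2] == a))
    tree$edge.length[row]
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      len <- 0
      for (k in seq_len(length(path) - 1)) len <- len + edge_len(path[k], path[k + 1])
      d[i, j] <- d[j, i] <- len
    }
  }
  d
}

# standardized trait table with independent N(0,1) columns
random_trait_table <- function(species, p = 3, seed = 1, prefix = "tr") {
  withr::with_seed(seed, {
    tab <- tibble::tibble(species = species)
    for (k in seq_len(p)) tab[[paste0(prefix, k)]] <- rnorm(length(species))
    tab
  })
}

# independent hierarchical-partitioning oracle: average the R^2 increment of
# adding variable i over all p! orderings (Shapley form) — a different
# formulation from the level-averaging implementation
hp_oracle <- function(data, response, predictors) {
  p <- length(predictors)
  y <- data[[response]]
  r2_of <- function(set) {
    if (!length(set)) return(0)
    summary(lm(y ~ ., data = data[set]))$r.squared
  }
  perms <- all_orderings(p)
  indep <- numeric(p)
  for (i in seq_len(p)) {
    inc <- 0
    for (r in seq_len(nrow(perms))) {
      ord <- perms[r, ]
      pos <- which(ord == i)
      before <- predictors[ord[seq_len(pos - 1)]]
      inc <- inc + r2_of(c(before, predictors[i])) - r2_of(before)
    }
    indep[i] <- inc / nrow(perms)
  }
  indep
}

# all permutations of 1..n as rows (tiny n)
all_orderings <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_orderings(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    blk <- cbind(k, sub + (sub >= k))
    out <- rbind(out, blk)
  }
  out
}
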