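#' Remove all columns containing a gap
#'
#' Restriction of an MSA to its ungapped columns, the input expected by the
#' distance and tree operations.
#'
#' @param msa An `msa` object.
#' @return An `msa` with only gap-free columns; errors when none remain.
#' @export
ungapped_columns <- function(msa) {
  m <- .msa_matrix(msa)
  keep <- colSums(m == "-") == 0L
  if (!any(keep)) stop("no ungapped columns remain")
  new_msa(msa$ids, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
          taxa = unname(msa$taxa))
}

#' Pairwise distance matrix from an ungapped MSA
#'
#' `p-distance` is the mismatch fraction per pair; `poisson` applies the
#' Poisson correction `-ln(1 - p)` for multiple substitutions. A distance
#' pipeline is used here as a desk-scale stand-in for full
#' maximum-likelihood fitting; the clustering claims it supports concern
#' topology, not branch-length likelihoods.
#'
#' @param msa An `msa`, gap-free (see [ungapped_columns()]).
#' @param model `"p-distance"` or `"poisson"`.
#' @param undefined_policy When `p >= 1` makes the Poisson correction
#'   undefined: `"cap"` substitutes `cap_value`, `"error"` aborts.
#' @param cap_value Cap for undefined corrected distances (default 10).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = record
#'   ids.
#' @export
distance_matrix <- function(msa, model = c("p-distance", "poisson"),
                            undefined_policy = c("cap", "error"),
                            cap_value = 10) {
  model <- match.arg(model)
  undefined_policy <- match.arg(undefined_policy)
  m <- .msa_matrix(msa)
  if (any(m == "-")) stop("distance_matrix expects a gap-free MSA")
  n <- msa$n
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(m[i, ] != m[j, ])
    if (model == "poisson") {
      if (p >= 1) {
        if (undefined_policy == "error")
          stop("Poisson correction undefined for completely different pair ",
               msa$ids[i], " / ", msa$ids[j])
        p <- cap_value
      } else p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix (via ape).
#'
#' @param d Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  ape::nj(d)
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement `n` times, rebuilds the
#' distance/NJ tree per replicate, and reports per-edge support as the
#' fraction of replicate trees containing each bipartition of the original
#' tree. Supports are stored in `node.label` on the returned tree.
#'
#' @param msa Gap-free `msa`.
#' @param model Distance model, see [distance_matrix()].
#' @param n Number of bootstrap replicates (default 100).
#' @param seed Integer random seed (required; no hidden default).
#' @return List with `tree` (node labels = support in `[0, 1]`),
#'   `supports` (numeric vector per internal node), `n`.
#' @export
bootstrap_support <- function(msa, model = "p-distance", n = 100L, seed) {
  if (missing(seed)) stop("a random seed is required for the bootstrap")
  stopifnot(n >= 1L)
  base <- nj_tree(distance_matrix(msa, model = model))
  m <- .msa_matrix(msa)
  set.seed(seed)
  reps <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_msa <- new_msa(msa$ids,
                       apply(m[, cols, drop = FALSE], 1, paste, collapse = ""))
    reps[[b]] <- nj_tree(distance_matrix(rep_msa, model = model))
  }
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- counts / n
  base$node.label <- format(supports, trim = TRUE)
  list(tree = base, supports = supports, n = n)
}

.tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) sort(tips[idx]))
}

#' Support of the bipartition separating a given leaf set
#'
#' @param boot Result of [bootstrap_support()].
#' @param group Character vector of tip labels.
#' @return Support in `[0, 1]`, or `NA` when no edge of the tree separates
#'   exactly this group.
#' @export
split_support <- function(boot, group) {
  tree <- boot$tree
  tips <- tree$tip.label
  target <- sort(match(group, tips))
  comp <- sort(setdiff(seq_along(tips), target))
  pp <- ape::prop.part(tree)
  for (k in seq_along(pp)) {
    part <- sort(pp[[k]])
    if (identical(part, target) || identical(part, comp))
      return(unname(boot$supports[k]))
  }
  NA_real_
}

#' Monophyly of labeled groups on an unrooted tree
#'
#' For each group, reports whether some edge of the tree separates exactly
#' the group's leaves from everything else (strict bipartition identity).
#' Non-monophyletic groups get a description of the nearest clade (highest
#' Jaccard overlap with the group).
#'
#' @param tree A `phylo` tree.
#' @param label_map Named character vector: tip label -> group.
#' @return Data frame: `group`, `n_leaves`, `monophyletic`,
#'   `nearest_clade` (description, `NA` when monophyletic).
#' @export
cluster_membership <- function(tree, label_map) {
  tips <- tree$tip.label
  if (!all(tips %in% names(label_map)))
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(label_map)), collapse = ", "))
  groups <- split(tips, label_map[tips])
  biparts <- .tree_bipartitions(tree)
  all_sorted <- sort(tips)
  res <- lapply(names(groups), function(g) {
    mem <- sort(groups[[g]])
    comp <- sort(setdiff(tips, mem))
    mono <- length(mem) == 1L || length(comp) == 0L ||
      any(vapply(biparts, function(b)
        identical(b, mem) || identical(b, comp), TRUE))
    nearest <- NA_character_
    if (!mono) {
      jac <- vapply(biparts, function(b) {
        length(intersect(b, mem)) / length(union(b, mem))
      }, 0)
      jac[vapply(biparts, function(b) identical(b, all_sorted), TRUE)] <- -1
      best <- biparts[[which.max(jac)]]
      nearest <- sprintf("closest clade {%s} (Jaccard %.2f)",
                         paste(best, collapse = ","), max(jac))
    }
    data.frame(group = g, n_leaves = length(mem), monophyletic = mono,
               nearest_clade = nearest, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
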