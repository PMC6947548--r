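# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# Exhaustive O(n*m) residue-within-cutoff oracle: double loop over atoms.
oracle_region_residues <- function(structure, lig_xyz, cutoff,
                                   exclude_key = NULL) {
  at <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  if (!is.null(exclude_key)) {
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 at$resname, sep = "|")
    at <- at[key != exclude_key, , drop = FALSE]
  }
  found <- character()
  for (i in seq_len(nrow(at))) {
    for (j in seq_len(nrow(lig_xyz))) {
      d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) - lig_xyz[j, ])^2))
      if (d <= cutoff) {
        found <- c(found, paste(at$chain[i], at$resno[i], sep = "|"))
        break
      }
    }
  }
  sort(unique(found))
}

region_keys <- function(region) {
  sort(unique(paste(region$residues$chain, region$residues$resno, sep = "|")))
}

# Minimum RMSD over a rotation grid (after centroid alignment): coarse
# 10-degree Euler sweep refined locally at 2 degrees.
oracle_grid_min_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_for <- function(a, b, c) {
    R <- rotation_matrix(a, "z") %*% rotation_matrix(b, "y") %*%
      rotation_matrix(c, "z")
    sqrt(mean(rowSums((Xc - Yc %*% t(R))^2)))
  }
  deg <- pi / 180
  best <- c(0, 0, 0); best_r <- Inf
  for (a in seq(0, 350, 10)) for (b in seq(0, 180, 10))
    for (c in seq(0, 350, 10)) {
      r <- rmsd_for(a * deg, b * deg, c * deg)
      if (r < best_r) { best_r <- r; best <- c(a, b, c) }
    }
  for (a in seq(best[1] - 10, best[1] + 10, 2))
    for (b in seq(best[2] - 10, best[2] + 10, 2))
      for (c in seq(best[3] - 10, best[3] + 10, 2)) {
        r <- rmsd_for(a * deg, b * deg, c * deg)
        if (r < best_r) best_r <- r
      }
  best_r
}

# All monotone pairings of positions of a (length n) with b (length m).
enumerate_monotone_pairings <- function(n, m) {
  out <- list()
  recurse <- function(i, j, pairs) {
    out[[length(out) + 1L]] <<- pairs
    if (i > n || j > m) return()
    for (ii in i:n) for (jj in j:m)
      recurse(ii + 1L, jj + 1L, rbind(pairs, c(ii, jj)))
  }
  recurse(1L, 1L, matrix(integer(), 0, 2))
  out
}

# Affine-gap global alignment score of a pairing (gap of length L costs
# open + L * extend, matching the pairwise aligner's convention).
score_pairing <- function(pairs, a, b, mat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  s <- 0
  if (nrow(pairs)) for (k in seq_len(nrow(pairs)))
    s <- s + mat[av[pairs[k, 1]], bv[pairs[k, 2]]]
  gap_cost <- function(L) if (L > 0) open + L * extend else 0
  bounds_a <- c(0, pairs[, 1], length(av) + 1L)
  bounds_b <- c(0, pairs[, 2], length(bv) + 1L)
  for (k in seq_len(length(bounds_a) - 1L)) {
    ga <- bounds_a[k + 1L] - bounds_a[k] - 1L
    gb <- bounds_b[k + 1L] - bounds_b[k] - 1L
    s <- s - gap_cost(ga) - gap_cost(gb)
  }
  s
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# A toy structure with one planted FAD-like ligand near residue 10.
toy_with_pocket <- function(n = 40, seed = 3,
                            lig = list(het_code = "FAD", anchor = 10,
                                       offset = c(4.5, 0, 0))) {
  make_toy_structure(n, ligands = list(lig), seed = seed)
}

# Deterministic additive distance matrix from a random 6-taxon tree.
random_additive_matrix <- function(seed) {
  set.seed(seed)
  tree <- ape::rtree(6, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.2, 1.5))
  tree$tip.label <- paste0("t", 1:6)
  d <- ape::cophenetic.phylo(tree)[paste0("t", 1:6), paste0("t", 1:6)]
  list(tree = tree, d = d)
}
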