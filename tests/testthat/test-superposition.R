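test_that("global alignment pairs match a brute-force affine-gap oracle", {
  aln <- align_sequences("ACDE", "ACDE")
  expect_equal(nrow(aln$pairs), 4L)
  expect_equal(aln$pairs$ref_pos, aln$pairs$mob_pos)

  # enumerate every monotone pairing of ACDE vs ACE and score it with the
  # same affine-gap convention; the aligner must reach the optimum
  pairings <- enumerate_monotone_pairings(4L, 3L)
  scores <- vapply(pairings, score_pairing, 0, a = "ACDE", b = "ACE",
                   mat = blosum62)
  best <- pairings[[which.max(scores)]]
  aln2 <- align_sequences("ACDE", "ACE")
  expect_equal(unname(as.matrix(aln2$pairs)), unname(best))
  expect_equal(aln2$score, max(scores))
  # the unmatched D is skipped
  expect_false(3L %in% aln2$pairs$ref_pos)
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("kabsch recovers planted transforms and rejects degeneracy", {
  # identity
  X <- matrix(rnorm(12), 4)
  k <- kabsch(X, X)
  expect_equal(k$rotation, diag(3), tolerance = 1e-10)
  expect_equal(k$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(k$rmsd, 0, tolerance = 1e-10)

  # 4 non-coplanar points, 90 degrees about z plus translation
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  R <- rotation_matrix(pi / 2, "z"); tr <- c(1, 2, 3)
  Q <- sweep(P %*% t(R), 2, tr, "+")
  k <- kabsch(Q, P)   # transform P onto Q
  expect_lt(max(abs(k$rotation - R)), 1e-8)
  expect_lt(max(abs(k$translation - tr)), 1e-8)
  expect_lt(k$rmsd, 1e-8)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
  L <- cbind(0:3, 0, 0)
  expect_error(kabsch(L, L), "collinear")
})

test_that("kabsch equals the rotation-grid brute-force minimum, mirrors included", {
  set.seed(11)
  for (rep in 1:3) {
    X <- matrix(rnorm(15), 5)
    Y <- matrix(rnorm(15), 5)
    k <- kabsch(X, Y)
    grid <- oracle_grid_min_rmsd(X, Y)
    expect_lte(k$rmsd, grid + 1e-9)
    expect_lt(abs(k$rmsd - grid), 0.05)  # grid resolution slack
  }
  # mirrored point set: result must stay a proper rotation
  X <- matrix(rnorm(15), 5)
  Ym <- X %*% diag(c(-1, 1, 1))
  k <- kabsch(X, Ym)
  expect_equal(det(k$rotation), 1, tolerance = 1e-8)
  expect_lt(abs(k$rmsd - oracle_grid_min_rmsd(X, Ym)), 0.05)
})

test_that("noise-free rigid copies are recovered exactly over many seeds", {
  s <- toy_with_pocket(n = 40)
  for (seed in 1:20) {
    set.seed(seed)
    ang <- runif(3, 0, 2 * pi)
    R <- rotation_matrix(ang[1], "z") %*% rotation_matrix(ang[2], "y") %*%
      rotation_matrix(ang[3], "x")
    tr <- runif(3, -20, 20)
    p <- perturb_structure(s, R, tr, seed = seed)
    sup <- superpose_structures(s, p)
    expect_lt(sup$rmsd_refined, 1e-6)
    expect_lt(max(abs(sup$rotation %*% R - diag(3))), 1e-6)
    expect_equal(sup$n_pairs_retained, 40L)
  }
})

test_that("superposition handles deletions and stays symmetric", {
  s <- toy_with_pocket(n = 50, seed = 8)
  R <- rotation_matrix(1.1, "y"); tr <- c(5, -3, 2)
  p <- perturb_structure(s, R, tr, deletion_fraction = 0.1, seed = 4)
  sup <- superpose_structures(s, p)
  expect_lt(sup$rmsd_refined, 1e-6)
  expect_equal(sup$n_pairs_initial, 45L)  # 10% of residues deleted
  # self-superposition is exact
  self <- superpose_structures(s, s)
  expect_equal(self$rmsd_refined, 0, tolerance = 1e-9)
  expect_equal(self$n_pairs_retained, 50L)
  # direction symmetry of the refined rmsd
  a <- superpose_structures(s, p)$rmsd_refined
  b <- superpose_structures(p, s)$rmsd_refined
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("outlier rejection only ever lowers the refined rmsd", {
  s <- toy_with_pocket(n = 40, seed = 5)
  p <- perturb_structure(s, diag(3), c(0, 0, 0), noise_sd = 0.15, seed = 9)
  # displace a few residues far out to create genuine outliers
  bad <- p$atoms$resno %in% c(7, 21, 33)
  p$atoms$x[bad] <- p$atoms$x[bad] + 8
  rmsds <- vapply(1:5, function(cy)
    superpose_structures(s, p, max_cycles = cy)$rmsd_refined, 0)
  expect_true(all(diff(rmsds) <= 1e-9))
  final <- superpose_structures(s, p)
  expect_lt(final$n_pairs_retained, final$n_pairs_initial)
  expect_lte(final$rmsd_refined, final$rmsd_all)
})

test_that("transforms compose with their inverse to identity", {
  s <- toy_with_pocket()
  sup <- list(rotation = rotation_matrix(0.7, "x"), translation = c(2, 1, -4))
  there <- apply_transform(s, sup)
  back <- apply_transform(there, invert_transform(
    structure(sup, class = "superposition")))
  expect_lt(max(abs(coords(back) - coords(s))), 1e-8)
  # identity transform leaves coordinates untouched
  same <- apply_transform(s, identity_superposition())
  expect_identical(coords(same), coords(s))
  # hand-computed single point
  m <- apply_transform(matrix(c(1, 0, 0), 1), list(
    rotation = rotation_matrix(pi / 2, "z"), translation = c(0, 0, 1)))
  expect_equal(m, matrix(c(0, 1, 1), 1), tolerance = 1e-12)
})

test_that("rmsd matrices are symmetric with zero diagonal and record failures", {
  s <- toy_with_pocket(n = 30, seed = 2)
  copies <- list(a = s,
                 b = perturb_structure(s, rotation_matrix(0.4), c(1, 1, 1),
                                       noise_sd = 0.2, seed = 1),
                 c = perturb_structure(s, rotation_matrix(-0.9, "x"),
                                       c(-2, 0, 5), noise_sd = 0.2, seed = 2))
  m <- rmsd_matrix(copies)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m))
  off <- m[upper.tri(m)]
  # sigma 0.2 A per coordinate: rmsd vs the clean original concentrates near
  # sigma*sqrt(3) ~ 0.35; between two independently noisy copies near
  # sigma*sqrt(6) ~ 0.49
  expect_true(all(off > 0.2 & off < 0.65))
  # a degenerate partner is recorded, not fatal
  tiny <- make_toy_structure(2, sequence = "GG")
  m2 <- rmsd_matrix(list(a = s, tiny = tiny))
  expect_true(is.na(m2["a", "tiny"]))
  expect_equal(nrow(attr(m2, "failures")), 1L)
})
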