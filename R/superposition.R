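#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment of two amino-acid sequences, used to
#' pair residues before rigid-body superposition. Scoring follows the usual
#' protein defaults: BLOSUM62 with gap open 10 and gap extend 0.5. Letters
#' outside the BLOSUM62 alphabet are scored as `X`.
#'
#' @param seq_a,seq_b One-letter amino-acid strings (reference, mobile).
#' @param substitution_matrix Name of a Biostrings substitution matrix.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A `pairwise_alignment`: list with `pairs` (data frame of matched
#'   `ref_pos`, `mob_pos`, strictly increasing in both), `score`, `params`.
#' @export
align_sequences <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  mat <- .subst_matrix(substitution_matrix)
  clean <- function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    v[!v %in% rownames(mat)] <- "X"
    paste(v, collapse = "")
  }
  pa <- Biostrings::pairwiseAlignment(
    clean(seq_a), clean(seq_b), type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- 0L; ib <- 0L
  ref_pos <- integer(); mob_pos <- integer()
  for (k in seq_along(ga)) {
    if (ga[k] != "-") ia <- ia + 1L
    if (gb[k] != "-") ib <- ib + 1L
    if (ga[k] != "-" && gb[k] != "-") {
      ref_pos <- c(ref_pos, ia); mob_pos <- c(mob_pos, ib)
    }
  }
  structure(list(
    pairs = data.frame(ref_pos = ref_pos, mob_pos = mob_pos),
    score = as.numeric(Biostrings::score(pa)),
    params = list(substitution_matrix = substitution_matrix,
                  gap_open = gap_open, gap_extend = gap_extend)),
    class = "pairwise_alignment")
}

.subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping the mobile
#' point set onto the reference, by singular value decomposition of the
#' cross-covariance matrix with reflection correction. The returned
#' transform is `x_fit = R x_mob + t`.
#'
#' @param coords_ref,coords_mob n x 3 matrices of paired coordinates.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` (post-fit, Angstrom).
#' @export
kabsch <- function(coords_ref, coords_mob) {
  X <- as.matrix(coords_ref); Y <- as.matrix(coords_mob)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 point pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (qr(Xc)$rank < 2L || qr(Yc)$rank < 2L)
    stop("degenerate (collinear) point set")
  H <- t(Yc) %*% Xc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cx - R %*% cy)
  fit <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xc - fit)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

.backbone_atoms <- c("N", "CA", "C", "O")

.chain_backbone <- function(structure, chain_id, atom_set) {
  at <- structure$atoms
  at <- at[at$chain == chain_id & !at$het & at$atom %in% atom_set, ,
           drop = FALSE]
  at
}

#' Superpose two structures guided by sequence alignment
#'
#' Pairs residues of the two structures' chains by global sequence alignment,
#' fits backbone atoms (N, CA, C, O present in both partners) with the
#' Kabsch algorithm, then iteratively rejects outlier residue pairs whose
#' backbone deviation exceeds `max(2.0, 2 x current RMSD)` Angstrom, for at
#' most `max_cycles` cycles or until no pair is dropped. Mirrors the default
#' refinement behaviour of interactive superposition tools.
#'
#' @param ref,mobile `structure3d` objects.
#' @param ref_chain,mob_chain Chain ids; default the first polymer chain.
#' @param fit_atoms `"backbone"` (N, CA, C, O) or `"CA"`.
#' @param max_cycles Maximum outlier-rejection cycles (default 5).
#' @param reject_min Deviation floor for rejection in Angstrom (default 2.0).
#' @return A `superposition` object: `rotation`, `translation` (mobile into
#'   reference frame), `rmsd_refined` (over retained pairs), `rmsd_all`
#'   (over all initially paired atoms), `n_pairs_initial`,
#'   `n_pairs_retained`, `cycles_run`, and the residue `pairs` table with a
#'   `retained` flag.
#' @export
superpose_structures <- function(ref, mobile,
                                 ref_chain = NULL, mob_chain = NULL,
                                 fit_atoms = c("backbone", "CA"),
                                 max_cycles = 5L, reject_min = 2.0) {
  fit_atoms <- match.arg(fit_atoms)
  atom_set <- if (fit_atoms == "backbone") .backbone_atoms else "CA"
  if (is.null(ref_chain)) ref_chain <- first_polymer_chain(ref)
  if (is.null(mob_chain)) mob_chain <- first_polymer_chain(mobile)
  sr <- extract_chain_sequence(ref, ref_chain)
  sm <- extract_chain_sequence(mobile, mob_chain)
  aln <- align_sequences(sr$sequence, sm$sequence)
  pr <- aln$pairs
  if (nrow(pr) < 3L) stop("fewer than 3 aligned residue pairs")

  ra <- .chain_backbone(ref, ref_chain, atom_set)
  ma <- .chain_backbone(mobile, mob_chain, atom_set)
  rkey <- paste(ra$resno, ifelse(is.na(ra$insert), "", ra$insert), ra$atom)
  mkey <- paste(ma$resno, ifelse(is.na(ma$insert), "", ma$insert), ma$atom)

  # per aligned residue pair, collect backbone atoms present on both sides
  pair_rows <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    rres <- sr$numbering_map[pr$ref_pos[i]]
    rins <- sr$insert_codes[pr$ref_pos[i]]
    mres <- sm$numbering_map[pr$mob_pos[i]]
    mins <- sm$insert_codes[pr$mob_pos[i]]
    common <- intersect(
      ra$atom[ra$resno == rres &
                ifelse(is.na(ra$insert), "", ra$insert) ==
                ifelse(is.na(rins), "", rins)],
      ma$atom[ma$resno == mres &
                ifelse(is.na(ma$insert), "", ma$insert) ==
                ifelse(is.na(mins), "", mins)])
    if (!length(common)) next
    ri <- match(paste(rres, ifelse(is.na(rins), "", rins), common), rkey)
    mi <- match(paste(mres, ifelse(is.na(mins), "", mins), common), mkey)
    pair_rows[[i]] <- data.frame(pair = i, ref_row = ri, mob_row = mi)
  }
  pair_atoms <- do.call(rbind, pair_rows)
  if (is.null(pair_atoms) || length(unique(pair_atoms$pair)) < 3L)
    stop("fewer than 3 residue pairs with usable fit atoms")

  X <- as.matrix(ra[pair_atoms$ref_row, c("x", "y", "z")])
  Y <- as.matrix(ma[pair_atoms$mob_row, c("x", "y", "z")])
  pair_id <- pair_atoms$pair
  initial_pairs <- unique(pair_id)

  retained <- initial_pairs
  cycles <- 0L
  fit <- NULL
  repeat {
    sel <- pair_id %in% retained
    fit <- kabsch(X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
    cycles <- cycles + 1L
    if (cycles > max_cycles) { cycles <- max_cycles; break }
    Yt <- sweep(Y %*% t(fit$rotation), 2, fit$translation, "+")
    dev2 <- rowSums((X - Yt)^2)
    res_dev <- sqrt(tapply(dev2[sel], pair_id[sel], mean))
    cut <- max(reject_min, 2 * fit$rmsd)
    drop_ids <- as.integer(names(res_dev)[res_dev > cut])
    if (!length(drop_ids) || length(retained) - length(drop_ids) < 3L) break
    retained <- setdiff(retained, drop_ids)
  }
  Yt <- sweep(Y %*% t(fit$rotation), 2, fit$translation, "+")
  rmsd_all <- sqrt(mean(rowSums((X - Yt)^2)))

  pairs_tab <- data.frame(
    ref_resno = sr$numbering_map[pr$ref_pos],
    mob_resno = sm$numbering_map[pr$mob_pos],
    retained = seq_len(nrow(pr)) %in% retained &
      seq_len(nrow(pr)) %in% initial_pairs)
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd_refined = fit$rmsd, rmsd_all = rmsd_all,
    n_pairs_initial = length(initial_pairs),
    n_pairs_retained = length(retained),
    cycles_run = cycles,
    ref_id = ref$id, mobile_id = mobile$id,
    ref_chain = ref_chain, mob_chain = mob_chain,
    fit_atoms = fit_atoms,
    pairs = pairs_tab), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "superposition %s -> %s: rmsd_refined %.3f A (%d/%d pairs, %d cycle(s)); rmsd_all %.3f A\n",
    x$mobile_id, x$ref_id, x$rmsd_refined, x$n_pairs_retained,
    x$n_pairs_initial, x$cycles_run, x$rmsd_all))
  invisible(x)
}

#' Identity superposition
#' @return A `superposition` with identity rotation and zero translation.
#' @export
identity_superposition <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 rmsd_refined = 0, rmsd_all = 0,
                 n_pairs_initial = 0L, n_pairs_retained = 0L,
                 cycles_run = 0L, ref_id = NA, mobile_id = NA,
                 ref_chain = NA, mob_chain = NA, fit_atoms = NA,
                 pairs = NULL), class = "superposition")
}

#' Invert a superposition
#' @param superposition A `superposition` object.
#' @return The inverse transform as a `superposition`.
#' @export
invert_transform <- function(superposition) {
  R <- t(superposition$rotation)
  out <- superposition
  out$rotation <- R
  out$translation <- as.numeric(-R %*% superposition$translation)
  tmp <- out$ref_id; out$ref_id <- out$mobile_id; out$mobile_id <- tmp
  out
}

#' Apply a rigid transform to a structure or ligand
#'
#' Maps every coordinate `x` to `R x + t` using the rotation/translation of
#' a [superpose_structures()] result (or any list with `rotation` and
#' `translation`).
#'
#' @param x A `structure3d`, `ligand_instance`, or n x 3 matrix.
#' @param superposition A `superposition` object.
#' @return A transformed copy of `x`.
#' @export
apply_transform <- function(x, superposition) {
  R <- superposition$rotation; tr <- superposition$translation
  tf <- function(m) sweep(m %*% t(R), 2, tr, "+")
  if (is.matrix(x)) return(tf(x))
  if (inherits(x, "structure3d") || inherits(x, "ligand_instance")) {
    m <- tf(as.matrix(x$atoms[, c("x", "y", "z")]))
    x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
    return(x)
  }
  stop("cannot transform object of class ", paste(class(x), collapse = "/"))
}

#' Pairwise RMSD matrix over a structure set
#'
#' Runs [superpose_structures()] for each pair and tabulates
#' `rmsd_refined`. A failing pair is recorded as `NA` with its reason in the
#' `failures` attribute rather than aborting the whole matrix.
#'
#' @param structures Named list of `structure3d` objects (names default to
#'   structure ids).
#' @param reference Optional id: compute only the column against this
#'   reference.
#' @param ... Passed to [superpose_structures()].
#' @return Numeric matrix of refined RMSDs (Angstrom), zero diagonal;
#'   attribute `failures` is a data frame of failed pairs and reasons.
#' @export
rmsd_matrix <- function(structures, reference = NULL, ...) {
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    names(structures) <- vapply(structures, function(s) s$id, "")
  ids <- names(structures)
  if (length(ids) < 2L) stop("need at least 2 structures")
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  fails <- data.frame(ref = character(), mobile = character(),
                      reason = character())
  cols <- if (is.null(reference)) ids else reference
  for (a in cols) for (b in ids) {
    if (a == b || !is.na(m[a, b])) next
    if (is.null(reference) && match(a, ids) > match(b, ids)) next
    r <- tryCatch(superpose_structures(structures[[a]], structures[[b]], ...),
                  error = function(e) e)
    if (inherits(r, "error")) {
      fails <- rbind(fails, data.frame(ref = a, mobile = b,
                                       reason = conditionMessage(r)))
    } else {
      m[a, b] <- r$rmsd_refined
      if (is.null(reference)) m[b, a] <- r$rmsd_refined
    }
  }
  if (!is.null(reference)) m <- m[, reference, drop = FALSE]
  attr(m, "failures") <- fails
  m
}
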