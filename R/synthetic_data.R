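#' Rotation matrix about a coordinate axis
#' @param angle Rotation angle in radians.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(angle, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  switch(axis,
         z = matrix(c(c0, -s0, 0, s0, c0, 0, 0, 0, 1), 3, byrow = TRUE),
         x = matrix(c(1, 0, 0, 0, c0, -s0, 0, s0, c0), 3, byrow = TRUE),
         y = matrix(c(c0, 0, s0, 0, 1, 0, -s0, 0, c0), 3, byrow = TRUE))
}

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a toy protein structure on an idealized helix
#'
#' Deterministic generator of test structures: CA atoms lie on an idealized
#' helix (rise 1.5 Angstrom, 100 degree twist, radius 2.3 Angstrom) with
#' N, C, O backbone atoms at fixed local offsets, so all pocket geometry is
#' computable in closed form. Ligands are planted as heteroresidues at
#' exact offsets from anchor CA atoms. No physical realism is claimed
#' beyond sane interatomic distances.
#'
#' @param n_residues Number of polymer residues.
#' @param sequence Optional one-letter sequence (default: random under
#'   `seed`).
#' @param ligands List of ligand specs: each a list with `het_code`,
#'   `anchor` (residue index, 1-based), `offset` (3-vector, Angstrom,
#'   relative to the anchor CA), and optionally `atom_offsets` (matrix of
#'   additional atom offsets relative to the ligand origin).
#' @param numbering_offset Added to 1..n to form author numbers.
#' @param chain Chain identifier (default `"A"`).
#' @param seed Integer seed controlling the random sequence.
#' @return A `structure3d`; errors if any two atoms fall closer than
#'   1 Angstrom.
#' @export
make_toy_structure <- function(n_residues, sequence = NULL, ligands = list(),
                               numbering_offset = 0L, chain = "A", seed = 1L) {
  stopifnot(n_residues >= 1L)
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(.AA1, n_residues, replace = TRUE), collapse = "")
  }
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) != n_residues)
    stop("sequence length does not match n_residues")
  res3 <- bio3d::aa123(letters1)
  theta <- (seq_len(n_residues) - 1L) * 100 * pi / 180
  radius <- 2.3; rise <- 1.5
  ca <- cbind(radius * cos(theta), radius * sin(theta),
              rise * seq_len(n_residues))
  radial <- cbind(cos(theta), sin(theta), 0)
  rows <- list()
  for (i in seq_len(n_residues)) {
    resno <- i + numbering_offset
    xyz <- rbind(N = ca[i, ] + c(0, 0, -1.2),
                 CA = ca[i, ],
                 C = ca[i, ] + c(0, 0, 1.2),
                 O = ca[i, ] + 1.3 * radial[i, ] + c(0, 0, 1.2))
    rows[[i]] <- data.frame(
      chain = chain, resno = resno, insert = NA_character_,
      resname = res3[i], atom = rownames(xyz),
      element = c("N", "C", "C", "O"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }
  lig_no <- n_residues + numbering_offset
  for (ls in ligands) {
    lig_no <- lig_no + 1L
    stopifnot(!is.null(ls$het_code), !is.null(ls$anchor), !is.null(ls$offset))
    origin <- ca[ls$anchor, ] + ls$offset
    offs <- rbind(c(0, 0, 0))
    if (!is.null(ls$atom_offsets)) offs <- rbind(offs, ls$atom_offsets)
    xyz <- sweep(offs, 2, origin, "+")
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain, resno = lig_no, insert = NA_character_,
      resname = ls$het_code,
      atom = paste0("C", seq_len(nrow(xyz))),
      element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, het = TRUE, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (nrow(xyz) > 1L) {
    d2 <- .dist2(xyz, xyz); diag(d2) <- Inf
    if (min(d2) < 1)
      stop("overlapping atoms: minimum interatomic distance ",
           sprintf("%.2f", sqrt(max(0, min(d2)))), " A < 1 A")
  }
  new_structure3d(at, id = sprintf("toy%02d", seed), source_format = "memory")
}

#' Rigidly transform and degrade a structure
#'
#' Applies a planted rotation/translation, adds isotropic Gaussian
#' coordinate noise, and deletes a fraction of polymer residues uniformly
#' at random. The planted transform is recorded in the
#' `planted_transform` attribute so downstream tests can close the loop.
#'
#' @param structure A `structure3d`.
#' @param rotation 3 x 3 proper rotation (default identity).
#' @param translation 3-vector (default zero).
#' @param noise_sd Per-coordinate Gaussian noise SD in Angstrom.
#' @param deletion_fraction Fraction of polymer residues to delete, in
#'   `[0, 1)`.
#' @param seed Integer seed for noise and deletions.
#' @return A transformed `structure3d` copy.
#' @export
perturb_structure <- function(structure, rotation = diag(3),
                              translation = c(0, 0, 0), noise_sd = 0,
                              deletion_fraction = 0, seed = 1L) {
  if (deletion_fraction >= 1) stop("deletion_fraction must be < 1")
  set.seed(seed)
  at <- structure$atoms
  if (deletion_fraction > 0) {
    polymer_keys <- unique(.residue_key(at[!at$het, , drop = FALSE]))
    n_del <- floor(deletion_fraction * length(polymer_keys))
    if (n_del > 0) {
      drop_keys <- sample(polymer_keys, n_del)
      at <- at[!(.residue_key(at) %in% drop_keys), , drop = FALSE]
    }
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  if (noise_sd > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd), ncol = 3)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  out <- new_structure3d(at, id = paste0(structure$id, "_pert"),
                         source_format = "memory")
  attr(out, "planted_transform") <- list(rotation = rotation,
                                         translation = translation)
  out
}

#' Generate a synthetic MSA with planted conserved blocks
#'
#' Background columns are uniform over the 20 amino acids with independent
#' gaps at `gap_rate`; planted blocks carry a (possibly per-taxon)
#' consensus with a controlled mutation rate and no gaps. Mutations are
#' planted at an exact per-column count (`round(mutation_rate * n)`
#' sequences mutated per block column), so a block's per-column
#' conservation is exactly `1 - mutation_rate` up to rounding and the
#' default motif detector recovers planted spans deterministically for
#' rates at or below 0.1.
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param blocks List of block specs: `span` (inclusive column pair),
#'   `consensus` (single string, or named character vector per taxon, each
#'   of the span's length), `mutation_rate` (default 0).
#' @param taxa Character vector of taxon labels per sequence (default one
#'   taxon `"taxonA"`).
#' @param gap_rate Background gap probability (default 0.05).
#' @param seed Integer seed.
#' @return List with `msa` (taxon labels attached), `block_spans` (matrix),
#'   and `taxa`.
#' @export
make_synthetic_msa <- function(n_sequences = 20L, n_columns = 200L,
                               blocks = list(), taxa = NULL,
                               gap_rate = 0.05, seed = 1L) {
  if (is.null(taxa)) taxa <- rep("taxonA", n_sequences)
  stopifnot(length(taxa) == n_sequences)
  spans <- do.call(rbind, lapply(blocks, function(b) b$span))
  if (!is.null(spans)) {
    ord <- order(spans[, 1])
    spans <- spans[ord, , drop = FALSE]
    blocks <- blocks[ord]
    if (any(spans[, 2] < spans[, 1]) || any(spans < 1) ||
        any(spans > n_columns))
      stop("block span out of range")
    if (nrow(spans) > 1L &&
        any(spans[-1, 1] <= spans[-nrow(spans), 2]))
      stop("overlapping blocks")
  }
  set.seed(seed)
  m <- matrix(sample(.AA1, n_sequences * n_columns, replace = TRUE),
              n_sequences, n_columns)
  gaps <- matrix(stats::runif(n_sequences * n_columns) < gap_rate,
                 n_sequences, n_columns)
  m[gaps] <- "-"
  for (b in blocks) {
    s <- b$span[1]; e <- b$span[2]; L <- e - s + 1L
    rate <- if (is.null(b$mutation_rate)) 0 else b$mutation_rate
    cons <- b$consensus
    if (length(cons) == 1L && is.null(names(cons)))
      cons <- stats::setNames(rep(cons, length(unique(taxa))), unique(taxa))
    for (tx in unique(taxa)) {
      rows <- which(taxa == tx)
      cstr <- strsplit(cons[[tx]], "")[[1]]
      if (length(cstr) != L)
        stop("consensus length != span length for block at ", s)
      for (j in seq_len(L)) m[rows, s + j - 1L] <- cstr[j]
    }
    n_mut <- round(rate * n_sequences)
    if (n_mut > 0) for (j in s:e) {
      victims <- sample.int(n_sequences, n_mut)
      for (v in victims) {
        cur <- m[v, j]
        m[v, j] <- sample(setdiff(.AA1, cur), 1L)
      }
    }
  }
  ids <- sprintf("seq%03d", seq_len(n_sequences))
  msa <- new_msa(ids, apply(m, 1, paste, collapse = ""), taxa = taxa)
  list(msa = msa, block_spans = spans,
       taxa = stats::setNames(taxa, ids))
}

#' Generate a synthetic homology-hit table with ground truth
#'
#' Records are drawn on both sides of each retention threshold so the
#' filter's kept set can be checked exactly against planted labels. With
#' `include_boundary`, three records sit exactly on the three thresholds
#' (and are therefore rejected under the strict inequalities).
#'
#' @param n_records Number of records.
#' @param fraction_passing Fraction planted to pass all criteria.
#' @param seed Integer seed.
#' @param path Optional file path; when given, a 13-column tab-separated
#'   hit file (with query-coverage column) is written.
#' @param include_boundary Plant exact-threshold records (default TRUE).
#' @return List with `records` (data frame as from [parse_hits()]),
#'   `truth` (logical vector), and `path` (or `NULL`).
#' @export
make_hit_table <- function(n_records = 100L, fraction_passing = 0.5,
                           seed = 1L, path = NULL, include_boundary = TRUE) {
  stopifnot(fraction_passing >= 0, fraction_passing <= 1)
  set.seed(seed)
  n_pass <- round(fraction_passing * n_records)
  n_fail <- n_records - n_pass
  mk <- function(n, evalue, cov, id) {
    if (n == 0L) return(NULL)
    alen <- sample(100:500, n, replace = TRUE)
    data.frame(query_id = "query1",
               subject_id = sprintf("subj%04d", seq_len(n)),
               percent_identity = round(id, 2),
               alignment_length = alen,
               mismatches = sample(0:50, n, replace = TRUE),
               gap_opens = sample(0:5, n, replace = TRUE),
               q_start = 1L, q_end = alen,
               s_start = 1L, s_end = alen,
               evalue = evalue,
               bitscore = round(stats::runif(n, 50, 900), 1),
               query_coverage = round(cov, 2),
               stringsAsFactors = FALSE)
  }
  pass <- mk(n_pass,
             evalue = 10^-stats::runif(n_pass, 26, 60),
             cov = stats::runif(n_pass, 70.5, 100),
             id = stats::runif(n_pass, 30.5, 95))
  # each failing record violates a random non-empty subset of criteria
  viol <- replicate(n_fail, {
    v <- stats::runif(3) < 0.5
    if (!any(v)) v[sample.int(3, 1)] <- TRUE
    v
  })
  fail <- mk(n_fail,
             evalue = ifelse(viol[1, ], 10^-stats::runif(n_fail, 0, 24.5),
                             10^-stats::runif(n_fail, 26, 60)),
             cov = ifelse(viol[2, ], stats::runif(n_fail, 5, 69.5),
                          stats::runif(n_fail, 70.5, 100)),
             id = ifelse(viol[3, ], stats::runif(n_fail, 5, 29.5),
                         stats::runif(n_fail, 30.5, 95)))
  truth <- c(rep(TRUE, n_pass), rep(FALSE, n_fail))
  records <- rbind(pass, fail)
  if (include_boundary) {
    b <- mk(3L, evalue = c(1e-25, 1e-30, 1e-30), cov = c(80, 70, 80),
            id = c(40, 40, 30))
    b$subject_id <- sprintf("boundary%d", 1:3)
    records <- rbind(records, b)
    truth <- c(truth, rep(FALSE, 3L))
  }
  records$subject_id <- make.unique(records$subject_id)
  if (!is.null(path)) {
    utils::write.table(
      records[, c(.HIT_COLS, "query_coverage")], path, sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(records = records, truth = truth, path = path)
}

# md5 of the packaged structure catalogue; guards against silent edits.
.TABLE1_MD5 <- "8f01910ea4a735f9040d74451f1882f1"

#' The packaged catalogue of investigated crystallized structures
#'
#' Machine-readable transcription of the 49-entry structure catalogue used
#' throughout the comparative analysis: PDB id, structural group, functional
#' annotation, residue count, organism, crystallized cofactors and
#' inhibitors, and the published backbone RMSD of each entry against the
#' three query structures (4bur, 5kmr, 4g73). `n.a.` cells are preserved as
#' printed; the alternative RMSD values quoted for the three query pairs in
#' a figure caption of the source analysis are carried in the
#' `caption_rmsd` attribute rather than overwriting the table cells.
#'
#' @param path Optional override path (default: the packaged fixture).
#' @return Data frame of 49 rows; attributes `caption_rmsd`.
#' @export
table1_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1.tsv", package = "flavocompare")
  if (!nzchar(path) || !file.exists(path))
    stop("structure catalogue fixture not found")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .TABLE1_MD5))
    stop("structure catalogue checksum mismatch (", md5, "): file edited?")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("n.a.", "n.a", "n..a."))
  attr(df, "caption_rmsd") <- data.frame(
    pair = c("4bur-4g73", "4bur-5kmr", "4g73-5kmr"),
    rmsd = c(2.891, 1.891, 1.384))
  df
}

#' Summary counts over the structure catalogue
#'
#' @param df Data frame from [table1_fixture()].
#' @return Named list: total row count, per-group counts, and the number of
#'   rows whose cofactor/inhibitor annotations include FAD, a UQ-like
#'   ligand (ubiquinone analogues, decylubiquinone, stigmatellin), or CoA.
#' @export
table1_counts <- function(df = table1_fixture()) {
  toks <- function(x) {
    x[is.na(x)] <- ""
    lapply(strsplit(x, "[/,]"), function(v) toupper(trimws(v)))
  }
  cof <- toks(df$cofactors); inh <- toks(df$inhibitors)
  both <- mapply(c, cof, inh, SIMPLIFY = FALSE)
  uq_codes <- c("UQ5", "UQ1", "UQ2", "UQ6", "DCQ", "STIGMATELLIN")
  has <- function(sets, codes) vapply(sets, function(v) any(v %in% codes), TRUE)
  list(n_structures = nrow(df),
       groups = as.list(table(df$group)),
       n_fad = sum(has(cof, "FAD")),
       n_uq_like = sum(has(both, uq_codes)),
       n_coa = sum(has(cof, "COA")))
}
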