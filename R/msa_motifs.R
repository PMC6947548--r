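#' Construct an MSA object
#'
#' @param ids Character vector of unique record ids.
#' @param seqs Character vector of gapped sequences (equal lengths; gaps
#'   `-`).
#' @param taxa Optional character vector of taxon labels, same length.
#' @return An object of class `msa`: list with `ids`, `seqs` (named),
#'   `taxa` (named, possibly `NA`), `n`, `length`.
#' @export
new_msa <- function(ids, seqs, taxa = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(gsub("\\.", "-", as.character(seqs)))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment: sequence lengths ",
                            paste(sort(L), collapse = ", "))
  names(seqs) <- ids
  if (is.null(taxa)) taxa <- rep(NA_character_, length(ids))
  taxa <- as.character(taxa); names(taxa) <- ids
  structure(list(ids = ids, seqs = seqs, taxa = taxa,
                 n = length(ids), length = L), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (%d with taxon labels)\n",
              x$n, x$length, sum(!is.na(x$taxa))))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' FASTA or Clustal format, via Biostrings. Record ids are FASTA headers
#' truncated at the first whitespace. Taxon labels can be attached from a
#' sidecar tab-separated file mapping record id to taxon (FASTA headers are
#' too free-form to parse reliably).
#'
#' @param path Alignment file.
#' @param format `"fasta"`, `"clustal"`, or `NULL` to guess from content.
#' @param taxa_tsv Optional two-column TSV (id, taxon), no header.
#' @return An `msa` object.
#' @export
read_alignment <- function(path, format = NULL, taxa_tsv = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    head <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(trimws(head), ">")) "fasta" else "clustal"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  ids <- sub("\\s.*$", "", names(seqs))
  msa <- new_msa(ids, unname(seqs))
  if (!is.null(taxa_tsv)) {
    tt <- utils::read.table(taxa_tsv, sep = "\t", header = FALSE,
                            col.names = c("id", "taxon"),
                            stringsAsFactors = FALSE)
    msa$taxa[tt$id] <- tt$taxon
  }
  msa
}

#' Write an MSA to FASTA
#' @param msa An `msa` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(msa, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in msa$ids)
    cat(">", id, "\n", msa$seqs[[id]], "\n", sep = "", file = con)
  invisible(path)
}

.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$seqs), ""))
}

#' Per-column conservation profile
#'
#' For each alignment column: the modal residue among non-gap entries, the
#' conservation (fraction of non-gap residues equal to the mode), and the
#' gap fraction. An all-gap column has conservation 0, gap fraction 1 and
#' an `NA` mode. Modal ties resolve to the alphabetically first residue.
#'
#' @param msa An `msa` object with at least 2 sequences.
#' @return Data frame: `column` (1-based), `modal_residue`, `conservation`,
#'   `gap_fraction`.
#' @export
column_conservation <- function(msa) {
  if (msa$n < 2L) stop("need at least 2 sequences")
  m <- .msa_matrix(msa)
  profile_one <- function(col) {
    gaps <- col == "-"
    ng <- col[!gaps]
    if (!length(ng))
      return(list(mode = NA_character_, cons = 0, gapf = 1))
    tab <- table(ng)
    mx <- max(tab)
    mode <- sort(names(tab)[tab == mx])[1]
    list(mode = mode, cons = mx / length(ng), gapf = mean(gaps))
  }
  prof <- apply(m, 2, profile_one)
  data.frame(column = seq_len(ncol(m)),
             modal_residue = vapply(prof, `[[`, "", "mode"),
             conservation = vapply(prof, `[[`, 0, "cons"),
             gap_fraction = vapply(prof, `[[`, 0, "gapf"))
}

#' Detect conserved motifs in an MSA
#'
#' A motif is a maximal run of alignment columns that each satisfy
#' `conservation >= conservation_threshold` and
#' `gap_fraction <= max_gap_fraction`, with run length at least `min_len`.
#' Hits are ordered by start column and are disjoint by construction.
#'
#' @param msa An `msa` object.
#' @param min_len Minimum motif length in columns (default 5).
#' @param conservation_threshold Per-column conservation floor (default
#'   0.8).
#' @param max_gap_fraction Per-column gap ceiling (default 0.2).
#' @return List of `motif_hit` objects: `span` (inclusive column range),
#'   `consensus` (modal string), `mean_conservation`, and
#'   `per_sequence_span` (start/end in each sequence's own 1-based
#'   ungapped coordinates; `NA` when the sequence is all-gap in the span).
#' @export
detect_motifs <- function(msa, min_len = 5L, conservation_threshold = 0.8,
                          max_gap_fraction = 0.2) {
  prof <- column_conservation(msa)
  ok <- prof$conservation >= conservation_threshold &
    prof$gap_fraction <= max_gap_fraction
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hits <- list()
  m <- .msa_matrix(msa)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < min_len) next
    s <- starts[i]; e <- ends[i]
    spans <- t(vapply(seq_len(msa$n), function(r) {
      row <- m[r, ]
      before <- sum(row[seq_len(s - 1L)] != "-")
      inside <- sum(row[s:e] != "-")
      if (inside == 0L) return(c(NA_integer_, NA_integer_))
      c(before + 1L, before + inside)
    }, integer(2)))
    hit <- structure(list(
      span = c(start = s, end = e),
      consensus = paste(prof$modal_residue[s:e], collapse = ""),
      mean_conservation = mean(prof$conservation[s:e]),
      per_sequence_span = data.frame(id = msa$ids,
                                     start = spans[, 1], end = spans[, 2])),
      class = "motif_hit")
    hits[[length(hits) + 1L]] <- hit
  }
  hits
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("motif %d-%s-%d (mean conservation %.2f)\n",
              x$span["start"], x$consensus, x$span["end"],
              x$mean_conservation))
  invisible(x)
}

#' Taxon-stratified consensus of a motif
#'
#' Modal residue per column within each taxon group over the motif span.
#' Ties resolve to the alphabetically first residue and are flagged.
#'
#' @param msa An `msa` object; every record must carry a taxon label
#'   (either in the MSA or via `taxa`).
#' @param hit A `motif_hit` from [detect_motifs()].
#' @param taxa Optional named character vector overriding `msa$taxa`.
#' @return Named list: taxon -> list(`consensus`, `ties` logical vector).
#' @export
taxon_consensus <- function(msa, hit, taxa = NULL) {
  if (is.null(taxa)) taxa <- msa$taxa
  taxa <- taxa[msa$ids]
  if (any(is.na(taxa)))
    stop("unlabeled records: ", paste(msa$ids[is.na(taxa)], collapse = ", "))
  m <- .msa_matrix(msa)
  s <- hit$span["start"]; e <- hit$span["end"]
  out <- list()
  for (tx in unique(taxa)) {
    sub <- m[taxa == tx, s:e, drop = FALSE]
    cons <- character(ncol(sub)); tie <- logical(ncol(sub))
    for (j in seq_len(ncol(sub))) {
      col <- sub[, j]; col <- col[col != "-"]
      if (!length(col)) { cons[j] <- "-"; next }
      tab <- table(col)
      win <- sort(names(tab)[tab == max(tab)])
      cons[j] <- win[1]
      tie[j] <- length(win) > 1L
    }
    out[[tx]] <- list(consensus = paste(cons, collapse = ""), ties = tie)
  }
  out
}

#' Map a motif onto structure residue numbering
#'
#' Converts a motif's span in one MSA record into author-numbered residues
#' of a structure chain, via the chain's numbering map. The chain sequence
#' must match the record's ungapped sequence up to a constant numbering
#' offset (e.g. a construct starting at a different residue). Positions
#' falling outside the crystallized (coordinate-bearing) part of the chain
#' are flagged unmapped.
#'
#' @param hit A `motif_hit`.
#' @param msa The `msa` the hit came from.
#' @param seq_id Record id within the MSA.
#' @param structure A `structure3d`.
#' @param chain_id Chain identifier (default: first polymer chain).
#' @return Data frame: `seq_pos` (record's own 1-based position), `letter`
#'   (motif letter in that record), `author_number`, `residue_name`,
#'   `mapped` (logical).
#' @export
motif_to_structure <- function(hit, msa, seq_id, structure,
                               chain_id = NULL) {
  if (!seq_id %in% msa$ids) stop("record '", seq_id, "' not in MSA")
  if (is.null(chain_id)) chain_id <- first_polymer_chain(structure)
  cs <- extract_chain_sequence(structure, chain_id)
  span <- hit$per_sequence_span
  row <- span[span$id == seq_id, ]
  if (is.na(row$start))
    stop("record '", seq_id, "' is all-gap within the motif span")
  gapped <- strsplit(msa$seqs[[seq_id]], "")[[1]]
  ungapped <- gapped[gapped != "-"]
  off <- .constant_offset(paste(ungapped, collapse = ""), cs$sequence)
  pos <- row$start:row$end
  chain_idx <- pos - off
  mapped <- chain_idx >= 1 & chain_idx <= length(cs$numbering_map)
  resnames <- rep(NA_character_, length(pos))
  authors <- rep(NA_integer_, length(pos))
  if (any(mapped)) {
    authors[mapped] <- cs$numbering_map[chain_idx[mapped]]
    chainvec <- strsplit(cs$sequence, "")[[1]]
    # report the 3-letter residue name from the structure
    at <- structure$atoms[structure$atoms$chain == chain_id &
                            !structure$atoms$het, , drop = FALSE]
    resnames[mapped] <- at$resname[match(authors[mapped], at$resno)]
    # consistency: structure letters must equal the record's letters
    mismatch <- which(mapped &
                        chainvec[chain_idx] != ungapped[pos] &
                        chainvec[chain_idx] != "X")
    if (length(mismatch))
      stop("sequence/chain mismatch at motif position(s) ",
           paste(pos[mismatch], collapse = ", "),
           " (record letters ", paste(ungapped[pos[mismatch]], collapse = ""),
           " vs chain ", paste(chainvec[chain_idx[mismatch]], collapse = ""),
           ")")
  }
  data.frame(seq_pos = pos, letter = ungapped[pos],
             author_number = authors, residue_name = resnames,
             mapped = mapped)
}
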