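.HIT_COLS <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")

#' Parse a tabular homology-search hit file
#'
#' Reads the standard 12-column tab-separated hit dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score), optionally with an
#' extra 13th query-coverage column.
#'
#' @param path Hit file; comment lines starting `#` are ignored.
#' @param has_query_coverage The file carries a 13th `qcovs`-style column.
#' @return Data frame of hit records; `query_coverage` is `NA` unless the
#'   13th column is present.
#' @export
parse_hits <- function(path, has_query_coverage = FALSE) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  ncols <- 12L + as.integer(has_query_coverage)
  empty <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(.HIT_COLS)), .HIT_COLS))
  empty$query_id <- character(0); empty$subject_id <- character(0)
  empty$query_coverage <- numeric(0)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != ncols)
  if (length(bad))
    stop("malformed hit line ", bad[1], ": expected ", ncols,
         " tab-separated fields, got ", length(parts[[bad[1]]]))
  m <- do.call(rbind, parts)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    percent_identity = as.numeric(m[, 3]),
                    alignment_length = as.integer(m[, 4]),
                    mismatches = as.integer(m[, 5]),
                    gap_opens = as.integer(m[, 6]),
                    q_start = as.integer(m[, 7]),
                    q_end = as.integer(m[, 8]),
                    s_start = as.integer(m[, 9]),
                    s_end = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]),
                    query_coverage = if (has_query_coverage)
                      as.numeric(m[, 13]) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(is.na(out$evalue)) || any(out$evalue < 0))
    stop("invalid E-value in hit file")
  out
}

#' Homolog-retention criteria
#'
#' The sampling thresholds used when collecting homologous sequences:
#' E-value strictly lower than `max_evalue`, query coverage strictly higher
#' than `min_query_coverage` percent, and percent identity strictly greater
#' than `min_percent_identity`. All three inequalities are strict, so a
#' record sitting exactly on a threshold is rejected.
#'
#' @param max_evalue Exclusive E-value ceiling (default `1e-25`).
#' @param min_query_coverage Exclusive coverage floor in percent (default
#'   70).
#' @param min_percent_identity Exclusive identity floor in percent (default
#'   30).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(max_evalue = 1e-25, min_query_coverage = 70,
                            min_percent_identity = 30) {
  stopifnot(max_evalue >= 0,
            min_query_coverage >= 0, min_query_coverage <= 100,
            min_percent_identity >= 0, min_percent_identity <= 100)
  structure(list(max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage,
                 min_percent_identity = min_percent_identity),
            class = "filter_criteria")
}

#' Apply retention criteria to hit records
#'
#' Splits records into kept and rejected; each rejection is labeled with
#' every violated criterion. Query coverage is taken from the
#' `query_coverage` column when present, otherwise computed as
#' `100 * (|q_end - q_start| + 1) / query length` from `query_lengths`.
#'
#' @param records Data frame from [parse_hits()].
#' @param criteria A [filter_criteria()] object.
#' @param query_lengths Optional named vector of query lengths, used when
#'   the records carry no coverage column.
#' @return List with `kept` and `rejected` data frames; `rejected` carries
#'   a `reasons` column (comma-separated criterion names).
#' @export
apply_criteria <- function(records, criteria = filter_criteria(),
                           query_lengths = NULL) {
  cov <- records$query_coverage
  need <- is.na(cov)
  if (any(need)) {
    if (is.null(query_lengths))
      stop("records lack query coverage and no query_lengths supplied")
    qlen <- query_lengths[records$query_id[need]]
    if (any(is.na(qlen)))
      stop("missing query length for: ",
           paste(unique(records$query_id[need][is.na(qlen)]), collapse = ", "))
    cov[need] <- 100 * (abs(records$q_end[need] - records$q_start[need]) + 1) /
      qlen
  }
  bad_e <- !(records$evalue < criteria$max_evalue)
  bad_c <- !(cov > criteria$min_query_coverage)
  bad_i <- !(records$percent_identity > criteria$min_percent_identity)
  reasons <- mapply(function(e, c2, i)
    paste(c(if (e) "evalue", if (c2) "coverage", if (i) "identity"),
          collapse = ","), bad_e, bad_c, bad_i)
  keep <- !(bad_e | bad_c | bad_i)
  records$query_coverage <- cov
  rejected <- records[!keep, , drop = FALSE]
  rejected$reasons <- reasons[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Remove sequences that are exact full-length duplicates
#'
#' Among identical sequences the first-listed id is retained; input order
#' is preserved. Only 100% full-length string identity counts as
#' redundancy; no similarity clustering is done.
#'
#' @param sequences Data frame with columns `id` and `sequence`, or a named
#'   character vector.
#' @return Data frame of retained `id`, `sequence` rows, plus a
#'   `duplicates` attribute mapping removed id -> retained id.
#' @export
deduplicate <- function(sequences) {
  if (is.character(sequences))
    sequences <- data.frame(id = names(sequences), sequence = sequences,
                            stringsAsFactors = FALSE)
  dup <- duplicated(sequences$sequence)
  first_id <- sequences$id[match(sequences$sequence, sequences$sequence)]
  out <- sequences[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "duplicates") <-
    stats::setNames(first_id[dup], sequences$id[dup])
  out
}
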