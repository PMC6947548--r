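# Squared-distance matrix between two coordinate sets (n x 3, m x 3).
.dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
}

.ligand_self_key <- function(ligand) {
  paste(ligand$chain_id, ligand$author_number,
        ifelse(is.na(ligand$insert), "", ligand$insert),
        ligand$het_code, sep = "|")
}

#' Residues within a distance cutoff of a ligand
#'
#' Extracts the cofactor-binding region of a structure: every polymer
#' residue with at least one heavy atom within `cutoff` Angstrom of any
#' heavy atom of the ligand. Inclusion is whole-residue; the ligand's own
#' residue is excluded; waters are never counted (dropped on read).
#'
#' @param structure A `structure3d` object.
#' @param ligand A `ligand_instance` (need not belong to `structure` if
#'   `provenance = "transferred"`; coordinates must be in the structure's
#'   frame).
#' @param cutoff Distance cutoff in Angstrom (default 4.0, the conventional
#'   contact range for cofactor-binding residues).
#' @param include_hetero Also report heteroresidues near the ligand
#'   (default `FALSE`: protein residues only).
#' @param provenance `"crystallized"` or `"transferred"`.
#' @return A `binding_region`: list with `structure_id`, `ligand` summary,
#'   `cutoff`, `provenance`, and a `residues` data frame
#'   (`chain`, `resno`, `insert`, `resname`, `min_distance`).
#' @export
binding_region <- function(structure, ligand, cutoff = 4.0,
                           include_hetero = FALSE,
                           provenance = c("crystallized", "transferred")) {
  provenance <- match.arg(provenance)
  stopifnot(cutoff > 0)
  if (!inherits(ligand, "ligand_instance")) stop("ligand must be a ligand_instance")
  if (nrow(ligand$atoms) == 0L) stop("ligand has no heavy atoms")
  if (provenance == "crystallized" &&
      !identical(ligand$structure_id, structure$id) &&
      !.ligand_self_key(ligand) %in% .residue_key(structure$atoms))
    stop("ligand ", ligand$het_code, " is not part of structure '",
         structure$id, "'")
  at <- structure$atoms
  if (!include_hetero) at <- at[!at$het, , drop = FALSE]
  at <- at[.residue_key(at) != .ligand_self_key(ligand), , drop = FALSE]
  res <- .residues_within(at, coords(ligand), cutoff)
  structure(list(structure_id = structure$id,
                 ligand = list(het_code = ligand$het_code,
                               chain_id = ligand$chain_id,
                               author_number = ligand$author_number,
                               category = ligand$category),
                 cutoff = cutoff, provenance = provenance,
                 residues = res), class = "binding_region")
}

.residues_within <- function(at, lig_xyz, cutoff) {
  empty <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      min_distance = numeric())
  if (nrow(at) == 0L) return(empty)
  d2 <- .dist2(as.matrix(at[, c("x", "y", "z")]), lig_xyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- .residue_key(at)
  res_min <- tapply(mind, key, min)
  keep <- names(res_min)[res_min <= cutoff]
  if (!length(keep)) return(empty)
  first <- at[!duplicated(key) & key %in% keep, , drop = FALSE]
  first <- first[match(keep, .residue_key(first)), , drop = FALSE]
  out <- data.frame(chain = first$chain, resno = first$resno,
                    insert = first$insert, resname = first$resname,
                    min_distance = as.numeric(res_min[keep]))
  out[order(out$chain, out$resno, ifelse(is.na(out$insert), "", out$insert)), ,
      drop = FALSE]
}

#' @export
print.binding_region <- function(x, ...) {
  cat(sprintf("binding region of %s in %s (cutoff %.1f A, %s): %d residues\n",
              x$ligand$het_code, x$structure_id, x$cutoff, x$provenance,
              nrow(x$residues)))
  if (nrow(x$residues))
    cat(" ", paste(sprintf("%s%d", x$residues$resname, x$residues$resno),
                   collapse = " "), "\n")
  invisible(x)
}

#' Transfer a ligand into a homolog and predict its binding region
#'
#' Superposes the donor structure onto the acceptor, maps the donor's
#' ligand coordinates into the acceptor frame with the resulting rigid
#' transform, and computes the binding region the transferred ligand would
#' occupy in the acceptor. This is the operation used to propose unobserved
#' cofactor sites (e.g. a ubiquinone region in structures crystallized
#' without one).
#'
#' @param donor Structure carrying the crystallized ligand.
#' @param acceptor Structure into which the ligand is transferred.
#' @param ligand A `ligand_instance` from `donor`.
#' @param cutoff Region cutoff in Angstrom (default 4.0).
#' @param ... Passed to [superpose_structures()] (chains, fit atoms, ...).
#' @return List with `ligand` (coordinates in the acceptor frame),
#'   `region` (a `binding_region`, provenance `"transferred"`), and
#'   `superposition`.
#' @export
transfer_ligand <- function(donor, acceptor, ligand, cutoff = 4.0, ...) {
  sup <- superpose_structures(ref = acceptor, mobile = donor, ...)
  lig2 <- apply_transform(ligand, sup)
  lig2$structure_id <- acceptor$id
  reg <- binding_region(acceptor, lig2, cutoff = cutoff,
                        provenance = "transferred")
  list(ligand = lig2, region = reg, superposition = sup)
}

#' Protein-protein interface residues
#'
#' Residues of two chains that face each other within a cutoff, computed in
#' both directions (a residue of chain A is listed iff any of its heavy
#' atoms is within `cutoff` of any heavy atom of chain B, and vice versa).
#' The partner chain may live in a second structure already placed in the
#' same frame (e.g. by superposition).
#'
#' @param structure A `structure3d` holding `chain_a`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Interface cutoff in Angstrom (default 4.0).
#' @param partner Optional second `structure3d` holding `chain_b`
#'   (default: `structure` itself).
#' @return An `interface_report`: `chain_pair`, `cutoff`, and residue
#'   tables `residues_a`, `residues_b`.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 4.0,
                               partner = NULL) {
  if (is.null(partner)) partner <- structure
  ata <- structure$atoms[structure$atoms$chain == chain_a, , drop = FALSE]
  atb <- partner$atoms[partner$atoms$chain == chain_b, , drop = FALSE]
  if (nrow(ata) == 0L) stop("chain '", chain_a, "' not found in '",
                            structure$id, "'")
  if (nrow(atb) == 0L) stop("chain '", chain_b, "' not found in '",
                            partner$id, "'")
  ra <- .residues_within(ata, as.matrix(atb[, c("x", "y", "z")]), cutoff)
  rb <- .residues_within(atb, as.matrix(ata[, c("x", "y", "z")]), cutoff)
  structure(list(chain_pair = c(chain_a, chain_b), cutoff = cutoff,
                 structure_ids = c(structure$id, partner$id),
                 residues_a = ra, residues_b = rb),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface %s:%s / %s:%s (cutoff %.1f A): %d vs %d residues\n",
              x$structure_ids[1], x$chain_pair[1],
              x$structure_ids[2], x$chain_pair[2],
              x$cutoff, nrow(x$residues_a), nrow(x$residues_b)))
  invisible(x)
}

.partner_coords <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "ligand_instance") || inherits(x, "structure3d"))
    return(coords(x))
  stop("distance partner must be a ligand, structure, or coordinate matrix")
}

#' Cofactor-cofactor distance audit
#'
#' Minimum heavy-atom distance between two atom sets (ligands, heme groups,
#' or whole chains, handled uniformly) with a flag for physiological
#' electron-tunneling range. Edge-to-edge distances up to about 13 Angstrom
#' are conventionally considered compatible with productive electron
#' transfer, so the bound is read inclusively: a distance exactly equal to
#' the threshold is flagged as within range.
#'
#' @param a,b Ligand instances, `structure3d` objects (e.g. a chain
#'   subset), or n x 3 coordinate matrices, in a common frame.
#' @param threshold Tunneling threshold in Angstrom (default 13.0).
#' @param label_a,label_b Identifiers for the report.
#' @return A `distance_audit`: `partner_a`, `partner_b`,
#'   `min_heavy_atom_distance`, `tunneling_threshold`,
#'   `within_tunneling_range`.
#' @export
cofactor_distance <- function(a, b, threshold = 13.0,
                              label_a = NULL, label_b = NULL) {
  lab <- function(x, fallback) {
    if (!is.null(fallback)) return(fallback)
    if (inherits(x, "ligand_instance")) return(x$het_code)
    if (inherits(x, "structure3d")) return(x$id)
    "coords"
  }
  A <- .partner_coords(a); B <- .partner_coords(b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty atom set")
  d <- sqrt(max(0, min(.dist2(A, B))))
  structure(list(partner_a = lab(a, label_a), partner_b = lab(b, label_b),
                 min_heavy_atom_distance = d,
                 tunneling_threshold = threshold,
                 within_tunneling_range = d <= threshold),
            class = "distance_audit")
}

#' @export
print.distance_audit <- function(x, ...) {
  cat(sprintf("%s -- %s: min heavy-atom distance %.2f A (%s %4.1f A tunneling range)\n",
              x$partner_a, x$partner_b, x$min_heavy_atom_distance,
              if (x$within_tunneling_range) "within" else "outside",
              x$tunneling_threshold))
  invisible(x)
}

#' Project binding regions of several structures onto MSA columns
#'
#' Aligns each region's residues to the columns of a shared MSA (via the
#' structure's chain sequence and author numbering) and tabulates, per
#' column, which structures contribute a binding-region residue there. The
#' `overlap_fraction` attribute reports the fraction of contributing
#' columns shared by all structures (intersection over union), a measure of
#' how similarly located the regions are.
#'
#' @param regions List of `binding_region` objects.
#' @param msa An [new_msa()] object containing one record per structure.
#' @param id_map Named character vector: structure id -> MSA record id.
#' @param structures Named list of `structure3d` objects keyed by
#'   structure id (needed to recover author numbering).
#' @param chain_ids Optional named chain overrides per structure id.
#' @return Data frame keyed by MSA `column` with one logical column per
#'   structure; attribute `overlap_fraction`.
#' @export
compare_regions <- function(regions, msa, id_map, structures,
                            chain_ids = NULL) {
  col_sets <- list()
  for (reg in regions) {
    sid <- reg$structure_id
    if (!sid %in% names(id_map))
      stop("structure '", sid, "' absent from id_map/MSA")
    rec <- id_map[[sid]]
    if (!rec %in% msa$ids)
      stop("MSA record '", rec, "' (structure '", sid, "') not in MSA")
    st <- structures[[sid]]
    ch <- if (!is.null(chain_ids) && sid %in% names(chain_ids))
      chain_ids[[sid]] else first_polymer_chain(st)
    cs <- extract_chain_sequence(st, ch)
    map <- .numbering_to_msa_columns(msa, rec, cs)
    cols <- map$column[match(reg$residues$resno, map$author_number)]
    col_sets[[sid]] <- sort(unique(cols[!is.na(cols)]))
  }
  all_cols <- sort(unique(unlist(col_sets)))
  tab <- data.frame(column = all_cols)
  for (sid in names(col_sets)) tab[[sid]] <- all_cols %in% col_sets[[sid]]
  inter <- Reduce(intersect, col_sets)
  attr(tab, "overlap_fraction") <-
    if (length(all_cols)) length(inter) / length(all_cols) else NA_real_
  tab
}

# Map author numbers of a chain onto MSA columns for record `rec`,
# allowing a constant offset between chain sequence and the record's
# ungapped sequence.
.numbering_to_msa_columns <- function(msa, rec, chainseq) {
  gapped <- strsplit(msa$seqs[[rec]], "")[[1]]
  ungapped_cols <- which(gapped != "-")
  ungapped <- paste(gapped[ungapped_cols], collapse = "")
  off <- .constant_offset(ungapped, chainseq$sequence)
  # seq position p (1-based in record) sits at chain index p - off
  n <- length(ungapped_cols)
  chain_idx <- seq_len(n) - off
  valid <- chain_idx >= 1 & chain_idx <= length(chainseq$numbering_map)
  data.frame(column = ungapped_cols[valid],
             seq_pos = seq_len(n)[valid],
             author_number = chainseq$numbering_map[chain_idx[valid]])
}

# Constant offset o such that record position p corresponds to chain
# position p - o; found by locating one sequence inside the other.
.constant_offset <- function(record_seq, chain_seq) {
  if (identical(record_seq, chain_seq)) return(0L)
  hit <- regexpr(chain_seq, record_seq, fixed = TRUE)
  if (hit > 0) return(as.integer(hit) - 1L)
  hit <- regexpr(record_seq, chain_seq, fixed = TRUE)
  if (hit > 0) return(-(as.integer(hit) - 1L))
  # fall back: align and require a single dominant diagonal
  aln <- align_sequences(record_seq, chain_seq)
  offs <- aln$pairs$ref_pos - aln$pairs$mob_pos
  tab <- table(offs)
  best <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) / nrow(aln$pairs) < 0.9)
    stop("sequence/chain mismatch beyond a constant offset (",
         "dominant diagonal covers ",
         round(100 * max(tab) / nrow(aln$pairs)), "% of aligned positions)")
  best
}
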