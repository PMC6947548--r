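# Water and common monoatomic-ion het codes excluded from ligand listings.
.WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")
.ION_CODES <- c("NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "FE2", "CU",
                "CU1", "HG", "CD", "NI", "CO", "BR", "IOD", "CS", "LI", "SR")

#' Default ligand category dictionary
#'
#' Maps het codes to the cofactor categories used throughout the package.
#' Flavins, nicotinamide cofactors and ubiquinone analogues get their own
#' categories; coenzyme A is separate; everything else (including small
#' substrates such as molecular oxygen and hydrogen sulfide, and inhibitors
#' such as stigmatellin analogues not listed here) falls into `other`.
#' The dictionary is user-extensible: pass a modified copy to
#' [list_ligands()] or set the `ligands` section of a YAML run config.
#'
#' @return Named list mapping category name to a character vector of het codes.
#' @export
#' @examples
#' default_ligand_dict()
default_ligand_dict <- function() {
  list(
    "FAD-like" = c("FAD"),
    "NAD-like" = c("NAD", "NAI", "NAP", "NDP"),
    "UQ-like"  = c("UQ1", "UQ2", "UQ5", "UQ6", "DCQ", "SMA"),
    "CoA"      = c("COA")
  )
}

#' Categorize a het code
#'
#' @param het_code Three-letter het code.
#' @param dict Category dictionary, as from [default_ligand_dict()].
#' @return Category name; `"other"` when the code is in no category.
#' @export
categorize_het <- function(het_code, dict = default_ligand_dict()) {
  for (cat in names(dict)) {
    if (toupper(het_code) %in% toupper(dict[[cat]])) return(cat)
  }
  "other"
}

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic-data
#' generators. The atom table is a flat data frame, one row per heavy atom,
#' in the style of bio3d.
#'
#' @param atoms Data frame with columns `chain`, `resno` (author numbering),
#'   `insert` (insertion code, `NA` when absent), `resname`, `atom` (atom
#'   name), `element`, `x`, `y`, `z`, `occ`, `het` (logical HETATM flag).
#' @param id Accession-like identifier.
#' @param source_format `"pdb"`, `"cif"` or `"memory"`.
#' @return An object of class `structure3d`.
#' @export
new_structure3d <- function(atoms, id = "unknown", source_format = "memory") {
  required <- c("chain", "resno", "insert", "resname", "atom", "element",
                "x", "y", "z", "occ", "het")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- chain_ids(x)
  cat(sprintf("structure3d '%s' (%s): %d atoms, %d chain(s): %s\n",
              x$id, x$source_format, nrow(x$atoms), length(ch),
              paste(ch, collapse = ", ")))
  lig <- list_ligands(x)
  if (length(lig))
    cat("ligands:", paste(vapply(lig, function(l)
      sprintf("%s(%s)", l$het_code, l$category), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Chain identifiers of a structure
#' @param structure A `structure3d` object.
#' @return Character vector of chain ids, in order of first appearance.
#' @export
chain_ids <- function(structure) unique(structure$atoms$chain)

#' Coordinates of a structure as a matrix
#' @param structure A `structure3d`, `ligand_instance`, or numeric matrix.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(structure) {
  if (is.matrix(structure)) return(structure)
  at <- if (inherits(structure, "ligand_instance")) structure$atoms
        else structure$atoms
  as.matrix(at[, c("x", "y", "z")])
}

.residue_key <- function(at) {
  paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
        at$resname, sep = "|")
}

.guess_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("pdb", "cif")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 50L, warn = FALSE)
  if (any(startsWith(head, "data_")) || any(grepl("^_atom_site\\.", head)))
    return("cif")
  "pdb"
}

# Collapse alternate locations: keep the highest-occupancy conformer per
# (chain, resno, insert, atom name); ties keep the first encountered.
.collapse_altlocs <- function(at) {
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$atom, sep = "|")
  if (!anyDuplicated(key)) return(at)
  ord <- order(match(key, unique(key)), -at$occ,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno,
                             ifelse(is.na(at$insert), "", at$insert),
                             at$atom, sep = "|")), , drop = FALSE]
  # restore file order of retained atoms
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in '", path, "'")
  element <- a$elesy
  no_el <- is.na(element) | element == ""
  if (any(no_el))  # derive from atom name: first alphabetic character
    element[no_el] <- sub("^[0-9']*([A-Za-z]).*$", "\\1", a$elety[no_el])
  data.frame(chain = as.character(a$chain),
             resno = as.integer(a$resno),
             insert = ifelse(is.na(a$insert) | a$insert == "", NA_character_,
                             as.character(a$insert)),
             resname = as.character(a$resid),
             atom = as.character(a$elety),
             element = toupper(trimws(element)),
             x = a$x, y = a$y, z = a$z,
             occ = ifelse(is.na(a$o), 1, a$o),
             het = a$type == "HETATM",
             stringsAsFactors = FALSE)
}

.read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagged <- grep("^_atom_site\\.", lines)
  if (!length(tagged))
    stop("no _atom_site loop found in mmCIF file '", path, "'")
  fields <- sub("^_atom_site\\.", "", trimws(lines[tagged]))
  start <- max(tagged) + 1L
  rows <- character()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_") || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
  }
  if (!length(rows)) stop("empty _atom_site loop in '", path, "'")
  toks <- lapply(rows, function(r)
    scan(text = r, what = "character", quiet = TRUE))
  bad <- which(vapply(toks, length, 0L) != length(fields))
  if (length(bad))
    stop("malformed _atom_site row at data line ", bad[1], " of '", path, "'")
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  na_dot <- function(v) ifelse(v %in% c("?", ".", ""), NA_character_, v)
  at <- data.frame(
    chain = na_dot(get("auth_asym_id", "label_asym_id")),
    resno = as.integer(na_dot(get("auth_seq_id", "label_seq_id"))),
    insert = na_dot(get("pdbx_PDB_ins_code")),
    resname = na_dot(get("auth_comp_id", "label_comp_id")),
    atom = na_dot(get("auth_atom_id", "label_atom_id")),
    element = toupper(na_dot(get("type_symbol"))),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = suppressWarnings(as.numeric(get("occupancy"))),
    het = get("group_PDB") %in% "HETATM",
    stringsAsFactors = FALSE)
  at$occ[is.na(at$occ)] <- 1
  alt <- na_dot(get("label_alt_id"))
  attr(at, "altloc") <- alt
  at
}

#' Read a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinate files into a flat-atom [new_structure3d()]
#' object. Only the first model is read. Hydrogens and waters are dropped on
#' read (the crystal structures this package targets lack hydrogens and all
#' distance work is heavy-atom); alternate locations are collapsed to the
#' highest-occupancy conformer (ties keep the first encountered).
#'
#' @param path Path to a coordinate file.
#' @param format `"pdb"`, `"cif"`, or `NULL` to auto-detect from the file
#'   extension and content.
#' @param keep_waters Keep water molecules (default `FALSE`).
#' @return A `structure3d` object.
#' @export
read_structure <- function(path, format = NULL, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .guess_format(path, format)
  at <- if (fmt == "pdb") .read_pdb_atoms(path) else .read_cif_atoms(path)
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (!keep_waters)
    at <- at[!(toupper(at$resname) %in% .WATER_CODES), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms left after filtering in '", path, "'")
  rownames(at) <- seq_len(nrow(at))
  at <- .collapse_altlocs(at)
  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  new_structure3d(at, id = id, source_format = fmt)
}

#' Write a structure to a PDB file
#'
#' Writes the retained fields (names, author numbering, coordinates,
#' occupancies, het flags) so that `read_structure(write_structure(s))`
#' round-trips. Coordinates are written at PDB precision (3 decimals).
#'
#' @param structure A `structure3d` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno,
                   resid = at$resname,
                   eleno = seq_len(nrow(at)),
                   elety = at$atom,
                   chain = at$chain,
                   insert = ifelse(is.na(at$insert), "", at$insert),
                   o = at$occ,
                   b = rep(0, nrow(at)),
                   elesy = at$element)
  invisible(path)
}

#' Extract the one-letter sequence and author numbering of a chain
#'
#' Polymer (non-het) residues only, ordered by author number then insertion
#' code. Non-standard residues map to `X`.
#'
#' @param structure A `structure3d` object.
#' @param chain_id Chain identifier.
#' @return List with `sequence` (one-letter string), `numbering_map`
#'   (integer author numbers, same length), and `insert_codes`.
#' @export
extract_chain_sequence <- function(structure, chain_id) {
  at <- structure$atoms
  if (!chain_id %in% at$chain)
    stop("chain '", chain_id, "' not found; available: ",
         paste(chain_ids(structure), collapse = ", "))
  at <- at[at$chain == chain_id & !at$het, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("chain '", chain_id, "' has no polymer residues")
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  first <- !duplicated(key)
  res <- at[first, , drop = FALSE]
  ord <- order(res$resno, ifelse(is.na(res$insert), "", res$insert))
  res <- res[ord, , drop = FALSE]
  one <- suppressWarnings(bio3d::aa321(res$resname))
  one[is.na(one) | !one %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  list(sequence = paste(one, collapse = ""),
       numbering_map = res$resno,
       insert_codes = res$insert)
}

#' List ligand instances in a structure
#'
#' One entry per heteroresidue, categorized via the het-code dictionary.
#' Waters and common monoatomic ions are excluded unless requested; small
#' substrates such as O2 or H2S are retained as category `"other"`.
#'
#' @param structure A `structure3d` object.
#' @param categories Optional character vector restricting the categories
#'   returned (e.g. `c("FAD-like", "UQ-like")`).
#' @param dict Het-code dictionary, see [default_ligand_dict()].
#' @param include_ions Include monoatomic ions (default `FALSE`).
#' @return List of `ligand_instance` objects, each with `het_code`,
#'   `chain_id`, `author_number`, `insert`, `category` and an `atoms` table.
#' @export
list_ligands <- function(structure, categories = NULL,
                         dict = default_ligand_dict(),
                         include_ions = FALSE) {
  at <- structure$atoms
  at <- at[at$het & !(toupper(at$resname) %in% .WATER_CODES), , drop = FALSE]
  if (nrow(at) == 0L) return(list())
  key <- .residue_key(at)
  out <- list()
  for (k in unique(key)) {
    sub <- at[key == k, , drop = FALSE]
    if (!include_ions && nrow(sub) == 1L &&
        toupper(sub$resname) %in% .ION_CODES) next
    lig <- structure(list(
      het_code = sub$resname[1],
      chain_id = sub$chain[1],
      author_number = sub$resno[1],
      insert = sub$insert[1],
      category = categorize_het(sub$resname[1], dict),
      atoms = sub,
      structure_id = structure$id), class = "ligand_instance")
    out[[length(out) + 1L]] <- lig
  }
  if (!is.null(categories))
    out <- Filter(function(l) l$category %in% categories, out)
  out
}

#' @export
print.ligand_instance <- function(x, ...) {
  cat(sprintf("ligand %s chain %s %d (%s), %d heavy atoms [%s]\n",
              x$het_code, x$chain_id, x$author_number, x$category,
              nrow(x$atoms), x$structure_id))
  invisible(x)
}

#' Find a ligand by het code
#'
#' Convenience lookup over [list_ligands()]; errors when no instance of the
#' code is present.
#'
#' @param structure A `structure3d` object.
#' @param het_code Three-letter het code.
#' @param which Index among instances of that code (default first).
#' @inheritParams list_ligands
#' @return A `ligand_instance`.
#' @export
get_ligand <- function(structure, het_code, which = 1L,
                       dict = default_ligand_dict()) {
  lig <- list_ligands(structure, dict = dict, include_ions = TRUE)
  hits <- Filter(function(l) toupper(l$het_code) == toupper(het_code), lig)
  if (!length(hits))
    stop("no ligand '", het_code, "' in structure '", structure$id, "'")
  hits[[which]]
}

#' Extract one chain (all its residues, polymer and hetero) as a structure
#' @param structure A `structure3d` object.
#' @param chain_id Chain identifier.
#' @param polymer_only Drop heteroresidues of the chain (default `FALSE`).
#' @return A `structure3d` restricted to the chain.
#' @export
subset_chain <- function(structure, chain_id, polymer_only = FALSE) {
  at <- structure$atoms
  keep <- at$chain == chain_id
  if (polymer_only) keep <- keep & !at$het
  if (!any(keep))
    stop("chain '", chain_id, "' not found in '", structure$id, "'")
  new_structure3d(at[keep, , drop = FALSE],
                  id = paste0(structure$id, "_", chain_id),
                  source_format = structure$source_format)
}

#' First chain containing polymer residues
#' @param structure A `structure3d` object.
#' @return Chain identifier.
#' @export
first_polymer_chain <- function(structure) {
  at <- structure$atoms
  ch <- unique(at$chain[!at$het])
  if (!length(ch)) stop("structure '", structure$id, "' has no polymer chain")
  ch[1]
}
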