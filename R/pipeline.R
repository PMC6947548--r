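# Tab-separated report with a commented "# key=value" metadata preamble.
.write_report <- function(df, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(list(package = "flavocompare",
                 version = as.character(utils::packageVersion("flavocompare")),
                 date = "run"), meta)
  for (k in names(meta))
    cat(sprintf("# %s=%s\n", k, meta[[k]]), file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.region_table <- function(regions) {
  do.call(rbind, lapply(regions, function(r) {
    if (nrow(r$residues) == 0L) return(NULL)
    data.frame(structure = r$structure_id, ligand = r$ligand$het_code,
               category = r$ligand$category, provenance = r$provenance,
               cutoff = r$cutoff,
               chain = r$residues$chain, resno = r$residues$resno,
               insert = ifelse(is.na(r$residues$insert), "",
                               r$residues$insert),
               resname = r$residues$resname,
               min_distance = round(r$residues$min_distance, 3))
  }))
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML mappings; see [run_pipeline()] for the
#' recognized sections. A `ligands` section (category -> het codes)
#' extends [default_ligand_dict()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$ligands)) {
    dict <- default_ligand_dict()
    for (nm in names(cfg$ligands))
      dict[[nm]] <- unique(c(dict[[nm]], cfg$ligands[[nm]]))
    cfg$ligand_dict <- dict
  }
  cfg
}

#' Run the comparative-analysis pipeline end to end
#'
#' Orchestrates the stages over a configuration and writes paper-style
#' tab-separated reports into `output_dir`: RMSD matrix, crystallized
#' binding regions, transferred regions, distance audits, motif table,
#' filter log, and a Newick tree, plus a run log with parameters and
#' seeds. Stages are independent: a failing stage is recorded in the run
#' log and the remaining stages still run.
#'
#' Recognized config entries: `structures` (named list of coordinate file
#' paths), `chains` (named chain overrides), `binding_cutoff` (default 4),
#' `interface_cutoff` (default 4), `tunneling_threshold` (default 13),
#' `transfers` (list of `donor`/`acceptor`/`het_code`), `audits` (list of
#' `structure`/`het_a`/`het_b`), `msa` (+ optional `taxa_tsv`,
#' `motif_min_len`, `motif_conservation`, `motif_max_gap`), `hits`
#' (+ `hits_has_coverage`, threshold overrides), `tree` (logical),
#' `bootstrap_n`, `seed` (required when `tree`), `output_dir`.
#'
#' @param config Config list or path to a YAML file
#'   ([read_run_config()]).
#' @return Invisibly, a list of stage results; component `errors` is a
#'   named character vector of stage failures (empty on full success).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir %||% "flavocompare_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dict <- config$ligand_dict %||% default_ligand_dict()
  bc <- config$binding_cutoff %||% 4.0
  ic <- config$interface_cutoff %||% 4.0
  tt <- config$tunneling_threshold %||% 13.0
  errors <- character()
  results <- list()
  log_lines <- c(sprintf("binding_cutoff=%g interface_cutoff=%g tunneling_threshold=%g",
                         bc, ic, tt),
                 sprintf("seed=%s", config$seed %||% "none"))
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) {
      errors[[name]] <<- conditionMessage(r)
      log_lines <<- c(log_lines, sprintf("stage %s: FAILED (%s)", name,
                                         conditionMessage(r)))
      NULL
    } else {
      log_lines <<- c(log_lines, sprintf("stage %s: ok", name))
      r
    }
  }

  structures <- NULL
  if (!is.null(config$structures)) {
    structures <- stage("read_structures", {
      st <- lapply(config$structures, read_structure)
      names(st) <- names(config$structures)
      st
    })
  } else log_lines <- c(log_lines, "stage read_structures: skipped (no structures configured)")

  if (!is.null(structures) && length(structures) >= 2L) {
    results$rmsd <- stage("rmsd_matrix", {
      m <- rmsd_matrix(structures)
      .write_report(as.data.frame(cbind(id = rownames(m), round(m, 3))),
                    file.path(out_dir, "rmsd_matrix.tsv"),
                    list(fit = "backbone"))
      m
    })
  }

  if (!is.null(structures)) {
    results$regions <- stage("binding_regions", {
      regions <- list()
      for (nm in names(structures))
        for (lig in list_ligands(structures[[nm]], dict = dict))
          regions[[length(regions) + 1L]] <-
            binding_region(structures[[nm]], lig, cutoff = bc)
      tab <- .region_table(regions)
      if (!is.null(tab))
        .write_report(tab, file.path(out_dir, "binding_regions.tsv"),
                      list(cutoff = bc))
      regions
    })
    if (!is.null(config$transfers)) {
      results$transfers <- stage("transfers", {
        trs <- lapply(config$transfers, function(tr) {
          lig <- get_ligand(structures[[tr$donor]], tr$het_code, dict = dict)
          transfer_ligand(structures[[tr$donor]], structures[[tr$acceptor]],
                          lig, cutoff = bc)
        })
        tab <- .region_table(lapply(trs, `[[`, "region"))
        if (!is.null(tab))
          .write_report(tab, file.path(out_dir, "transferred_regions.tsv"),
                        list(cutoff = bc))
        trs
      })
    }
    if (!is.null(config$audits)) {
      results$audits <- stage("distance_audits", {
        auds <- lapply(config$audits, function(a) {
          st <- structures[[a$structure]]
          cofactor_distance(get_ligand(st, a$het_a, dict = dict),
                            get_ligand(st, a$het_b, dict = dict),
                            threshold = tt)
        })
        tab <- do.call(rbind, lapply(auds, function(x)
          data.frame(partner_a = x$partner_a, partner_b = x$partner_b,
                     min_distance = round(x$min_heavy_atom_distance, 3),
                     threshold = x$tunneling_threshold,
                     within_range = x$within_tunneling_range)))
        .write_report(tab, file.path(out_dir, "distance_audits.tsv"),
                      list(threshold = tt))
        auds
      })
    }
  }

  if (!is.null(config$msa)) {
    results$motifs <- stage("motifs", {
      msa <- read_alignment(config$msa, taxa_tsv = config$taxa_tsv)
      hits <- detect_motifs(msa,
                            min_len = config$motif_min_len %||% 5L,
                            conservation_threshold =
                              config$motif_conservation %||% 0.8,
                            max_gap_fraction = config$motif_max_gap %||% 0.2)
      tab <- do.call(rbind, lapply(seq_along(hits), function(i)
        data.frame(motif = i, start = hits[[i]]$span["start"],
                   end = hits[[i]]$span["end"],
                   consensus = hits[[i]]$consensus,
                   mean_conservation =
                     round(hits[[i]]$mean_conservation, 3))))
      if (!is.null(tab))
        .write_report(tab, file.path(out_dir, "motifs.tsv"),
                      list(min_len = config$motif_min_len %||% 5,
                           conservation = config$motif_conservation %||% 0.8))
      list(msa = msa, hits = hits)
    })
    if (isTRUE(config$tree)) {
      results$tree <- stage("tree", {
        if (is.null(config$seed))
          stop("a seed is required when the bootstrap tree is requested")
        msa <- results$motifs$msa %||% read_alignment(config$msa)
        ug <- ungapped_columns(msa)
        boot <- bootstrap_support(ug, n = config$bootstrap_n %||% 100L,
                                  seed = config$seed)
        ape::write.tree(boot$tree, file.path(out_dir, "tree.nwk"))
        boot
      })
    }
  } else log_lines <- c(log_lines, "stage motifs: skipped (no MSA configured)")

  if (!is.null(config$hits)) {
    results$filter <- stage("filter_hits", {
      rec <- parse_hits(config$hits,
                        has_query_coverage =
                          isTRUE(config$hits_has_coverage))
      crit <- filter_criteria(
        max_evalue = config$max_evalue %||% 1e-25,
        min_query_coverage = config$min_query_coverage %||% 70,
        min_percent_identity = config$min_percent_identity %||% 30)
      res <- apply_criteria(rec, crit, query_lengths = config$query_lengths)
      log_tab <- rbind(
        if (nrow(res$kept)) cbind(res$kept, status = "kept", reasons = ""),
        if (nrow(res$rejected)) cbind(
          res$rejected[, setdiff(names(res$rejected), "reasons")],
          status = "rejected", reasons = res$rejected$reasons))
      .write_report(log_tab, file.path(out_dir, "filter_log.tsv"),
                    list(max_evalue = crit$max_evalue,
                         min_query_coverage = crit$min_query_coverage,
                         min_percent_identity = crit$min_percent_identity))
      res
    })
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  results$errors <- unlist(errors)
  results$output_dir <- out_dir
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structural checks against the reference crystal structures
#'
#' Re-runs the headline structural comparisons on user-supplied coordinate
#' files of the reference entries (4bur, 4g73, 5yjw, 5kmr, 5n1t, 5na1,
#' 5jwc, 3hyw, 4j56): NDI crystal-pair RMSD, minimum NDH-2 family RMSD
#' against 5kmr, the FAD-to-transferred-ubiquinone tunneling distance in
#' AIF, the thioredoxin interface count on 5kmr, the transferred RYL-552
#' region size, and the fifth-motif sequence of the NDH-2 chain. The
#' coordinate files are not shipped with the package (they are large
#' external database entries); download them into a directory as
#' lowercase `<id>.pdb` files.
#'
#' @param pdb_dir Directory containing `4bur.pdb`, `4g73.pdb`, `5yjw.pdb`,
#'   `5kmr.pdb`, `5n1t.pdb`, `5na1.pdb`, `5jwc.pdb`, `3hyw.pdb`,
#'   `4j56.pdb`.
#' @param trx_chain Chain of thioredoxin within 4j56 (default `"C"`).
#' @param ryl_het Het code of the RYL-552 inhibitor in 5jwc.
#' @return Named list of computed quantities.
#' @export
reference_structure_checks <- function(pdb_dir, trx_chain = "C",
                                       ryl_het = "RYL") {
  need <- c("4bur", "4g73", "5yjw", "5kmr", "5n1t", "5na1", "5jwc", "3hyw",
            "4j56")
  paths <- file.path(pdb_dir, paste0(need, ".pdb"))
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing reference coordinate files in '", pdb_dir, "': ",
         paste(missing, collapse = ", "))
  st <- lapply(paths, read_structure); names(st) <- need
  out <- list()
  out$rmsd_5yjw_4g73 <-
    superpose_structures(st[["4g73"]], st[["5yjw"]])$rmsd_refined
  ndh2 <- c("5n1t", "5na1", "5jwc", "3hyw")
  out$min_rmsd_ndh2_vs_5kmr <- min(vapply(ndh2, function(id)
    superpose_structures(st[["5kmr"]], st[[id]])$rmsd_refined, 0))
  uq <- get_ligand(st[["4g73"]], "UQ5")
  tr <- transfer_ligand(st[["4g73"]], st[["4bur"]], uq)
  out$fad4bur_uq_distance <- cofactor_distance(
    get_ligand(st[["4bur"]], "FAD"), tr$ligand)$min_heavy_atom_distance
  sup <- superpose_structures(st[["5kmr"]], st[["4j56"]])
  trx <- apply_transform(st[["4j56"]], sup)
  ifc <- interface_residues(st[["5kmr"]], first_polymer_chain(st[["5kmr"]]),
                            trx_chain, partner = trx)
  out$n_5kmr_trx_interface <- nrow(ifc$residues_a)
  ryl <- get_ligand(st[["5jwc"]], ryl_het)
  out$n_5kmr_ryl_region <-
    nrow(transfer_ligand(st[["5jwc"]], st[["5kmr"]], ryl)$region$residues)
  cs <- extract_chain_sequence(st[["5kmr"]], first_polymer_chain(st[["5kmr"]]))
  idx <- match(161:169, cs$numbering_map)
  out$fifth_motif_5kmr <- paste(strsplit(cs$sequence, "")[[1]][idx],
                                collapse = "")
  out
}
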