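test_that("alignments read identically from FASTA and Clustal encodings", {
  seqs <- c(s1 = "ACDE-GHIK", s2 = "ACDEFGHIK")
  ff <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", seqs[1], ">s2", seqs[2]), ff)
  fc <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.82) multiple sequence alignment", "", "",
               sprintf("%-16s%s", "s1", seqs[1]),
               sprintf("%-16s%s", "s2", seqs[2]), ""), fc)
  m1 <- read_alignment(ff)
  m2 <- read_alignment(fc)
  expect_equal(m1$seqs, m2$seqs)
  expect_equal(m1$length, 9L)
  # an all-gap column is preserved on read
  fg <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-D", ">b", "AC-D"), fg)
  expect_equal(read_alignment(fg)$length, 4L)
  # ragged input errors
  expect_error(new_msa(c("a", "b"), c("ACD", "AC")), "ragged")
})

test_that("column conservation counts modal residues among non-gaps", {
  msa <- new_msa(paste0("s", 1:10),
                 c(rep("GGA", 6), rep("GAA", 4)))
  prof <- column_conservation(msa)
  expect_equal(prof$conservation, c(1, 0.6, 1))
  expect_equal(prof$modal_residue[2], "G")
  all_gap <- new_msa(c("a", "b"), c("A-", "C-"))
  p2 <- column_conservation(all_gap)
  expect_true(is.na(p2$modal_residue[2]))
  expect_equal(p2$conservation[2], 0)
  expect_equal(p2$gap_fraction[2], 1)
})

test_that("ten planted conserved blocks are recovered exactly", {
  spans <- lapply(0:9, function(i) c(15 + i * 30, 24 + i * 30))
  set.seed(101)
  blocks <- lapply(spans, function(sp)
    list(span = sp,
         consensus = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                  10, replace = TRUE), collapse = ""),
         mutation_rate = 0.1))
  gen <- make_synthetic_msa(20, 320, blocks = blocks, gap_rate = 0.05,
                            seed = 7)
  hits <- detect_motifs(gen$msa)
  expect_length(hits, 10L)
  got <- t(vapply(hits, function(h) unname(h$span), integer(2)))
  expect_equal(got, unname(gen$block_spans))
})

test_that("random alignments yield no motifs; identical ones a single span", {
  for (seed in c(1, 2, 3)) {
    bg <- make_synthetic_msa(20, 200, gap_rate = 0, seed = seed)
    expect_length(detect_motifs(bg$msa), 0L)
  }
  same <- new_msa(paste0("s", 1:5), rep(strrep("MKLV", 5), 5))
  hits <- detect_motifs(same)
  expect_length(hits, 1L)
  expect_equal(unname(hits[[1]]$span), c(1L, 20L))
})

test_that("motif spans are maximal and threshold-monotone", {
  spans <- list(c(20, 29), c(60, 71))
  blocks <- lapply(spans, function(sp)
    list(span = sp, consensus = strrep("W", sp[2] - sp[1] + 1),
         mutation_rate = 0.1))
  gen <- make_synthetic_msa(20, 100, blocks = blocks, gap_rate = 0.03,
                            seed = 13)
  hits <- detect_motifs(gen$msa)
  prof <- column_conservation(gen$msa)
  for (h in hits) {
    s <- h$span["start"]; e <- h$span["end"]
    ok <- function(j) j >= 1 && j <= nrow(prof) &&
      prof$conservation[j] >= 0.8 && prof$gap_fraction[j] <= 0.2
    expect_false(ok(s - 1))
    expect_false(ok(e + 1))
  }
  # lowering the threshold never removes covered columns
  cols_hi <- unlist(lapply(hits, function(h) h$span["start"]:h$span["end"]))
  hits_lo <- detect_motifs(gen$msa, conservation_threshold = 0.6)
  cols_lo <- unlist(lapply(hits_lo,
                           function(h) h$span["start"]:h$span["end"]))
  expect_true(all(cols_hi %in% cols_lo))
})

test_that("taxon consensus separates planted per-taxon variants", {
  taxa <- rep(c("Metazoa", "Bacteria"), each = 6)
  blocks <- list(list(span = c(11, 19),
                      consensus = c(Metazoa = "IGGGTAAFA",
                                    Bacteria = "LGAGYGGIV"),
                      mutation_rate = 0))
  gen <- make_synthetic_msa(12, 40, blocks = blocks, taxa = taxa,
                            gap_rate = 0, seed = 5)
  hits <- detect_motifs(gen$msa, conservation_threshold = 0.5)
  hit <- hits[[which(vapply(hits, function(h) h$span["start"] == 11L, TRUE))]]
  tc <- taxon_consensus(gen$msa, hit)
  expect_equal(tc$Metazoa$consensus, "IGGGTAAFA")
  expect_equal(tc$Bacteria$consensus, "LGAGYGGIV")
  unlabeled <- gen$msa; unlabeled$taxa[1] <- NA
  expect_error(taxon_consensus(unlabeled, hit), "unlabeled")
})

test_that("the packaged exemplar alignment gives the metazoan glycine motif", {
  f <- system.file("extdata", "synthetic_first_motif.fasta",
                   package = "flavocompare")
  tt <- system.file("extdata", "synthetic_first_motif_taxa.tsv",
                    package = "flavocompare")
  msa <- read_alignment(f, taxa_tsv = tt)
  hit <- structure(list(span = c(start = 7L, end = 15L)),
                   class = "motif_hit")
  tc <- taxon_consensus(msa, hit)
  expect_equal(tc$Metazoa$consensus, "IGGGTAAFA")
  expect_equal(tc$Bacteria$consensus, "LGAGYGGIV")
  expect_equal(tc$Fungi$consensus, "LGSGWGAIS")
})

test_that("motifs map onto structure author numbering, offsets included", {
  # chain numbered 153.. so that the planted motif sits at authors 161-169
  seq40 <- paste0("MKVWDHTP", "IGGAGFTGE", strrep("L", 23))
  s <- make_toy_structure(40, sequence = seq40, numbering_offset = 152L)
  msa <- new_msa(c("q", "r"), c(seq40, seq40))
  hits <- detect_motifs(msa, conservation_threshold = 0.9)
  hit <- hits[[1]]  # whole alignment is conserved; use the explicit span
  hit$span <- c(start = 9L, end = 17L)
  hit$per_sequence_span <- data.frame(id = c("q", "r"), start = 9L, end = 17L)
  mp <- motif_to_structure(hit, msa, "q", s, "A")
  expect_equal(mp$author_number, 161:169)
  expect_true(all(mp$mapped))
  expect_equal(paste(bio3d::aa321(mp$residue_name), collapse = ""),
               "IGGAGFTGE")

  # a constant +10 numbering offset shifts mapped numbers by exactly 10
  s10 <- make_toy_structure(40, sequence = seq40, numbering_offset = 162L)
  mp10 <- motif_to_structure(hit, msa, "q", s10, "A")
  expect_equal(mp10$author_number, mp$author_number + 10L)

  # span falling outside the crystallized segment is flagged unmapped
  short <- make_toy_structure(5, sequence = substr(seq40, 21, 25),
                              numbering_offset = 172L)
  hit2 <- hit; hit2$span <- c(start = 1L, end = 5L)
  hit2$per_sequence_span <- data.frame(id = c("q", "r"), start = 1L, end = 5L)
  mp2 <- motif_to_structure(hit2, msa, "q", short, "A")
  expect_false(any(mp2$mapped))
})
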