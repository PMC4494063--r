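# Intron size spectra, family alignment, position conservation and
# oversized (fused) introns.

mk_intron_gene <- function(id, chrom, exon_bounds, strand = "+",
                           category = "function-predicted") {
  gene_model(id, chrom, strand,
             matrix(as.integer(exon_bounds), ncol = 2, byrow = TRUE),
             category = category)
}

test_that("intron size histograms count and normalize lengths", {
  # introns of 19, 19, 20 nt
  genes <- list(
    mk_intron_gene("g1", "c1", c(0, 30, 49, 79)),
    mk_intron_gene("g2", "c1", c(100, 130, 149, 179)),
    mk_intron_gene("g3", "c1", c(200, 230, 250, 280)))
  ann <- nm_annotation("toy", genes)
  h <- intron_size_histogram(ann)
  expect_identical(h$length, c(19L, 20L))
  expect_identical(h$count, c(2L, 1L))
  expect_identical(attr(h, "mode"), 19L)
  expect_identical(attr(h, "total"), 3L)
  expect_equal(sum(h$proportion), 100)

  empty <- intron_size_histogram(nm_annotation("toy", list()))
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "total"), 0L)

  # conservation of counts on a synthetic annotation
  tr <- small_sim()
  h2 <- intron_size_histogram(tr$annotation)
  expect_identical(attr(h2, "total"),
                   nrow(annotation_introns(tr$annotation)))
})

test_that("center-star alignment is deterministic and degenerates cleanly", {
  # identical sequences align without gaps
  msa <- align_family(c(a = "MKLVNF", b = "MKLVNF", c = "MKLVNF"))
  expect_true(all(!grepl("-", msa$rows, fixed = TRUE)))
  expect_identical(msa$width, 6L)

  # two sequences equal the pairwise global alignment
  p1 <- "MKLVNFYW"
  p2 <- "MKLNFYW"
  msa2 <- align_family(c(x = p1, y = p2))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  expect_identical(unname(msa2$rows[["x"]]),
                   as.character(Biostrings::alignedPattern(pa)))
  expect_identical(unname(msa2$rows[["y"]]),
                   as.character(Biostrings::alignedSubject(pa)))

  expect_error(align_family(c(a = "MK")), "at least 2")
})

test_that("center-star sum-of-pairs score is near the 3-way DP optimum", {
  mat <- blosum62_matrix()
  trip <- list(c(a = "MKLVNFY", b = "MKLVNFY", c = "MKLNFY"),
               c(a = "WCDEKRH", b = "WCDEKR", c = "WCEKRH"),
               c(a = "MKKLVYF", b = "MKLVYF", c = "MKKLVF"))
  for (prots in trip) {
    msa <- align_family(prots)
    rows <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
    sp <- sp_score_pair(rows[[1]], rows[[2]], mat, -5) +
      sp_score_pair(rows[[1]], rows[[3]], mat, -5) +
      sp_score_pair(rows[[2]], rows[[3]], mat, -5)
    opt <- oracle_msa3_optimum(prots[[1]], prots[[2]], prots[[3]])
    expect_gte(sp, 0.9 * opt)
  }
})

test_that("intron positions map through the alignment with phase", {
  # two identical genes: ATG AAA AAT | intron 19 | GAA TAA  (split at nt 9)
  seqs <- paste0("ATGAAAAAT", "GTTTAATTAATTAACCAAG", "GAATAA")
  g <- nm_genome("toy", c(c1 = paste0(seqs, strrep("T", 20)),
                          c2 = paste0(seqs, strrep("T", 20))))
  genes <- list(
    mk_intron_gene("gA", "c1", c(0, 9, 28, 34)),
    mk_intron_gene("gB", "c2", c(0, 9, 28, 34)))
  ann <- nm_annotation("toy", genes)
  prot <- vapply(genes, function(x) translate_gene(x, g), character(1L))
  names(prot) <- c("gA", "gB")
  msa <- align_family(prot)
  pos <- map_intron_positions("fam1", msa, list(toy = ann))
  expect_identical(nrow(pos), 2L)
  expect_identical(pos$alignment_column[1], pos$alignment_column[2])
  expect_identical(pos$phase[1], pos$phase[2])
  expect_identical(pos$phase[1], 0L)  # splice after 9 nt = codon boundary

  # shifting one intron by one codon breaks identity
  g2 <- nm_genome("toy", c(
    c1 = paste0("ATGAAAAAT", "GTTTAATTAATTAACCAAG", "GAATAA", strrep("T", 20)),
    c2 = paste0("ATGAAAAATGAA", "GTTTAATTAATTAACCAAG", "TAA", strrep("T", 20))))
  genes2 <- list(
    mk_intron_gene("gA", "c1", c(0, 9, 28, 34)),
    mk_intron_gene("gB", "c2", c(0, 12, 31, 34)))
  ann2 <- nm_annotation("toy", genes2)
  prot2 <- vapply(genes2, function(x) translate_gene(x, g2), character(1L))
  names(prot2) <- c("gA", "gB")
  pos2 <- map_intron_positions("fam1", align_family(prot2),
                               list(toy = ann2))
  expect_false(pos2$alignment_column[1] == pos2$alignment_column[2] &&
                 pos2$phase[1] == pos2$phase[2])

  # an intron immediately after the start codon maps to column 1 without
  # underflow
  g3 <- nm_genome("toy", c(c1 = paste0(
    "ATG", "GTTTAATTAATTAACCAAG", "AAAGAATAA", strrep("T", 20))))
  genes3 <- list(mk_intron_gene("gC", "c1", c(0, 3, 22, 31)))
  ann3 <- nm_annotation("toy", genes3)
  prot3 <- c(gC = translate_gene(genes3[[1]], g3),
             gD = translate_gene(genes3[[1]], g3))
  # map against a two-member alignment of identical proteins
  msa3 <- align_family(prot3)
  msa3$ids <- "gC"
  msa3$rows <- msa3$rows["gC"]
  pos3 <- map_intron_positions("fam1", msa3, list(toy = ann3))
  expect_identical(pos3$alignment_column, 2L)
  expect_identical(pos3$phase, 0L)
})

test_that("conservation summaries count sites and occurrences correctly", {
  # all genomes identical -> (100, 100)
  pos <- expand.grid(genome = c("g1", "g2", "g3", "g4"),
                     alignment_column = c(5L, 9L, 12L),
                     stringsAsFactors = FALSE)
  pos$family_id <- "famA"
  pos$gene_id <- paste0(pos$genome, "_x")
  pos$phase <- 0L
  s <- conservation_summary(pos, n_genomes = 4)
  expect_equal(s$pct_identical_all, 100)
  expect_equal(s$pct_shared_ge2, 100)

  # 10-site fixture: 3 sites in all 4 genomes, 5 more in 2, 2 singletons
  rows <- list()
  add <- function(col, genomes) {
    for (g in genomes) {
      rows[[length(rows) + 1L]] <<- data.frame(
        family_id = "famB", genome = g, gene_id = paste0(g, "_y"),
        alignment_column = col, phase = 0L, stringsAsFactors = FALSE)
    }
  }
  for (col in 1:3) add(col, c("g1", "g2", "g3", "g4"))
  for (col in 4:8) add(col, c("g1", "g2"))
  add(9L, "g3")
  add(10L, "g4")
  fix <- do.call(rbind, rows)
  s2 <- conservation_summary(fix, n_genomes = 4)
  expect_identical(s2$n_sites, 10L)
  expect_equal(s2$pct_identical_all, 30)
  expect_equal(s2$pct_shared_ge2, 80)

  # occurrence weighting uses intron records as the denominator
  s3 <- conservation_summary(fix, n_genomes = 4, unit = "occurrence")
  expect_equal(s3$pct_identical_all, 100 * 12 / 24)
  expect_equal(s3$pct_shared_ge2, 100 * 22 / 24)
  # invariant: shared >= identical
  expect_gte(s2$pct_shared_ge2, s2$pct_identical_all)
  expect_gte(s3$pct_shared_ge2, s3$pct_identical_all)
})

test_that("oversized introns are flagged with relict internal AG positions", {
  # 40-nt intron: GT + 16 nt + AG + 18 nt + AG, relict AG at prefix 20
  intron40 <- paste0("GT", strrep("TA", 8), "AG", strrep("TC", 9), "AG")
  expect_identical(nchar(intron40), 40L)
  seq <- paste0("ATGAAAAAT", intron40, "GAATAA", strrep("T", 20))
  g <- nm_genome("toy", c(c1 = seq))
  gene <- mk_intron_gene("g1", "c1", c(0, 9, 49, 55))
  ann <- nm_annotation("toy", list(gene))
  res <- detect_oversized_introns(ann, g)
  expect_identical(nrow(res), 1L)
  expect_identical(res$length, 40L)
  expect_identical(res$relict_ag, "20")

  # annotations whose introns are all <= 23 nt yield nothing
  tr <- small_sim()
  expect_identical(nrow(detect_oversized_introns(tr$annotation, tr$genome)),
                   0L)

  # oversized intron without an in-range internal AG: flagged, empty relict
  intron40b <- paste0("GT", strrep("TC", 18), "AG")
  seq2 <- paste0("ATGAAAAAT", intron40b, "GAATAA", strrep("T", 20))
  g2 <- nm_genome("toy", c(c1 = seq2))
  ann2 <- nm_annotation("toy", list(mk_intron_gene("g1", "c1",
                                                   c(0, 9, 49, 55))))
  res2 <- detect_oversized_introns(ann2, g2)
  expect_identical(res2$relict_ag, "")
})
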