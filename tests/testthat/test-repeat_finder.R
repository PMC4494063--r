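# Telomeres, shared subtelomeric units, exact duplicated regions and
# pseudogene fragments.

test_that("terminal tandem repeats are detected with the smallest period", {
  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # right end: G-rich motif reads on the forward strand
  t <- detect_telomere(paste0(bg, strrep("TCTAGGG", 8)), "right",
                       chromosome_id = "c1")
  expect_identical(t$motif, "AGGGTCT")  # canonical rotation of TCTAGGG
  expect_identical(t$copies, 8)
  # left end: the G-rich strand is the reverse strand
  tl <- detect_telomere(paste0(oracle_revcomp(strrep("TCTAGGG", 8)), bg),
                        "left", chromosome_id = "c1")
  expect_identical(tl$motif, "AGGGTCT")
  expect_identical(tl$copies, 8)
  expect_identical(tl$span, c(0L, 56L))
})

test_that("random termini yield no telomere call", {
  set.seed(32)
  chrom <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  t <- detect_telomere(chrom, "left")
  # oracle: no period <= 10 with >= 3 terminal copies
  v <- strsplit(chrom, "")[[1]]
  has <- FALSE
  for (p in 1:10) {
    run <- p
    i <- p + 1
    while (i <= length(v) && v[i] == v[i - p]) {
      run <- run + 1
      i <- i + 1
    }
    if (run / p >= 3) has <- TRUE
  }
  expect_false(has)
  expect_null(t)
})

test_that("a period-14 spelling of a 7-mer repeat is reported as period 7", {
  chrom <- paste0(strrep("CAA", 60), strrep("TCTAGGGTCTAGGG", 5))
  t <- detect_telomere(chrom, "right")
  expect_identical(nchar(t$motif_observed), 7L)
  expect_identical(t$copies, 10)
})

test_that("the shared subtelomeric unit is found at all ends only", {
  set.seed(33)
  unit <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  mk <- function(left_fwd, right_fwd) {
    paste0(if (left_fwd) unit else oracle_revcomp(unit), rnd(20000),
           if (right_fwd) unit else oracle_revcomp(unit))
  }
  g <- nm_genome("toy", c(c1 = mk(TRUE, FALSE), c2 = mk(FALSE, TRUE),
                          c3 = mk(TRUE, TRUE)))
  res <- find_shared_terminal_repeat(g, search_depth = 8000)
  expect_identical(res$unit_length, 5000L)
  expect_identical(nrow(res$occurrences), 6L)
  expect_setequal(res$occurrences$end, c("left", "right"))

  # three random chromosomes share nothing >= 100 bp
  g2 <- nm_genome("toy", c(c1 = rnd(20000), c2 = rnd(20000),
                           c3 = rnd(20000)))
  expect_identical(find_shared_terminal_repeat(g2, 8000)$unit_length, 0L)

  # unit planted at only 5 of 6 ends does not qualify
  g3 <- nm_genome("toy", c(c1 = mk(TRUE, FALSE), c2 = mk(FALSE, TRUE),
                           c3 = paste0(unit, rnd(20000), rnd(5000))))
  expect_identical(find_shared_terminal_repeat(g3, 8000)$unit_length, 0L)
})

test_that("planted exact duplications are found exactly and maximally", {
  set.seed(34)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  block <- rnd(2000)
  # pin distinct flanking characters so the maximal region is exactly the
  # planted block
  c1 <- paste0(rnd(3999), "A", block, "A", rnd(3999))
  c2 <- paste0(rnd(2999), "C", block, "C", rnd(4999))
  g <- nm_genome("toy", c(c1 = c1, c2 = c2))
  d <- find_duplicated_regions(g, min_len = 1000)
  expect_identical(nrow(d), 1L)
  expect_identical(d$length, 2000L)
  expect_identical(d$placement, "inter")
  expect_identical(d$orientation, "same")
  expect_identical(c(d$start_a, d$end_a), c(4000L, 6000L))
  expect_identical(c(d$start_b, d$end_b), c(3000L, 5000L))
  # exact identity and maximality by direct substring comparison
  sa <- substr(c1, d$start_a + 1, d$end_a)
  sb <- substr(c2, d$start_b + 1, d$end_b)
  expect_identical(sa, sb)
  expect_false(substr(c1, d$start_a, d$end_a) ==
                 substr(c2, d$start_b, d$end_b))
  expect_false(substr(c1, d$start_a + 1, d$end_a + 1) ==
                 substr(c2, d$start_b + 1, d$end_b + 1))
})

test_that("duplication discovery equals the quadratic oracle on toys", {
  set.seed(35)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  blockA <- rnd(700)
  blockB <- rnd(550)
  c1 <- paste0(rnd(1100), blockA, rnd(900), oracle_revcomp(blockB),
               rnd(700))
  c2 <- paste0(rnd(500), blockB, rnd(800), blockA, rnd(900))
  seqs <- c(c1 = c1, c2 = c2)
  g <- nm_genome("toy", seqs)
  got <- find_duplicated_regions(g, min_len = 500)
  exp <- oracle_exact_repeats(seqs, 500L)
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "length", "orientation")
  expect_identical(got[, cols], exp[, cols])

  # random toy genome has no repeat >= 500
  g3 <- nm_genome("toy", c(c1 = rnd(3000), c2 = rnd(3000)))
  expect_identical(nrow(find_duplicated_regions(g3, 500)), 0L)
  expect_null(oracle_exact_repeats(c(c1 = g3$chromosomes[[1]],
                                     c2 = g3$chromosomes[[2]]), 500L))
})

test_that("a wholly duplicated chromosome yields one maximal region", {
  set.seed(36)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  g <- nm_genome("toy", c(c1 = s, c2 = s))
  d <- find_duplicated_regions(g, min_len = 1000)
  expect_identical(nrow(d), 1L)
  expect_identical(d$length, 5000L)
})

test_that("duplicated-region lengths are invariant under reverse complement", {
  set.seed(37)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  block <- rnd(1200)
  g <- nm_genome("toy", c(c1 = paste0(rnd(2000), block, rnd(2000)),
                          c2 = paste0(rnd(1000), block, rnd(3000))))
  d1 <- find_duplicated_regions(g, 1000)
  g2 <- g
  g2$chromosomes[["c2"]] <- oracle_revcomp(g2$chromosomes[["c2"]])
  d2 <- find_duplicated_regions(g2, 1000)
  expect_identical(sort(d1$length), sort(d2$length))
  expect_identical(d2$orientation, "inverted")
})

test_that("excluded intervals suppress subtelomeric self-matches", {
  tr <- small_sim()
  excl <- rbind(tr$subtelomeres[, c("chromosome_id", "start", "stop")],
                tr$telomeres[, c("chromosome_id", "start", "stop")])
  excl$start <- pmax(0L, excl$start - 60L)
  excl$stop <- excl$stop + 60L
  d <- find_duplicated_regions(tr$genome, 1000, exclude = excl)
  expect_identical(nrow(d), 0L)
})

test_that("complete and partial genes in duplicated regions are counted", {
  genes <- list(
    gene_model("a", "c1", "+", matrix(c(100L, 400L), ncol = 2)),
    gene_model("b", "c1", "+", matrix(c(500L, 800L), ncol = 2)),
    gene_model("c", "c1", "+", matrix(c(850L, 1200L), ncol = 2)))
  ann <- nm_annotation("toy", genes)
  regions <- data.frame(chrom_a = "c1", start_a = 50L, end_a = 900L,
                        chrom_b = "c2", start_b = 0L, end_b = 850L,
                        length = 850L, orientation = "same",
                        placement = "inter", stringsAsFactors = FALSE)
  r <- annotate_duplicated_genes(regions, ann)
  expect_identical(r$complete_genes, 2L)  # a, b inside; c straddles
  expect_identical(r$partial_genes, 1L)
  expect_identical(attr(r, "totals"), c(complete = 2L, partial = 1L))

  # region exactly covering two genes
  regions2 <- data.frame(chrom_a = "c1", start_a = 100L, end_a = 800L,
                         chrom_b = "c2", start_b = 0L, end_b = 700L,
                         length = 700L, orientation = "same",
                         placement = "inter", stringsAsFactors = FALSE)
  r2 <- annotate_duplicated_genes(regions2, ann)
  expect_identical(r2$complete_genes, 2L)
  expect_identical(r2$partial_genes, 0L)
})

test_that("planted duplications in evolved genomes are fully recovered", {
  tr <- generate_ancestor(sim_params(
    seed = 402, n_chromosomes = 2, chromosome_length = 45000, n_genes = 25,
    subtelomere_length = 1500, verify_unique = FALSE))
  sp <- evolve_species(tr, evolve_events(duplications = 3), seed = 8,
                       species = "spD")
  expect_gte(nrow(sp$duplications), 2L)  # placement can reject at most one
  excl <- rbind(sp$subtelomeres[, c("chromosome_id", "start", "stop")],
                sp$telomeres[, c("chromosome_id", "start", "stop")])
  excl$start <- pmax(0L, excl$start - 60L)
  excl$stop <- excl$stop + 60L
  d <- find_duplicated_regions(sp$genome, 1000, exclude = excl)
  sc <- score_predictions(sp, sp$annotation, predicted_dups = d)
  expect_identical(sc$duplication_recall, 1)
})

test_that("3'-terminal pseudogene fragments are flagged within families", {
  tr <- small_sim()
  prot <- tr$proteins
  full_ids <- names(prot)[1:2]
  frag <- substr(prot[[full_ids[1]]],
                 nchar(prot[[full_ids[1]]]) %/% 2 + 1,
                 nchar(prot[[full_ids[1]]]))
  prot <- c(prot, frag9 = frag)
  fams <- data.frame(
    family_id = c("famA", "famA", "famB"),
    gene_id = c(full_ids[1], "frag9", full_ids[2]),
    stringsAsFactors = FALSE)
  res <- find_pseudogene_fragments(tr$annotation, prot, fams)
  expect_identical(res$gene_id, "frag9")
  expect_identical(res$side, "3prime")
  # full-length members are never flagged; singleton families neither
  expect_false(full_ids[1] %in% res$gene_id)
  expect_false(full_ids[2] %in% res$gene_id)
})
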