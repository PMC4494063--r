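# Spliced-ORF gene calling with ultrasmall introns.

test_that("intron candidate enumeration matches a brute-force scan", {
  # constructed single candidate
  s <- paste0(strrep("C", 30), "GT", strrep("A", 16), "AG", strrep("C", 30))
  cand <- enumerate_intron_candidates(s, "+", caller_params())
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$length, 20L)
  expect_identical(cand$start, 30L)
  expect_identical(cand$end, 50L)

  # no AG anywhere -> empty
  expect_identical(
    nrow(enumerate_intron_candidates(strrep("GTC", 40), "+",
                                     caller_params())), 0L)

  # random sequence vs brute-force oracle, both strands
  set.seed(77)
  rseq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                       prob = c(.36, .14, .14, .36)), collapse = "")
  for (strand in c("+", "-")) {
    got <- enumerate_intron_candidates(rseq, strand, caller_params())
    target <- if (strand == "+") rseq else oracle_revcomp(rseq)
    exp <- oracle_intron_candidates(target, 18L, 23L)
    if (strand == "-") {
      exp <- cbind(2000L - exp[, 2L], 2000L - exp[, 1L])
    }
    exp <- exp[order(exp[, 1L], exp[, 2L]), , drop = FALSE]
    expect_identical(cbind(got$start, got$end), unname(exp))
  }
})

test_that("a planted intronless ORF is recovered with its exact protein", {
  set.seed(5)
  pool <- nucmorph:::sense_codon_pool(0.28)
  cds <- paste0("ATG", paste(sample(pool$codons, 59, TRUE, pool$weights),
                             collapse = ""), "TAA")
  guard <- strrep("TTAATTAATTAA", 3)
  chrom <- paste0(strrep("C", 40), guard, cds, guard, strrep("C", 40))
  genes <- call_genes(chrom, caller_params(), "c1")
  expect_length(genes, 1L)
  expect_identical(nrow(genes[[1]]$exons), 1L)
  expect_identical(unname(attr(genes, "proteins")[1]), oracle_translate(cds))
})

test_that("a 19-nt GT..AG insert is spliced out, recovering the protein", {
  set.seed(6)
  pool <- nucmorph:::sense_codon_pool(0.28)
  cds <- paste0("ATG", paste(sample(pool$codons, 59, TRUE, pool$weights),
                             collapse = ""), "TAA")
  intron <- paste0("GT", "TTAATTAATTAA", "CAT", "AG")  # 19 nt, guarded
  at <- 90  # codon 30
  interrupted <- paste0(substr(cds, 1, at), intron,
                        substr(cds, at + 1, nchar(cds)))
  guard <- strrep("TTAATTAATTAA", 3)
  chrom <- paste0(strrep("C", 40), guard, interrupted, guard, strrep("C", 40))
  genes <- call_genes(chrom, caller_params(), "c1")
  expect_length(genes, 1L)
  expect_identical(nrow(genes[[1]]$exons), 2L)
  expect_identical(unname(attr(genes, "proteins")[1]), oracle_translate(cds))
  intr <- gene_introns(genes[[1]])
  expect_identical(intr$length, 19L)
})

test_that("ORFs below the minimum protein length are discarded", {
  set.seed(7)
  pool <- nucmorph:::sense_codon_pool(0.28)
  cds49 <- paste0("ATG", paste(sample(pool$codons, 48, TRUE, pool$weights),
                               collapse = ""), "TAA")
  guard <- strrep("TTAATTAATTAA", 3)
  chrom <- paste0(guard, cds49, guard)
  expect_length(call_genes(chrom, caller_params(), "c1"), 0L)
  # the same protein passes at a lower threshold
  expect_length(call_genes(chrom, caller_params(min_protein_aa = 40), "c1"),
                1L)
})

test_that("on intronless genomes the caller equals a six-frame ORF finder", {
  tr <- generate_ancestor(sim_params(
    seed = 88, n_chromosomes = 1, chromosome_length = 15000, n_genes = 8,
    introns_per_gene_mean = 0, subtelomere_length = 800,
    verify_unique = FALSE))
  chrom <- tr$genome$chromosomes[[1]]
  # splicing disabled: with no introns planted the caller should reduce to
  # a plain ORF finder (with splicing enabled it may legitimately open
  # longer spliced readings in random non-coding sequence)
  got <- call_genes(chrom, caller_params(max_introns_per_gene = 0), "chr1")

  # oracle: plain six-frame ATG..stop ORF finder with the same greedy
  # overlap resolution
  orf_scan <- function(s) {
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    out <- NULL
    for (f in 0:2) {
      starts <- seq(f + 1, n - 2, 3)
      codons <- paste0(v[starts], v[starts + 1], v[starts + 2])
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      prev <- 0L
      for (si in stops) {
        seg <- codons[(prev + 1L):si]
        atg <- which(seg == "ATG")
        if (length(atg) > 0L) {
          a <- prev + atg[1L]
          aa_len <- si - a  # codons between ATG and stop, excl stop
          if (aa_len >= 50L) {
            out <- rbind(out, c(starts[a] - 1L, starts[si] + 2L))
          }
        }
        prev <- si
      }
    }
    out
  }
  n <- nchar(chrom)
  fw <- orf_scan(chrom)
  rc <- orf_scan(oracle_revcomp(chrom))
  models <- NULL
  if (!is.null(fw)) models <- rbind(models, cbind(fw, 1L))
  if (!is.null(rc)) models <- rbind(models,
                                    cbind(n - rc[, 2L], n - rc[, 1L], 2L))
  # greedy overlap resolution: by length desc, then leftmost, then "+"
  len <- models[, 2L] - models[, 1L]
  ord <- order(-len, models[, 1L], models[, 3L])
  acc <- NULL
  for (i in ord) {
    if (!is.null(acc) &&
        any(models[i, 1L] < acc[, 2L] & models[i, 2L] > acc[, 1L])) next
    acc <- rbind(acc, models[i, , drop = FALSE])
  }
  acc <- acc[order(acc[, 1L]), , drop = FALSE]
  storage.mode(acc) <- "integer"
  got_spans <- t(vapply(got, function(g) {
    c(g$exons[1L, 1L], g$exons[nrow(g$exons), 2L])
  }, integer(2L)))
  dimnames(got_spans) <- NULL
  expect_identical(got_spans, unname(acc[, 1:2]))
  expect_true(all(vapply(got, function(g) nrow(g$exons), integer(1L)) == 1L))
})

test_that("translation matches an independent codon-table oracle", {
  g <- nm_genome("toy", c(c1 = "ATGAAATAA"))
  gene <- gene_model("g1", "c1", "+", matrix(c(0L, 9L), ncol = 2),
                     category = "ORFan")
  expect_identical(translate_gene(gene, g), "MK")

  # minus-strand gene equals its plus-strand reverse-complement twin
  g2 <- nm_genome("toy", c(c1 = oracle_revcomp("ATGAAATAA")))
  gene2 <- gene_model("g1", "c1", "-", matrix(c(0L, 9L), ncol = 2),
                      category = "ORFan")
  expect_identical(translate_gene(gene2, g2), "MK")

  # 100 synthetic genes vs seqinr
  tr <- small_sim()
  prot_genes <- Filter(nucmorph:::is_protein_coding, tr$annotation$genes)
  for (gene in prot_genes) {
    cds <- nucmorph:::spliced_cds(gene, tr$genome)
    expect_identical(translate_gene(gene, tr$genome), oracle_translate(cds))
  }
  # internal stop raises with the codon index
  g3 <- nm_genome("toy", c(c1 = "ATGTAAAAATAA"))
  gene3 <- gene_model("g1", "c1", "+", matrix(c(0L, 12L), ncol = 2),
                      category = "ORFan")
  expect_error(translate_gene(gene3, g3), "codon index 2")
})

test_that("classification by homology hits follows the e-value cutoff", {
  hits <- data.frame(query_id = c("g1", "g2"), evalue = c(1e-10, 0.01),
                     stringsAsFactors = FALSE)
  expect_identical(classify_gene("g1", hits), "function-predicted")
  expect_identical(classify_gene("g2", hits), "ORFan")  # 0.01 > 0.001
  expect_identical(classify_gene("g3", hits), "ORFan")  # absent
})

test_that("called introns always satisfy length and boundary invariants", {
  tr <- small_sim()
  ann <- annotate_genome(tr$genome)
  intr <- annotation_introns(ann, tr$genome)
  expect_true(all(intr$length >= 18L & intr$length <= 23L))
  expect_true(all(intr$boundary == "GTAG"))
  # spliced length divisible by 3 for every model
  for (g in ann$genes) {
    expect_identical(sum(g$exons[, 2L] - g$exons[, 1L]) %% 3L, 0L)
  }
})

test_that("planted genes are recovered exactly on a synthetic genome", {
  tr <- small_sim()
  ann <- annotate_genome(tr$genome)
  sc <- score_predictions(tr, ann)
  expect_gte(sc$gene_recall, 0.95)
  expect_gte(sc$intron_recall, 0.90)
  expect_identical(sc$protein_exact, 1)
})
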