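# Local alignment, e-values, family construction, synteny blocks and the
# missing-gene screen.

test_that("local alignment equals the quadratic DP oracle", {
  mat <- blosum62_matrix()
  # self-alignment of a 10-mer scores the diagonal sum
  p <- "MKLVNFYWCD"
  a <- align_local(p, p)
  expect_identical(a$score,
                   sum(vapply(strsplit(p, "")[[1]],
                              function(ch) mat[ch, ch], numeric(1L))))
  # random 30-mers, several seeds
  set.seed(41)
  aas <- rownames(mat)[1:20]
  for (i in 1:8) {
    x <- paste(sample(aas, 30, TRUE), collapse = "")
    y <- paste(sample(aas, 30, TRUE), collapse = "")
    got <- align_local(x, y)$score
    expect_identical(got, oracle_local_score(x, y))
    # score symmetry
    expect_identical(align_local(y, x)$score, got)
  }
  expect_error(align_local("", "MK"), "empty")
})

test_that("Karlin-Altschul e-values follow the closed form", {
  K <- 0.041; lambda <- 0.267
  m <- 250; n <- 400
  s <- log(K * m * n) / lambda
  expect_equal(estimate_evalue(s, m, n, K, lambda), 1.0)
  # doubling both lengths quadruples E at fixed score
  e1 <- estimate_evalue(60, m, n, K, lambda)
  e2 <- estimate_evalue(60, 2 * m, 2 * n, K, lambda)
  expect_equal(e2 / e1, 4)
  # spot value vs direct evaluation
  expect_equal(estimate_evalue(50, 300, 300, 0.041, 0.267),
               0.041 * 300 * 300 * exp(-0.267 * 50))
})

test_that("single-linkage families equal connected components", {
  hits <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                     evalue = c(1e-10, 1e-8), stringsAsFactors = FALSE)
  fam <- build_families(hits, 0.001)
  expect_identical(length(unique(fam$family_id)), 1L)
  expect_setequal(fam$gene_id, c("a", "b", "c"))

  # no qualifying edges -> all singletons
  fam2 <- build_families(hits[0, ], 0.001, all_genes = c("x", "y", "z"))
  expect_identical(length(unique(fam2$family_id)), 3L)

  # random graphs vs BFS oracle
  set.seed(42)
  for (rep in 1:5) {
    verts <- sprintf("v%02d", 1:20)
    e <- data.frame(query_id = sample(verts, 15, TRUE),
                    subject_id = sample(verts, 15, TRUE),
                    evalue = 10^(-sample(1:8, 15, TRUE)),
                    stringsAsFactors = FALSE)
    fam3 <- build_families(e, 0.001, all_genes = verts)
    keep <- e$evalue < 0.001 & e$query_id != e$subject_id
    comps <- oracle_components(verts,
                               as.matrix(e[keep, c("query_id", "subject_id")]))
    got <- split(fam3$gene_id, fam3$family_id)
    norm <- function(x) sort(vapply(x, function(s) paste(sort(s),
                                                         collapse = ","),
                                    character(1L)))
    expect_identical(unname(norm(got)), unname(norm(comps)))
  }
})

test_that("identical gene orders give one same-orientation block", {
  a <- toy_gene_order("A", sprintf("f%02d", 1:10))
  b <- toy_gene_order("B", sprintf("f%02d", 1:10))
  fam <- toy_families(list(a, b), list(sprintf("f%02d", 1:10),
                                       sprintf("f%02d", 1:10)))
  blocks <- find_synteny_blocks(a, b, fam)
  expect_length(blocks, 1L)
  expect_identical(blocks[[1]]$size, 10L)
  expect_identical(blocks[[1]]$orientation, "same")
})

test_that("a segment inversion splits into a same and an inverted block", {
  labs_a <- c("a", "b", "c", "d", "e", "f")
  labs_b <- c("a", "b", "c", "f", "e", "d")
  A <- toy_gene_order("A", labs_a)
  B <- toy_gene_order("B", labs_b)
  fam <- toy_families(list(A, B), list(labs_a, labs_b))
  blocks <- find_synteny_blocks(A, B, fam, min_genes = 3)
  expect_length(blocks, 2L)
  sizes <- sort(vapply(blocks, `[[`, integer(1L), "size"))
  expect_identical(sizes, c(3L, 3L))
  expect_setequal(vapply(blocks, `[[`, character(1L), "orientation"),
                  c("same", "inverted"))
  # matches the exhaustive oracle total
  exp_total <- oracle_chain_packing_total(1:6, match(labs_b, labs_a),
                                          max_gap = 3, min_genes = 3)
  expect_identical(sum(sizes), exp_total)
})

test_that("block detection is symmetric under swapping genomes", {
  set.seed(43)
  for (rep in 1:5) {
    labs_a <- sprintf("f%02d", 1:9)
    labs_b <- sample(labs_a)
    A <- toy_gene_order("A", labs_a)
    B <- toy_gene_order("B", labs_b)
    fam <- toy_families(list(A, B), list(labs_a, labs_b))
    ab <- find_synteny_blocks(A, B, fam, min_genes = 3)
    ba <- find_synteny_blocks(B, A, fam, min_genes = 3)
    sz <- function(bl) sort(vapply(bl, `[[`, integer(1L), "size"))
    expect_identical(sz(ab), sz(ba))
    expect_identical(sort(vapply(ab, `[[`, character(1L), "orientation")),
                     sort(vapply(ba, `[[`, character(1L), "orientation")))
  }
})

test_that("raising min_genes never increases the number of blocked genes", {
  set.seed(44)
  for (rep in 1:5) {
    labs_a <- sprintf("f%02d", 1:12)
    labs_b <- sample(labs_a)
    A <- toy_gene_order("A", labs_a)
    B <- toy_gene_order("B", labs_b)
    fam <- toy_families(list(A, B), list(labs_a, labs_b))
    totals <- vapply(c(3L, 4L, 5L), function(mg) {
      sum(vapply(find_synteny_blocks(A, B, fam, min_genes = mg), `[[`,
                 integer(1L), "size"))
    }, integer(1L))
    expect_true(all(diff(totals) <= 0L))
    expect_true(all(vapply(find_synteny_blocks(A, B, fam, min_genes = 4),
                           `[[`, integer(1L), "size") >= 4L))
  }
})

test_that("block summaries report mean size and count", {
  mk <- function(size) list(size = size)
  expect_identical(block_summary(structure(list(mk(4L), mk(6L)),
                                           class = "nm_synteny")),
                   c(mean_genes = 5, n_blocks = 2))
  expect_identical(block_summary(structure(list(), class = "nm_synteny")),
                   c(mean_genes = 0, n_blocks = 0))
  expect_identical(block_summary(structure(list(mk(4L)),
                                           class = "nm_synteny")),
                   c(mean_genes = 4, n_blocks = 1))
})

test_that("syntenic ORFans are matched to their positional counterparts", {
  labs_a <- c("f1", "f2", NA, "f3", "f4")   # NA = the ORFan
  labs_b <- c("f1", "f2", NA, "f3", "f4")   # counterpart gene at same slot
  A <- toy_gene_order("A", labs_a, orfan = 3L)
  B <- toy_gene_order("B", labs_b)
  fam <- toy_families(list(A, B), list(labs_a, labs_b))
  blocks <- find_synteny_blocks(A, B, fam, min_genes = 2, max_gap = 3)
  res <- find_syntenic_orfans(blocks, A, B, fam)
  expect_identical(res$orfan_id, "A_t03")
  expect_identical(res$counterpart_id, "B_t03")
  expect_false(any(res$split))

  # no ORFans -> empty
  A2 <- toy_gene_order("A", c("f1", "f2", "f3", "f4"))
  B2 <- toy_gene_order("B", c("f1", "f2", "f3", "f4"))
  fam2 <- toy_families(list(A2, B2), list(c("f1", "f2", "f3", "f4"),
                                          c("f1", "f2", "f3", "f4")))
  blocks2 <- find_synteny_blocks(A2, B2, fam2)
  expect_identical(nrow(find_syntenic_orfans(blocks2, A2, B2, fam2)), 0L)
})

test_that("the missing-gene screen hits identical queries and no decoys", {
  tr <- small_sim()
  prot <- tr$proteins[1:5]
  # identical query vs target -> reported
  hits <- screen_missing_genes(prot[1], prot)
  expect_true(any(hits$subject_id == names(prot)[1]))
  # empty target set -> empty
  expect_identical(nrow(screen_missing_genes(prot, character(0))), 0L)
  # shuffled decoys -> no hit below 1e-5
  set.seed(45)
  decoys <- vapply(prot, function(p) {
    paste(sample(strsplit(p, "")[[1]]), collapse = "")
  }, character(1L))
  names(decoys) <- paste0("decoy_", seq_along(decoys))
  hits2 <- screen_missing_genes(decoys, tr$proteins[6:10])
  expect_identical(nrow(hits2), 0L)
})
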