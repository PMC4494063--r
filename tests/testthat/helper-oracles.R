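# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives an expected value by brute force or through an
# unrelated code path, never through the implementation it checks.

# --- sequences ------------------------------------------------------------

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# translation via seqinr (independent codon table)
oracle_translate <- function(cds) {
  aa <- seqinr::translate(strsplit(tolower(cds), "")[[1]])
  paste(aa[aa != "*"], collapse = "")
}

# brute-force scan for GT..AG windows of length within [lo, hi]
oracle_intron_candidates <- function(seq, lo, hi) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  out <- NULL
  for (s in seq_len(n)) {
    for (L in lo:hi) {
      e <- s + L - 1L
      if (e > n) next
      if (v[s] == "G" && v[s + 1L] == "T" &&
          v[e - 1L] == "A" && v[e] == "G") {
        out <- rbind(out, c(s - 1L, e))  # 0-based half-open
      }
    }
  }
  out
}

# --- alignment ------------------------------------------------------------

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- as.matrix(e$BLOSUM62)
    }
    cache
  }
})

# quadratic affine-gap Smith-Waterman score (Gotoh), BLAST-style costs:
# a gap of length L costs open + L * extend
oracle_local_score <- function(a, b, open = 11, extend = 1,
                               mat = NULL) {
  if (is.null(mat)) mat <- blosum62_matrix()
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (consumes a)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open - extend,
                               E[i + 1L, j] - extend)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - open - extend,
                               F[i, j + 1L] - extend)
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + mat[va[i], vb[j]],
                               E[i + 1L, j + 1L],
                               F[i + 1L, j + 1L])
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# sum-of-pairs score of an MSA (linear gaps) and the 3-way DP optimum
sp_score_pair <- function(x, y, mat, gap) {
  s <- 0
  for (k in seq_along(x)) {
    if (x[k] == "-" && y[k] == "-") next
    if (x[k] == "-" || y[k] == "-") s <- s + gap
    else s <- s + mat[x[k], y[k]]
  }
  s
}

oracle_msa3_optimum <- function(p1, p2, p3, gap = -5, mat = NULL) {
  if (is.null(mat)) mat <- blosum62_matrix()
  v1 <- strsplit(p1, "")[[1]]; v2 <- strsplit(p2, "")[[1]]
  v3 <- strsplit(p3, "")[[1]]
  n1 <- length(v1); n2 <- length(v2); n3 <- length(v3)
  D <- array(-Inf, dim = c(n1 + 1L, n2 + 1L, n3 + 1L))
  D[1, 1, 1] <- 0
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    cur <- D[i + 1L, j + 1L, k + 1L]
    if (!is.finite(cur)) next
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0L) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii > n1 || jj > n2 || kk > n3) next
      c1 <- if (di == 1L) v1[ii] else "-"
      c2 <- if (dj == 1L) v2[jj] else "-"
      c3 <- if (dk == 1L) v3[kk] else "-"
      pairsc <- function(x, y) {
        if (x == "-" && y == "-") 0
        else if (x == "-" || y == "-") gap
        else mat[x, y]
      }
      s <- pairsc(c1, c2) + pairsc(c1, c3) + pairsc(c2, c3)
      val <- cur + s
      if (val > D[ii + 1L, jj + 1L, kk + 1L]) {
        D[ii + 1L, jj + 1L, kk + 1L] <- val
      }
    }
  }
  D[n1 + 1L, n2 + 1L, n3 + 1L]
}

# --- graphs ---------------------------------------------------------------

# connected components by hand-rolled BFS
oracle_components <- function(vertices, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (v in vertices) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  split(names(comp), comp)
}

# --- exact repeats --------------------------------------------------------

# quadratic diagonal scan for maximal exact repeats >= min_len between (and
# within) chromosomes, forward and reverse-complement; sequences are coded
# as integers and diagonals without a long enough run are rejected cheaply
oracle_exact_repeats <- function(seqs, min_len) {
  ids <- names(seqs)
  code <- function(x) match(strsplit(x, "")[[1]], c("A", "C", "G", "T", "N"))
  out <- NULL
  add <- function(ca, a0, a1, cb, b0, b1, orient) {
    # canonical ordering to match the package output
    if (ca > cb || (ca == cb && b0 < a0)) {
      tmp <- ca; ca <- cb; cb <- tmp
      tmp <- a0; a0 <- b0; b0 <- tmp
      tmp <- a1; a1 <- b1; b1 <- tmp
    }
    out <<- rbind(out, data.frame(
      chrom_a = ca, start_a = a0, end_a = a1, chrom_b = cb,
      start_b = b0, end_b = b1, length = a1 - a0, orientation = orient,
      stringsAsFactors = FALSE))
  }
  scan_pair <- function(ca, va, cb, vb, orient, self_same) {
    n <- length(va); m <- length(vb)
    for (d in (-(n - 1L)):(m - 1L)) {
      i0 <- max(1L, 1L - d)
      j0 <- i0 + d
      len <- min(n - i0, m - j0) + 1L
      if (len < min_len) next
      if (self_same && d == 0L) next
      eq <- va[i0:(i0 + len - 1L)] == vb[j0:(j0 + len - 1L)]
      bad <- which(!eq)
      runs <- diff(c(0L, bad, len + 1L)) - 1L
      if (max(runs) < min_len) next
      starts <- c(1L, bad + 1L)
      for (k in which(runs >= min_len)) {
        ai <- i0 + starts[k] - 1L
        bi <- j0 + starts[k] - 1L
        L <- runs[k]
        if (orient == "same") {
          add(ca, ai - 1L, ai + L - 1L, cb, bi - 1L, bi + L - 1L, "same")
        } else {
          # vb is the reverse complement of chromosome cb: map back
          fb0 <- m - (bi + L - 1L)
          fb1 <- m - bi + 1L
          add(ca, ai - 1L, ai + L - 1L, cb, fb0, fb1, "inverted")
        }
      }
    }
  }
  rc_code <- function(x) code(oracle_revcomp(x))
  for (x in seq_along(ids)) {
    vx <- code(seqs[[x]])
    for (y in x:length(ids)) {
      vy <- code(seqs[[y]])
      scan_pair(ids[x], vx, ids[y], vy, "same", self_same = x == y)
      scan_pair(ids[x], vx, ids[y], rc_code(seqs[[y]]), "inverted",
                self_same = FALSE)
    }
  }
  if (is.null(out)) return(out)
  # drop duplicate spellings of the same pair (self-inverted symmetry)
  key <- apply(out, 1L, paste, collapse = "|")
  out <- out[!duplicated(key), , drop = FALSE]
  if (nrow(out) > 0L) {
    drop <- out$chrom_a == out$chrom_b & out$orientation == "inverted" &
      out$start_a == out$start_b & out$end_a == out$end_b
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(-out$length, out$chrom_a, out$start_a), , drop = FALSE]
}

# --- synteny chains -------------------------------------------------------

# exhaustive chain enumeration + exact disjoint packing; returns the
# maximum total number of genes coverable by disjoint valid chains of size
# >= min_genes, via a bottom-up DP over availability bitmasks. Matches are
# (ra, rb) pairs; requires M <= 16.
oracle_chain_packing_total <- function(ra, rb, max_gap, min_genes) {
  M <- length(ra)
  if (M < min_genes) return(0L)
  step <- max_gap + 1L
  # successor lists per direction
  succ <- function(i, dir) {
    out <- integer(0)
    for (j in seq_len(M)) {
      da <- ra[j] - ra[i]
      if (da <= 0L || da > step) next
      db <- if (dir == "asc") rb[j] - rb[i] else rb[i] - rb[j]
      if (db <= 0L || db > step) next
      out <- c(out, j)
    }
    out
  }
  chains_mask <- integer(0)
  chains_size <- integer(0)
  for (dir in c("asc", "desc")) {
    sa <- lapply(seq_len(M), succ, dir = dir)
    # iterative DFS over (last, mask, size)
    stack <- lapply(seq_len(M), function(i) {
      c(i, bitwShiftL(1L, i - 1L), 1L)
    })
    while (length(stack) > 0L) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (st[3L] >= min_genes) {
        chains_mask <- c(chains_mask, st[2L])
        chains_size <- c(chains_size, st[3L])
      }
      for (j in sa[[st[1L]]]) {
        stack[[length(stack) + 1L]] <-
          c(j, bitwOr(st[2L], bitwShiftL(1L, j - 1L)), st[3L] + 1L)
      }
    }
  }
  if (length(chains_mask) == 0L) return(0L)
  low_of <- vapply(chains_mask, function(m) {
    bitwAnd(m, bitwAnd(bitwNot(m) + 1L, m))  # lowest set bit
  }, integer(1L))
  full <- bitwShiftL(1L, M) - 1L
  sel_by_low <- split(seq_along(chains_mask), low_of)
  f <- integer(full + 1L)  # f[mask + 1]
  for (mask in seq_len(full)) {
    low <- bitwAnd(mask, -mask)
    best <- f[bitwAnd(mask, bitwNot(low)) + 1L]  # leave low unused
    sel <- sel_by_low[[as.character(low)]]
    for (ci in sel) {
      cm <- chains_mask[ci]
      if (bitwAnd(cm, mask) == cm) {
        v <- chains_size[ci] + f[bitwAnd(mask, bitwNot(cm)) + 1L]
        if (v > best) best <- v
      }
    }
    f[mask + 1L] <- best
  }
  f[full + 1L]
}

# --- fixtures -------------------------------------------------------------

# annotation with single-family genes laid left to right along one
# chromosome, one gene per family label (NA = unmatched filler gene)
toy_gene_order <- function(species, labels, chrom = "chr1", orfan = NULL) {
  genes <- list()
  for (i in seq_along(labels)) {
    s <- (i - 1L) * 100L
    cat_i <- if (!is.null(orfan) && i %in% orfan) "ORFan" else
      "function-predicted"
    genes[[i]] <- gene_model(sprintf("%s_t%02d", species, i), chrom, "+",
                             matrix(c(s, s + 90L), ncol = 2L),
                             category = cat_i)
  }
  nm_annotation(species, genes)
}

toy_families <- function(annotations, labels_list) {
  rows <- NULL
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    labels <- labels_list[[k]]
    ids <- vapply(ann$genes, `[[`, character(1L), "id")
    keep <- !is.na(labels)
    rows <- rbind(rows, data.frame(family_id = labels[keep],
                                   gene_id = ids[keep],
                                   stringsAsFactors = FALSE))
  }
  rows
}

# small cached synthetic genomes shared across tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_ancestor(sim_params(
        seed = 401L, n_chromosomes = 1L, chromosome_length = 30000L,
        n_genes = 18L, subtelomere_length = 1500L, verify_unique = FALSE))
    }
    cache
  }
})

# all permutations of 1..n as an integer matrix (one per row)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}
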