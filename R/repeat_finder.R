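# Repeat discovery: telomeric tandem motifs at chromosome termini, the
# subtelomeric repeat unit shared by all chromosome ends (rDNA operon + dnaK
# in real nucleomorph genomes), maximal exactly identical duplicated regions,
# and pseudogene fragments of homolog families.

# merge overlapping/abutting intervals (chromosome_id, start, stop)
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  out <- list()
  for (chr in unique(iv$chromosome_id)) {
    sub <- iv[iv$chromosome_id == chr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    s <- sub$start[1L]
    e <- sub$stop[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] <= e) {
        e <- max(e, sub$stop[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chromosome_id = chr,
                                              start = s, stop = e)
        s <- sub$start[i]
        e <- sub$stop[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chromosome_id = chr,
                                          start = s, stop = e)
  }
  do.call(rbind, out)
}

# lexicographically smallest rotation of a motif
canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 0L) return(motif)
  rots <- vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L))
  }, character(1L))
  min(rots)
}

#' Detect a telomeric tandem repeat at a chromosome end
#'
#' Finds the smallest period `p <= max_motif_len` whose tandem occupies the
#' chromosome terminus with at least `min_copies` copies (fractional copies
#' allowed). The motif is reported as the lexicographically smallest rotation
#' of the G-rich-strand spelling; at the left end the G-rich strand is the
#' reverse strand, so the observed prefix is reverse-complemented first.
#'
#' @param chromosome chromosome sequence (character scalar).
#' @param end "left" or "right".
#' @param max_motif_len maximum motif period to consider (default 10).
#' @param min_copies minimum number of tandem copies (default 3).
#' @param chromosome_id chromosome label for the output.
#' @return a list with elements chromosome_id, end, motif (canonical
#'   rotation), motif_observed (terminal unit as read on the G-rich strand),
#'   copies, span (0-based half-open forward interval); or NULL if no
#'   terminal tandem is found.
#' @export
detect_telomere <- function(chromosome, end = c("left", "right"),
                            max_motif_len = 10L, min_copies = 3L,
                            chromosome_id = "chr") {
  end <- match.arg(end)
  n <- nchar(chromosome)
  win <- min(n, max_motif_len * 60L)
  if (end == "left") {
    y <- seq_chars(substr(chromosome, 1L, win))
  } else {
    # orient so the terminus is element 1
    y <- rev(seq_chars(substr(chromosome, n - win + 1L, n)))
  }
  m <- length(y)
  # terminal tandem run length for each candidate period; keep the period
  # whose tandem reaches deepest (ties -> smallest period, so a period-14
  # spelling of a 7-mer repeat is reported as the 7-mer)
  run_of <- integer(min(max_motif_len, m))
  for (p in seq_along(run_of)) {
    run <- p
    i <- p + 1L
    while (i <= m && y[i] == y[i - p]) {
      run <- run + 1L
      i <- i + 1L
    }
    run_of[p] <- run
  }
  ok <- which(run_of / seq_along(run_of) >= min_copies)
  if (length(ok) > 0L) {
    p <- ok[which.max(run_of[ok])]
    run <- run_of[p]
    copies <- run / p
    unit <- paste(y[seq_len(p)], collapse = "")
    if (end == "left") {
      # unit read 5'->3' on the forward strand from the terminus; the
      # G-rich strand reads its reverse complement
      observed <- revcomp(unit)
      span <- c(0L, run)
    } else {
      # y was reversed; un-reverse the unit to forward-strand spelling
      observed <- paste(rev(y[seq_len(p)]), collapse = "")
      span <- c(n - run, n)
    }
    return(list(chromosome_id = chromosome_id, end = end,
                motif = canonical_rotation(observed),
                motif_observed = observed,
                copies = copies, span = as.integer(span)))
  }
  NULL
}

# terminal windows of every chromosome end
terminal_windows <- function(genome, search_depth) {
  out <- list()
  for (id in names(genome$chromosomes)) {
    s <- genome$chromosomes[[id]]
    n <- nchar(s)
    d <- min(search_depth, n %/% 2L)
    out[[paste0(id, ":left")]] <- list(chromosome_id = id, end = "left",
                                       offset = 0L,
                                       seq = substr(s, 1L, d))
    out[[paste0(id, ":right")]] <- list(chromosome_id = id, end = "right",
                                        offset = n - d,
                                        seq = substr(s, n - d + 1L, n))
  }
  out
}

#' Find the repeat unit shared by all chromosome ends
#'
#' Searches for the longest sequence that occurs exactly (allowing reverse
#' complement) within `search_depth` of every chromosome end. Candidate
#' units are located by anchoring shared `min_unit`-mers and extended runs
#' are verified by direct substring search in every window, so the result is
#' always a true common substring; in pathological cases a longer common
#' substring interleaved across windows could be missed.
#'
#' @param genome an `nm_genome` with at least 2 chromosomes.
#' @param search_depth how far from each terminus to search (default 50 kb,
#'   capped at half the chromosome length).
#' @param min_unit minimum unit length to report (default 100 bp).
#' @return a list with `unit_length` (0 if no shared unit of at least
#'   `min_unit` bp exists), `unit` (sequence or NA), and `occurrences`
#'   (data.frame chromosome_id, end, start, stop, orientation; 0-based
#'   half-open forward coordinates).
#' @export
find_shared_terminal_repeat <- function(genome, search_depth = 50000L,
                                        min_unit = 100L) {
  if (length(genome$chromosomes) < 2L) {
    stop("genome must have at least 2 chromosomes")
  }
  wins <- terminal_windows(genome, search_depth)
  k <- as.integer(min_unit)
  empty <- list(unit_length = 0L, unit = NA_character_,
                occurrences = data.frame(chromosome_id = character(),
                                         end = character(), start = integer(),
                                         stop = integer(),
                                         orientation = character(),
                                         stringsAsFactors = FALSE))
  if (any(vapply(wins, function(w) nchar(w$seq), integer(1L)) < k)) {
    return(empty)
  }
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }
  w1 <- wins[[1L]]$seq
  km1 <- kmers_of(w1)
  present <- rep(TRUE, length(km1))
  for (j in seq_along(wins)[-1L]) {
    sj <- wins[[j]]$seq
    pool <- c(kmers_of(sj), kmers_of(revcomp(sj)))
    present <- present & (km1 %in% pool)
    if (!any(present)) return(empty)
  }
  runs <- rle(present)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand_runs <- which(runs$values)
  if (length(cand_runs) == 0L) return(empty)
  # longest runs first; verify candidate in every window
  lens <- runs$lengths[cand_runs]
  ord <- cand_runs[order(-lens)]
  occurrences_of <- function(unit) {
    occ <- NULL
    for (w in wins) {
      p <- regexpr(unit, w$seq, fixed = TRUE)
      orient <- "forward"
      if (p < 0L) {
        p <- regexpr(unit, revcomp(w$seq), fixed = TRUE)
        if (p < 0L) return(NULL)
        # position on the reverse strand; map to forward coordinates
        p <- nchar(w$seq) - (as.integer(p) - 1L) - nchar(unit) + 1L
        orient <- "reverse"
      }
      occ <- rbind(occ, data.frame(
        chromosome_id = w$chromosome_id, end = w$end,
        start = w$offset + as.integer(p) - 1L,
        stop = w$offset + as.integer(p) - 1L + nchar(unit),
        orientation = orient, stringsAsFactors = FALSE))
    }
    occ
  }
  for (r in ord) {
    unit <- substr(w1, starts[r], ends[r] + k - 1L)
    occ <- occurrences_of(unit)
    if (!is.null(occ)) {
      return(list(unit_length = nchar(unit), unit = unit, occurrences = occ))
    }
  }
  # anchored runs did not verify as one contiguous unit; fall back to the
  # longest single shared k-mer
  unit <- km1[which(present)[1L]]
  occ <- occurrences_of(unit)
  if (is.null(occ)) return(empty)
  list(unit_length = k, unit = unit, occurrences = occ)
}

# polynomial rolling hashes of all k-windows of an integer-coded vector
rolling_hashes <- function(v, k, base = 131, mod = 2147483647) {
  n <- length(v)
  if (n < k) return(numeric(0))
  pw <- 1
  for (i in seq_len(k - 1L)) pw <- (pw * base) %% mod
  h <- numeric(n - k + 1L)
  hv <- 0
  for (i in seq_len(k)) hv <- (hv * base + v[i]) %% mod
  h[1L] <- hv
  if (n > k) {
    for (i in 2L:(n - k + 1L)) {
      hv <- (((hv - v[i - 1L] * pw) %% mod) * base + v[i + k - 1L]) %% mod
      h[i] <- hv
    }
  }
  h
}

code_chars <- function(v) {
  unname(c(A = 1, C = 2, G = 3, T = 4, N = 5)[v])
}

#' Find maximal exactly identical duplicated regions
#'
#' Detects all maximal exact repeated pairs of length at least `min_len`,
#' forward and reverse-complement, intra- and inter-chromosomal, by k-mer
#' anchoring with maximal extension. Pairs whose two copies both lie fully
#' inside `exclude` intervals (typically the subtelomeric repeats) are
#' dropped.
#'
#' @param genome an `nm_genome`.
#' @param min_len minimum region length in bp (default 1000).
#' @param exclude optional data.frame with columns chromosome_id, start, stop
#'   (0-based half-open) of intervals to exclude.
#' @return data.frame with columns chrom_a, start_a, end_a, chrom_b, start_b,
#'   end_b (0-based half-open forward coordinates), length, orientation
#'   ("same"/"inverted") and placement ("intra"/"inter"), sorted by length
#'   descending.
#' @export
find_duplicated_regions <- function(genome, min_len = 1000L, exclude = NULL) {
  k <- max(8L, min(as.integer(min_len), 100L))
  chroms <- lapply(genome$chromosomes, function(s) seq_chars(s))
  ids <- names(chroms)

  entry_chr <- character(0); entry_strand <- character(0)
  entry_pos <- integer(0); entry_hash <- numeric(0)
  for (cid in ids) {
    v <- chroms[[cid]]
    n <- length(v)
    if (n < k) next
    hf <- rolling_hashes(code_chars(v), k)
    hr <- rolling_hashes(code_chars(revcomp_chars(v)), k)
    npos <- n - k + 1L
    entry_chr <- c(entry_chr, rep(cid, 2L * npos))
    entry_strand <- c(entry_strand, rep("+", npos), rep("-", npos))
    # forward start (1-based) of the window; for "-" entries map rc index j
    # to the forward interval it covers
    entry_pos <- c(entry_pos, seq_len(npos), n - seq_len(npos) - k + 2L)
    entry_hash <- c(entry_hash, hf, hr)
  }
  empty <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      length = integer(), orientation = character(),
                      placement = character(), stringsAsFactors = FALSE)
  if (length(entry_hash) == 0L) return(empty)

  dup <- duplicated(entry_hash) | duplicated(entry_hash, fromLast = TRUE)
  if (!any(dup)) return(empty)
  idx <- which(dup)
  groups <- split(idx, entry_hash[idx])

  covered <- new.env(parent = emptyenv(), hash = TRUE)
  is_covered <- function(key, pos) {
    iv <- covered[[key]]
    if (is.null(iv)) return(FALSE)
    any(pos >= iv[, 1L] & pos <= iv[, 2L])
  }
  add_cover <- function(key, lo, hi) {
    covered[[key]] <- rbind(covered[[key]], c(lo, hi))
  }

  regions <- list()
  seen <- new.env(parent = emptyenv(), hash = TRUE)

  try_pair <- function(ci, cj) {
    si <- entry_strand[ci]; sj <- entry_strand[cj]
    if (si == "-" && sj == "-") return(invisible())
    if (si == "-") { tmp <- ci; ci <- cj; cj <- tmp; si <- "+"; sj <- entry_strand[cj] }
    ca <- entry_chr[ci]; cb <- entry_chr[cj]
    pa <- entry_pos[ci]; pb <- entry_pos[cj]
    orient <- if (sj == "+") "same" else "inverted"
    if (orient == "same") {
      # canonical order
      if (ca == cb && pa == pb) return(invisible())
      if (ca > cb || (ca == cb && pa > pb)) {
        tmp <- ca; ca <- cb; cb <- tmp
        tmp <- pa; pa <- pb; pb <- tmp
      }
      key <- paste(ca, cb, "same", pb - pa, sep = "|")
      if (is_covered(key, pa)) return(invisible())
      A <- chroms[[ca]]; B <- chroms[[cb]]
      # verify the seed (hash collisions possible)
      if (!identical(A[pa:(pa + k - 1L)], B[pb:(pb + k - 1L)])) return(invisible())
      a0 <- pa; b0 <- pb
      while (a0 > 1L && b0 > 1L && A[a0 - 1L] == B[b0 - 1L]) {
        a0 <- a0 - 1L; b0 <- b0 - 1L
      }
      a1 <- pa + k - 1L; b1 <- pb + k - 1L
      while (a1 < length(A) && b1 < length(B) && A[a1 + 1L] == B[b1 + 1L]) {
        a1 <- a1 + 1L; b1 <- b1 + 1L
      }
      add_cover(key, a0, a1 - k + 1L)
      len <- a1 - a0 + 1L
      if (len < min_len) return(invisible())
      if (ca == cb && a0 == b0) return(invisible())
      rkey <- paste(ca, a0, cb, b0, "same", len, sep = "|")
      if (!is.null(seen[[rkey]])) return(invisible())
      seen[[rkey]] <- TRUE
      regions[[length(regions) + 1L]] <<- data.frame(
        chrom_a = ca, start_a = a0 - 1L, end_a = a1,
        chrom_b = cb, start_b = b0 - 1L, end_b = b1,
        length = len, orientation = "same",
        placement = if (ca == cb) "intra" else "inter",
        stringsAsFactors = FALSE)
    } else {
      # A forward window == revcomp of B forward window
      A <- chroms[[ca]]; B <- chroms[[cb]]
      if (!identical(A[pa:(pa + k - 1L)],
                     revcomp_chars(B[pb:(pb + k - 1L)]))) return(invisible())
      # anti-diagonal invariant: pa + pb is constant along the repeat
      if (ca > cb || (ca == cb && pa > pb)) {
        tmp <- ca; ca <- cb; cb <- tmp
        tmp <- pa; pa <- pb; pb <- tmp
        A <- chroms[[ca]]; B <- chroms[[cb]]
      }
      key <- paste(ca, cb, "inv", pa + pb, sep = "|")
      if (is_covered(key, pa)) return(invisible())
      a0 <- pa; a1 <- pa + k - 1L
      b0 <- pb; b1 <- pb + k - 1L
      # extend A left / B right
      while (a0 > 1L && b1 < length(B) &&
             A[a0 - 1L] == COMPLEMENT[[B[b1 + 1L]]]) {
        a0 <- a0 - 1L; b1 <- b1 + 1L
      }
      # extend A right / B left
      while (a1 < length(A) && b0 > 1L &&
             A[a1 + 1L] == COMPLEMENT[[B[b0 - 1L]]]) {
        a1 <- a1 + 1L; b0 <- b0 - 1L
      }
      add_cover(key, a0, a1 - k + 1L)
      len <- a1 - a0 + 1L
      if (len < min_len) return(invisible())
      if (ca == cb && a0 == b0 && a1 == b1) return(invisible())
      if (ca == cb && b0 < a0) {
        tmp <- a0; a0 <- b0; b0 <- tmp
        tmp <- a1; a1 <- b1; b1 <- tmp
      }
      rkey <- paste(ca, a0, cb, b0, "inv", len, sep = "|")
      if (!is.null(seen[[rkey]])) return(invisible())
      seen[[rkey]] <- TRUE
      regions[[length(regions) + 1L]] <<- data.frame(
        chrom_a = ca, start_a = a0 - 1L, end_a = a1,
        chrom_b = cb, start_b = b0 - 1L, end_b = b1,
        length = len, orientation = "inverted",
        placement = if (ca == cb) "intra" else "inter",
        stringsAsFactors = FALSE)
    }
    invisible()
  }

  for (grp in groups) {
    if (length(grp) > 1L) {
      for (x in seq_len(length(grp) - 1L)) {
        for (y in (x + 1L):length(grp)) {
          try_pair(grp[x], grp[y])
        }
      }
    }
  }
  if (length(regions) == 0L) return(empty)
  out <- do.call(rbind, regions)

  if (!is.null(exclude) && nrow(exclude) > 0L && nrow(out) > 0L) {
    exclude <- merge_intervals(exclude)
    inside <- function(chr, s, e) {
      any(exclude$chromosome_id == chr & exclude$start <= s & exclude$stop >= e)
    }
    drop <- vapply(seq_len(nrow(out)), function(i) {
      inside(out$chrom_a[i], out$start_a[i], out$end_a[i]) &&
        inside(out$chrom_b[i], out$start_b[i], out$end_b[i])
    }, logical(1L))
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(-out$length, out$chrom_a, out$start_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count complete and partial genes in duplicated regions
#'
#' Per region pair, a gene counts as complete if its span lies fully inside
#' the first (leftmost) copy, and partial if it overlaps a boundary of that
#' copy. The two copies of an exact duplication carry identical gene content,
#' so counting one copy counts each duplicated gene once per region.
#'
#' @param regions data.frame from [find_duplicated_regions()].
#' @param annotation an `nm_annotation` of the same genome.
#' @return `regions` with added columns complete_genes and partial_genes;
#'   attribute `"totals"` holds the summed counts.
#' @export
annotate_duplicated_genes <- function(regions, annotation) {
  gt <- gene_table(annotation)
  comp <- integer(nrow(regions))
  part <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    on_chr <- gt[gt$chromosome_id == regions$chrom_a[i], , drop = FALSE]
    s <- regions$start_a[i]; e <- regions$end_a[i]
    full <- on_chr$start >= s & on_chr$end <= e
    overlap <- on_chr$start < e & on_chr$end > s
    comp[i] <- sum(full)
    part[i] <- sum(overlap & !full)
  }
  regions$complete_genes <- comp
  regions$partial_genes <- part
  attr(regions, "totals") <- c(complete = sum(comp), partial = sum(part))
  regions
}

#' Flag pseudogene fragments within homolog families
#'
#' A gene is flagged when its protein length falls within
#' `[min_fraction, max_fraction]` of its family's median protein length and
#' its local alignment to the family's longest member covers a terminal
#' portion (N- or C-terminal) of that member.
#'
#' @param annotation an `nm_annotation` with family_id labels.
#' @param proteins named character vector of protein sequences (all genes).
#' @param families data.frame with columns family_id and gene_id (as from
#'   [build_families()]).
#' @param min_fraction,max_fraction protein-length window relative to the
#'   family median (defaults 0.3 and 0.8).
#' @param terminal_margin fraction of the parent length within which the
#'   alignment must reach an end to count as terminal (default 0.2).
#' @return data.frame with columns gene_id, family_id, parent_id, fraction,
#'   side ("5prime"/"3prime").
#' @export
find_pseudogene_fragments <- function(annotation, proteins, families,
                                      min_fraction = 0.3, max_fraction = 0.8,
                                      terminal_margin = 0.2) {
  out <- data.frame(gene_id = character(), family_id = character(),
                    parent_id = character(), fraction = numeric(),
                    side = character(), stringsAsFactors = FALSE)
  if (nrow(families) == 0L) return(out)
  for (fid in unique(families$family_id)) {
    members <- families$gene_id[families$family_id == fid]
    members <- members[members %in% names(proteins)]
    if (length(members) < 2L) next
    lens <- nchar(proteins[members])
    med <- stats::median(lens)
    parent <- members[which.max(lens)]
    for (g in members) {
      frac <- lens[[g]] / med
      if (frac < min_fraction || frac > max_fraction) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[g]]),
        Biostrings::AAString(proteins[[parent]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      sub_rng <- c(Biostrings::start(Biostrings::subject(aln)),
                   Biostrings::end(Biostrings::subject(aln)))
      plen <- lens[[parent]]
      side <- NULL
      if (sub_rng[2L] >= (1 - terminal_margin) * plen) side <- "3prime"
      if (sub_rng[1L] <= terminal_margin * plen) side <- "5prime"
      if (is.null(side)) next
      out <- rbind(out, data.frame(gene_id = g, family_id = fid,
                                   parent_id = parent, fraction = frac,
                                   side = side, stringsAsFactors = FALSE))
    }
  }
  out
}
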