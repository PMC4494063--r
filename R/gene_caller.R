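# Spliced-ORF gene calling with ultrasmall introns.
#
# Chlorarachniophyte nucleomorph genes are interrupted by 18-23 nt
# spliceosomal introns with canonical GT..AG boundaries. The caller
# operationalizes expert curation as dynamic programming: a gene model is a
# chain of exons separated by intron candidates, starting at ATG (optional)
# and terminated by a stop codon, and the DP maximizes spliced ORF length.
# Stop codons may span splice junctions, which is why the DP state carries
# the 0-2 pending nucleotides of a partially read codon.

#' Gene-caller parameters
#'
#' @param min_protein_aa minimum protein length in amino acids (default 50).
#' @param intron_min,intron_max intron length bounds in nt (default 18-23).
#' @param max_introns_per_gene cap on introns per model (default 12).
#' @param require_atg require an ATG start codon (default TRUE); when FALSE
#'   models run stop-to-stop.
#' @param genetic_code genetic code table id (only "standard").
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(min_protein_aa = 50L, intron_min = 18L,
                          intron_max = 23L, max_introns_per_gene = 12L,
                          require_atg = TRUE, genetic_code = "standard") {
  stopifnot(intron_min <= intron_max, min_protein_aa >= 1L)
  structure(list(min_protein_aa = as.integer(min_protein_aa),
                 intron_min = as.integer(intron_min),
                 intron_max = as.integer(intron_max),
                 max_introns_per_gene = as.integer(max_introns_per_gene),
                 require_atg = isTRUE(require_atg),
                 genetic_code = genetic_code),
            class = "caller_params")
}

# candidate introns on a strand-local char vector; returns 1-based inclusive
# (start, end) pairs sorted by start
scan_intron_candidates <- function(w, intron_min, intron_max) {
  n <- length(w)
  out_s <- integer(0)
  out_e <- integer(0)
  if (n >= intron_min) {
    gt <- which(w[seq_len(n - 1L)] == "G" & w[-1L] == "T")
    for (L in intron_min:intron_max) {
      g <- gt[gt + L - 1L <= n]
      if (length(g) == 0L) next
      keep <- w[g + L - 2L] == "A" & w[g + L - 1L] == "G"
      g <- g[keep]
      out_s <- c(out_s, g)
      out_e <- c(out_e, g + L - 1L)
    }
  }
  ord <- order(out_s, out_e)
  cbind(start = out_s[ord], end = out_e[ord])
}

#' Enumerate ultrasmall intron candidates
#'
#' Lists every substring with length in `[intron_min, intron_max]` that reads
#' GT..AG in transcript orientation on the requested strand. On the minus
#' strand this corresponds to forward-strand substrings reading CT..AC.
#'
#' @param chromosome chromosome sequence (character scalar).
#' @param strand "+" or "-".
#' @param params a [caller_params()] object.
#' @param chromosome_id chromosome label for the output.
#' @return data.frame with columns chromosome_id, strand, start, end
#'   (0-based half-open, forward coordinates) and length, sorted by start.
#' @export
enumerate_intron_candidates <- function(chromosome, strand = "+",
                                        params = caller_params(),
                                        chromosome_id = "chr") {
  w <- seq_chars(toupper(chromosome))
  n <- length(w)
  if (strand == "-") w <- revcomp_chars(w)
  cand <- scan_intron_candidates(w, params$intron_min, params$intron_max)
  if (nrow(cand) == 0L) {
    return(data.frame(chromosome_id = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  if (strand == "+") {
    start <- cand[, "start"] - 1L
    end <- cand[, "end"]
  } else {
    start <- n - cand[, "end"]
    end <- n - cand[, "start"] + 1L
  }
  ord <- order(start, end)
  data.frame(chromosome_id = chromosome_id, strand = strand,
             start = start[ord], end = end[ord],
             length = (end - start)[ord], stringsAsFactors = FALSE)
}

# DP over one strand. w: strand-local char vector. Returns list of models:
# list(start, exons (2-col 1-based inclusive strand-local), spliced_len,
# n_introns, cds). Positions 1-based here; callers convert.
scan_strand_models <- function(w, params) {
  n <- length(w)
  if (n < 3L) return(list())
  is_stop_at <- logical(n)
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    a <- w[i]; b <- w[i + 1L]; c3 <- w[i + 2L]
    is_stop_at[i] <- a == "T" &
      ((b == "A" & (c3 == "A" | c3 == "G")) | (b == "G" & c3 == "A"))
  }
  # NS[p]: smallest q >= p with q = p (mod 3) and a stop codon starting at q
  NS <- rep(NA_integer_, n)
  for (r in 1:3) {
    idx <- seq(r, n, 3L)
    s <- is_stop_at[idx]
    v <- ifelse(s, seq_along(idx), NA_integer_)
    # next defined value at or after each position
    for (k in rev(seq_len(length(v) - 1L))) {
      if (is.na(v[k])) v[k] <- v[k + 1L]
    }
    NS[idx] <- ifelse(is.na(v), NA_integer_, idx[ifelse(is.na(v), 1L, v)])
  }
  cand <- if (params$max_introns_per_gene > 0L) {
    scan_intron_candidates(w, params$intron_min, params$intron_max)
  } else {
    cbind(start = integer(0), end = integer(0))  # plain ORF mode
  }
  dstart <- cand[, "start"]
  dend <- cand[, "end"]

  val <- new.env(parent = emptyenv(), hash = TRUE)
  cho <- new.env(parent = emptyenv(), hash = TRUE)

  donors_in <- function(lo, hi) {
    if (length(dstart) == 0L || hi < lo) return(integer(0))
    i1 <- findInterval(lo - 1L, dstart) + 1L
    i2 <- findInterval(hi, dstart)
    if (i2 < i1) integer(0) else i1:i2
  }

  best_from <- function(e, carry) {
    key <- paste0(e, "|", carry)
    got <- val[[key]]
    if (!is.null(got)) return(got)
    o <- nchar(carry)
    best <- -Inf
    choice <- NULL
    if (o > 0L) {
      need <- 3L - o
      if (e + need - 1L <= n) {
        cod <- paste0(carry, paste(w[e:(e + need - 1L)], collapse = ""))
        if (cod %in% STOP_CODONS) {
          best <- need
          choice <- list(type = "stop_j", end = e + need - 1L)
        } else {
          sub <- best_from(e + need, "")
          if (need + sub > best) {
            best <- need + sub
            choice <- list(type = "cont", nxt = e + need)
          }
        }
      }
      for (ci in donors_in(e, e + need - 1L)) {
        g <- dstart[ci]
        pre <- if (g > e) paste(w[e:(g - 1L)], collapse = "") else ""
        v <- (g - e) + best_from(dend[ci] + 1L, paste0(carry, pre))
        if (v > best) {
          best <- v
          choice <- list(type = "donor", g = g, resume = dend[ci] + 1L,
                         carry2 = paste0(carry, pre))
        }
      }
    } else {
      S <- if (e <= n) NS[e] else NA_integer_
      if (!is.na(S)) {
        best <- S + 3L - e
        choice <- list(type = "stop", end = S + 2L)
      }
      hi <- if (!is.na(S)) S + 2L else n
      for (ci in donors_in(e, hi)) {
        g <- dstart[ci]
        m <- (g - e) %% 3L
        carry2 <- if (m > 0L) paste(w[(g - m):(g - 1L)], collapse = "") else ""
        v <- (g - e) + best_from(dend[ci] + 1L, carry2)
        if (v > best) {
          best <- v
          choice <- list(type = "donor", g = g, resume = dend[ci] + 1L,
                         carry2 = carry2)
        }
      }
    }
    val[[key]] <- best
    cho[[key]] <- choice
    best
  }

  trace_model <- function(a, first_exon_start, e0, carry0) {
    # walk the stored choices; exons recorded 1-based inclusive
    exons <- NULL
    cur_start <- first_exon_start
    e <- e0
    carry <- carry0
    repeat {
      ch <- cho[[paste0(e, "|", carry)]]
      if (is.null(ch)) return(NULL)
      if (ch$type == "stop") {
        exons <- rbind(exons, c(cur_start, ch$end))
        break
      } else if (ch$type == "stop_j") {
        exons <- rbind(exons, c(cur_start, ch$end))
        break
      } else if (ch$type == "cont") {
        e <- ch$nxt
        carry <- ""
      } else {  # donor
        if (ch$g > cur_start) {
          exons <- rbind(exons, c(cur_start, ch$g - 1L))
        } else {
          # zero-length exon piece: adjacent introns; extend nothing
          exons <- rbind(exons, c(cur_start, ch$g - 1L))
        }
        cur_start <- ch$resume
        e <- ch$resume
        carry <- ch$carry2
      }
    }
    exons <- exons[exons[, 2L] >= exons[, 1L], , drop = FALSE]
    exons
  }

  starts <- integer(0)
  if (params$require_atg) {
    if (n >= 3L) {
      i <- seq_len(n - 2L)
      atg <- which(w[i] == "A" & w[i + 1L] == "T" & w[i + 2L] == "G")
      starts <- atg
    }
  } else {
    stops <- which(is_stop_at)
    starts <- sort(unique(c(1L, 2L, 3L, stops + 3L)))
    starts <- starts[starts <= n - 2L]
  }

  models <- list()
  for (a in starts) {
    if (params$require_atg) {
      if (a + 3L > n + 1L) next
      v <- best_from(a + 3L, "")
      if (!is.finite(v)) next
      total <- 3L + v
      exons <- trace_model(a, a, a + 3L, "")
    } else {
      total <- best_from(a, "")
      if (!is.finite(total)) next
      exons <- trace_model(a, a, a, "")
    }
    if (is.null(exons)) next
    aa_len <- total %/% 3L - 1L
    if (total %% 3L != 0L) next
    if (aa_len < params$min_protein_aa) next
    n_intr <- nrow(exons) - 1L
    if (n_intr > params$max_introns_per_gene) next
    cds <- paste(unlist(lapply(seq_len(nrow(exons)), function(i)
      paste(w[exons[i, 1L]:exons[i, 2L]], collapse = ""))), collapse = "")
    models[[length(models) + 1L]] <- list(start = a, exons = exons,
                                          spliced_len = total,
                                          n_introns = n_intr, cds = cds)
  }
  models
}

#' Call protein-coding genes on a chromosome
#'
#' Runs the spliced-ORF dynamic program on both strands and resolves
#' overlapping candidate models greedily by descending spliced length (ties:
#' leftmost, then "+" strand). Exact ties among parses from the same start
#' are broken toward fewer introns.
#'
#' @param chromosome chromosome sequence (character scalar).
#' @param params a [caller_params()] object.
#' @param chromosome_id chromosome label used in the returned models.
#' @return list of `nm_gene` models (category "ORFan" until classified), with
#'   an attribute `"proteins"`: named character vector of translations.
#' @export
call_genes <- function(chromosome, params = caller_params(),
                       chromosome_id = "chr") {
  chromosome <- toupper(chromosome)
  wf <- seq_chars(chromosome)
  n <- length(wf)
  plus <- scan_strand_models(wf, params)
  minus <- scan_strand_models(revcomp_chars(wf), params)

  cand <- list()
  for (m in plus) {
    cand[[length(cand) + 1L]] <- list(
      strand = "+",
      exons = cbind(m$exons[, 1L] - 1L, m$exons[, 2L]),  # 0-based half-open
      spliced_len = m$spliced_len, cds = m$cds)
  }
  for (m in minus) {
    ex <- cbind(n - m$exons[, 2L], n - m$exons[, 1L] + 1L)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    cand[[length(cand) + 1L]] <- list(
      strand = "-", exons = ex, spliced_len = m$spliced_len, cds = m$cds)
  }
  if (length(cand) == 0L) return(list())

  span_start <- vapply(cand, function(m) m$exons[1L, 1L], numeric(1L))
  span_end <- vapply(cand, function(m) m$exons[nrow(m$exons), 2L], numeric(1L))
  lens <- vapply(cand, function(m) m$spliced_len, numeric(1L))
  strands <- vapply(cand, function(m) m$strand, character(1L))
  ord <- order(-lens, span_start, strands)

  acc_s <- numeric(0)
  acc_e <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    if (any(span_start[i] < acc_e & span_end[i] > acc_s)) next
    kept <- c(kept, i)
    acc_s <- c(acc_s, span_start[i])
    acc_e <- c(acc_e, span_end[i])
  }
  kept <- kept[order(span_start[kept])]

  out <- vector("list", length(kept))
  prot <- character(length(kept))
  for (k in seq_along(kept)) {
    m <- cand[[kept[k]]]
    id <- sprintf("%s_g%03d", chromosome_id, k)
    out[[k]] <- gene_model(id, chromosome_id, m$strand, m$exons,
                           category = "ORFan")
    prot[k] <- translate_cds(m$cds, params$genetic_code)
  }
  names(prot) <- vapply(out, `[[`, character(1L), "id")
  attr(out, "proteins") <- prot
  out
}

#' Annotate a whole genome with the spliced-ORF caller
#'
#' @param genome an `nm_genome`.
#' @param params a [caller_params()] object.
#' @return an `nm_annotation`; translations are attached as attribute
#'   `"proteins"`.
#' @export
annotate_genome <- function(genome, params = caller_params()) {
  genes <- list()
  prots <- character(0)
  for (id in names(genome$chromosomes)) {
    g <- call_genes(genome$chromosomes[[id]], params, chromosome_id = id)
    prots <- c(prots, attr(g, "proteins"))
    genes <- c(genes, g)
  }
  ann <- nm_annotation(genome$species, genes)
  attr(ann, "proteins") <- prots
  ann
}

#' Spliced, strand-corrected translation of a gene
#'
#' @param gene an `nm_gene` (protein-coding).
#' @param genome the `nm_genome` it lies on.
#' @param genetic_code genetic code table id.
#' @return protein string without the terminal stop. An internal stop codon
#'   raises an error citing the codon index.
#' @export
translate_gene <- function(gene, genome, genetic_code = "standard") {
  translate_cds(spliced_cds(gene, genome), genetic_code)
}

#' Classify a gene as function-predicted or ORFan
#'
#' A gene with at least one homology hit at `evalue <= evalue_cutoff` is
#' function-predicted; genes without such a hit (including genes absent from
#' the table) are ORFans.
#'
#' @param gene_id gene identifier (query id in the hit table).
#' @param hits data.frame with columns query_id and evalue.
#' @param evalue_cutoff e-value cutoff (default 0.001).
#' @return "function-predicted" or "ORFan".
#' @export
classify_gene <- function(gene_id, hits, evalue_cutoff = 0.001) {
  if (is.null(hits) || nrow(hits) == 0L) return("ORFan")
  e <- hits$evalue[hits$query_id == gene_id]
  if (length(e) > 0L && any(e <= evalue_cutoff)) "function-predicted" else "ORFan"
}
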