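# Synthetic nucleomorph-like genomes with fully known ground truth.
#
# A genome is assembled from "pieces" (telomere, subtelomeric unit, spacer,
# gene, filler); evolution events (divergence, loss, duplication, inversion,
# intron gain/loss) operate on the piece list, and assembly yields the
# sequence plus a planted annotation. Two guard rails make planted gene
# structures uniquely recoverable by a spliced-ORF-length-maximizing caller:
# (1) every gene is flanked by short G-free spacer zones carrying stop
# codons in all reading frames, so no parse can read across a gene boundary
# or splice over it (donor GT / acceptor AG sites cannot exist there); and
# (2) intron interiors are G-free and carry stops in all frames, so intron
# retention always truncates the parse and alternative GT/AG boundaries
# inside an intron cannot arise.

GUARD12 <- "TTAATTAATTAA"  # stops in all 3 frames, both strands; G-free
GUARD_ZONE <- paste0(GUARD12, GUARD12, "TA")  # 26 nt

# sampling helpers immune to R's scalar-sample() surprise
sample_one <- function(v) if (length(v) == 1L) v else sample(v, 1L)
sample_vals <- function(v, k, prob = NULL) {
  v[sample.int(length(v), k, replace = TRUE, prob = prob)]
}

#' Parameters of the synthetic-genome generator
#'
#' Defaults emulate the magnitudes reported for chlorarachniophyte
#' nucleomorph genomes: three chromosomes of ~120 kb, ~28% GC, proteins
#' averaging ~347 aa, ~3 ultrasmall (18-23 nt) introns per gene, intergenic
#' spacers of ~110 bp, [TCTAGGG]n telomeres and an identical multi-kb
#' subtelomeric unit at every chromosome end.
#'
#' @param seed RNG seed (integer).
#' @param n_chromosomes number of chromosomes (default 3).
#' @param chromosome_length chromosome length in bp (default 120000).
#' @param gc_target target GC percent (default 28).
#' @param n_genes protein-coding genes per chromosome (default 80).
#' @param protein_length_mean,protein_length_sd,protein_length_min protein
#'   length distribution in aa (defaults 347, 60, 60).
#' @param introns_per_gene_mean mean introns per gene, Poisson capped at 8
#'   (default 3).
#' @param intron_length_range intron length range in nt (default c(18, 23)).
#' @param intergenic_mean,intergenic_sd spacer length distribution in bp
#'   (defaults 110 and 25; minimum 52 bp to fit the guard zones).
#' @param telomere_motif,telomere_copies telomeric repeat (defaults
#'   "TCTAGGG" and 12 copies).
#' @param subtelomere_length length of the shared subtelomeric unit
#'   (default 3000 bp).
#' @param n_duplications exact segmental duplications planted in the
#'   ancestor (default 0).
#' @param duplication_length_range planted duplication length range in bp
#'   (default c(1500, 3000)).
#' @param orfan_fraction fraction of genes labeled ORFan (default 0.4).
#' @param verify_unique rejection-sample genomes containing unintended exact
#'   duplicates >= 1 kb (default TRUE).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_chromosomes = 3L,
                       chromosome_length = 120000L, gc_target = 28,
                       n_genes = 80L, protein_length_mean = 347,
                       protein_length_sd = 60, protein_length_min = 60L,
                       introns_per_gene_mean = 3,
                       intron_length_range = c(18L, 23L),
                       intergenic_mean = 110, intergenic_sd = 25,
                       telomere_motif = "TCTAGGG", telomere_copies = 12L,
                       subtelomere_length = 3000L, n_duplications = 0L,
                       duplication_length_range = c(1500L, 3000L),
                       orfan_fraction = 0.4, verify_unique = TRUE) {
  p <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
            chromosome_length = as.integer(chromosome_length),
            gc_target = gc_target, n_genes = as.integer(n_genes),
            protein_length_mean = protein_length_mean,
            protein_length_sd = protein_length_sd,
            protein_length_min = as.integer(protein_length_min),
            introns_per_gene_mean = introns_per_gene_mean,
            intron_length_range = as.integer(intron_length_range),
            intergenic_mean = intergenic_mean, intergenic_sd = intergenic_sd,
            telomere_motif = toupper(telomere_motif),
            telomere_copies = as.integer(telomere_copies),
            subtelomere_length = as.integer(subtelomere_length),
            n_duplications = as.integer(n_duplications),
            duplication_length_range = as.integer(duplication_length_range),
            orfan_fraction = orfan_fraction,
            verify_unique = isTRUE(verify_unique))
  stopifnot(p$n_chromosomes >= 1L, p$chromosome_length > 0L,
            p$intron_length_range[1L] >= 16L || p$introns_per_gene_mean == 0,
            p$intron_length_range[1L] <= p$intron_length_range[2L],
            p$orfan_fraction >= 0, p$orfan_fraction <= 1)
  structure(p, class = "sim_params")
}

PRODUCT_POOL <- c(
  "rpl2", "rpl5", "rpl12", "rpl27", "rps4", "rps11", "dnaK", "tubA", "tubB",
  "prp43", "rad25", "eif6", "eif2G", "tcpG", "myb1", "secY", "gsp2",
  "clpP", "nop56", "cwc22", "mce", "tbl3", "hsp90", "rpb1", "rpc2",
  "sf3b3", "cdc2", "mcm-like", "snu114", "orc1", "smc1", "smc2", "fet5",
  "cbf5", "fib", "gar1", "tif6", "nmd3", "rrp3", "dbp2")

# sense-codon sampler at the intergenic base composition
sense_codon_pool <- function(gc) {
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  grid <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
  codons <- apply(grid, 1L, paste0, collapse = "")
  w <- apply(grid, 1L, function(r) prod(pb[match(r, bases)]))
  keep <- !codons %in% STOP_CODONS
  list(codons = codons[keep], weights = w[keep] / sum(w[keep]))
}

# one planted intron of the requested length: GT + all-frame-stop interior
# (G-free) + AG
make_intron <- function(len) {
  pad <- len - 4L - nchar(GUARD12)
  stopifnot(pad >= 0L)
  padding <- paste(sample(c("A", "T", "C"), pad, replace = TRUE,
                          prob = c(0.42, 0.42, 0.16)), collapse = "")
  paste0("GT", GUARD12, padding, "AG")
}

# spacer: guard zone + random middle + guard zone
make_spacer <- function(total_len, gc) {
  total_len <- max(total_len, 2L * nchar(GUARD_ZONE))
  mid <- total_len - 2L * nchar(GUARD_ZONE)
  paste0(GUARD_ZONE, random_dna(mid, gc), GUARD_ZONE)
}

# A splice site is only uniquely recoverable if no alternative GT donor /
# AG acceptor lies within reach of an intron of legal length: an AG in the
# first (intron_max - len) exon nt after an acceptor, or a GT in the last
# such window before a donor, would allow a slightly longer legal excision
# whose frameshifted tail can out-score the planted parse.
splice_windows_clean <- function(cds_chars, offsets, ilens, intron_max) {
  for (i in seq_along(offsets)) {
    slack <- intron_max - ilens[i]
    if (slack <= 0L) next
    o <- offsets[i]
    # exon chars after the splice: positions o+1 .. o+slack (1-based)
    for (j in seq_len(slack - 1L)) {
      if (o + j + 1L > length(cds_chars)) break
      if (cds_chars[o + j] == "A" && cds_chars[o + j + 1L] == "G") {
        return(FALSE)
      }
    }
    # exon chars before the splice: a GT starting within slack of the donor
    for (j in seq_len(slack)) {
      if (o - j < 1L) break
      if (cds_chars[o - j] == "G" && cds_chars[o - j + 1L] == "T") {
        return(FALSE)
      }
    }
  }
  TRUE
}

# construct a gene piece in transcript orientation, then orient
make_gene_piece <- function(base_id, species, params, pool, uid) {
  gc <- params$gc_target / 100
  La <- max(params$protein_length_min,
            round(stats::rnorm(1L, params$protein_length_mean,
                               params$protein_length_sd)))
  codons <- sample(pool$codons, La - 1L, replace = TRUE, prob = pool$weights)
  stop_cod <- sample(STOP_CODONS, 1L, prob = c(0.6, 0.2, 0.2))
  cds <- paste0("ATG", paste(codons, collapse = ""), stop_cod)
  cds_len <- nchar(cds)
  cds_chars <- seq_chars(cds)
  k <- min(8L, stats::rpois(1L, params$introns_per_gene_mean))
  offsets <- integer(0)
  ilens <- integer(0)
  if (k > 0L) {
    # keep the terminal exon >= 17 nt: a retained intron reads into the
    # interior stop guard within at most ~14 nt, so a shorter genuine tail
    # could lose to retention
    lo <- 3L
    hi <- cds_len - 17L
    for (try in 1:200) {
      offsets <- sort(sample(lo:hi, k))
      ilens <- sample_vals(params$intron_length_range[1L]:
                             params$intron_length_range[2L], k)
      if ((k == 1L || min(diff(offsets)) >= 6L) &&
          splice_windows_clean(cds_chars, offsets, ilens,
                               params$intron_length_range[2L])) {
        break
      }
      offsets <- integer(0)
      ilens <- integer(0)
    }
  }
  # transcript-orientation piece sequence and exon intervals
  parts <- character(0)
  exons <- NULL
  prev <- 0L
  pos <- 0L
  for (i in seq_along(offsets)) {
    exon_seq <- substr(cds, prev + 1L, offsets[i])
    parts <- c(parts, exon_seq, make_intron(ilens[i]))
    exons <- rbind(exons, c(pos, pos + nchar(exon_seq)))
    pos <- pos + nchar(exon_seq) + ilens[i]
    prev <- offsets[i]
  }
  exon_seq <- substr(cds, prev + 1L, cds_len)
  parts <- c(parts, exon_seq)
  exons <- rbind(exons, c(pos, pos + nchar(exon_seq)))
  seq_t <- paste(parts, collapse = "")
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    L <- nchar(seq_t)
    seq_p <- revcomp(seq_t)
    exons <- cbind(L - exons[, 2L], L - exons[, 1L])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
  } else {
    seq_p <- seq_t
  }
  orfan <- stats::runif(1L) < params$orfan_fraction
  list(kind = "gene", uid = uid, seq = seq_p,
       gene = list(base = base_id,
                   id = paste0(species, "_", base_id),
                   strand = strand, exons_local = exons,
                   category = if (orfan) "ORFan" else "function-predicted",
                   product = if (orfan) "hypothetical protein"
                   else sample(PRODUCT_POOL, 1L),
                   protein = translate_cds(cds)))
}

# subtelomeric unit with planted rRNA features (transcript-forward layout)
make_subtel_template <- function(params) {
  L <- params$subtelomere_length
  seq <- random_dna(L, params$gc_target / 100)
  feat <- list(
    list(tag = "rrn_ssu", frac = c(0.05, 0.45), category = "rRNA",
         product = "small subunit ribosomal RNA"),
    list(tag = "rrn_5.8", frac = c(0.50, 0.55), category = "rRNA",
         product = "5.8S ribosomal RNA"),
    list(tag = "rrn_lsu", frac = c(0.60, 0.95), category = "rRNA",
         product = "large subunit ribosomal RNA"))
  feats <- lapply(feat, function(f) {
    list(tag = f$tag,
         exons_local = matrix(as.integer(round(f$frac * L)), ncol = 2L),
         strand = "+", category = f$category, product = f$product)
  })
  list(seq = seq, features = feats)
}

subtel_piece <- function(template, end, uid) {
  if (end == "left") {
    list(kind = "subtelomere", uid = uid, end = end, seq = template$seq,
         features = template$features)
  } else {
    L <- nchar(template$seq)
    feats <- lapply(template$features, function(f) {
      ex <- cbind(L - f$exons_local[, 2L], L - f$exons_local[, 1L])
      list(tag = f$tag, exons_local = ex, strand = "-",
           category = f$category, product = f$product)
    })
    list(kind = "subtelomere", uid = uid, end = end,
         seq = revcomp(template$seq), features = feats)
  }
}

new_uid_factory <- function() {
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("p%06d", counter)
  }
}

# assemble piece lists into genome + annotation + coordinate truth
assemble_pieces <- function(species, chrom_pieces) {
  seqs <- character(0)
  genes <- list()
  piece_map <- list()  # uid -> (chrom, start, end)
  telomeres <- list()
  subtel <- list()
  spacer_lengths <- integer(0)
  fillers <- list()
  rrn_counter <- 0L
  for (cid in names(chrom_pieces)) {
    offset <- 0L
    parts <- character(length(chrom_pieces[[cid]]))
    for (pi in seq_along(chrom_pieces[[cid]])) {
      p <- chrom_pieces[[cid]][[pi]]
      len <- nchar(p$seq)
      parts[pi] <- p$seq
      piece_map[[p$uid]] <- list(chromosome_id = cid, start = offset,
                                 end = offset + len, kind = p$kind)
      if (p$kind == "gene") {
        g <- p$gene
        genes[[length(genes) + 1L]] <- gene_model(
          g$id, cid, g$strand, g$exons_local + offset,
          category = g$category, product = g$product)
        attr(genes[[length(genes)]], "protein") <- g$protein
        attr(genes[[length(genes)]], "base") <- g$base
      } else if (p$kind == "subtelomere") {
        subtel[[length(subtel) + 1L]] <- data.frame(
          chromosome_id = cid, end = p$end, start = offset,
          stop = offset + len, stringsAsFactors = FALSE)
        for (f in p$features) {
          rrn_counter <- rrn_counter + 1L
          genes[[length(genes) + 1L]] <- gene_model(
            sprintf("%s_%s_%03d", species, f$tag, rrn_counter),
            cid, f$strand, f$exons_local + offset,
            category = f$category, product = f$product)
        }
      } else if (p$kind == "telomere") {
        telomeres[[length(telomeres) + 1L]] <- data.frame(
          chromosome_id = cid, end = p$end, start = offset,
          stop = offset + len, stringsAsFactors = FALSE)
      } else if (p$kind == "spacer") {
        spacer_lengths <- c(spacer_lengths, len)
      } else if (p$kind %in% c("filler", "lost_gene")) {
        fillers[[length(fillers) + 1L]] <- data.frame(
          chromosome_id = cid, start = offset, stop = offset + len,
          stringsAsFactors = FALSE)
      }
      offset <- offset + len
    }
    seqs[[cid]] <- paste(parts, collapse = "")
  }
  genome <- nm_genome(species, seqs)
  annotation <- nm_annotation(species, genes)
  proteins <- lapply(genes, function(g) attr(g, "protein"))
  names(proteins) <- vapply(genes, `[[`, character(1L), "id")
  proteins <- unlist(proteins[!vapply(proteins, is.null, logical(1L))])
  list(genome = genome, annotation = annotation, proteins = proteins,
       piece_map = piece_map,
       telomeres = do.call(rbind, telomeres),
       subtelomeres = do.call(rbind, subtel),
       fillers = if (length(fillers)) do.call(rbind, fillers) else NULL,
       spacer_lengths = spacer_lengths)
}

# resolve recorded duplication (uid runs) to coordinate truth
resolve_duplications <- function(pending, piece_map) {
  if (length(pending) == 0L) return(NULL)
  rows <- lapply(pending, function(d) {
    src <- piece_map[d$src_uids]
    cpy <- piece_map[d$copy_uids]
    data.frame(
      chrom_a = src[[1L]]$chromosome_id,
      start_a = src[[1L]]$start,
      end_a = src[[length(src)]]$end,
      chrom_b = cpy[[1L]]$chromosome_id,
      start_b = cpy[[1L]]$start,
      end_b = cpy[[length(cpy)]]$end,
      length = src[[length(src)]]$end - src[[1L]]$start,
      orientation = d$orientation,
      placement = if (src[[1L]]$chromosome_id == cpy[[1L]]$chromosome_id)
        "intra" else "inter",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# pick a run of consecutive pieces [spacer gene ... gene spacer] on a random
# chromosome with total length inside len_range; NULL if none found
pick_gene_run <- function(chrom_pieces, len_range, frozen, tries = 30L) {
  cids <- names(chrom_pieces)
  for (t in seq_len(tries)) {
    cid <- sample(cids, 1L)
    pieces <- chrom_pieces[[cid]]
    kinds <- vapply(pieces, `[[`, character(1L), "kind")
    gene_idx <- which(kinds == "gene")
    if (length(gene_idx) == 0L) next
    i <- sample_one(gene_idx)
    # expand to include flanking spacers
    if (i == 1L || i == length(pieces)) next
    if (kinds[i - 1L] != "spacer" || kinds[i + 1L] != "spacer") next
    lo <- i - 1L
    hi <- i + 1L
    total <- sum(vapply(pieces[lo:hi], function(p) nchar(p$seq), integer(1L)))
    while (total < len_range[1L] && hi + 2L <= length(pieces) &&
           kinds[hi + 1L] == "gene" && kinds[hi + 2L] == "spacer") {
      hi <- hi + 2L
      total <- sum(vapply(pieces[lo:hi], function(p) nchar(p$seq),
                          integer(1L)))
    }
    if (total < len_range[1L] || total > len_range[2L]) next
    uids <- vapply(pieces[lo:hi], `[[`, character(1L), "uid")
    if (any(uids %in% frozen)) next
    return(list(chromosome_id = cid, lo = lo, hi = hi, uids = uids,
                length = total))
  }
  NULL
}

# duplicate a run of pieces; returns updated state
apply_duplication <- function(chrom_pieces, species, len_range, frozen,
                              new_uid, copy_tag) {
  run <- pick_gene_run(chrom_pieces, len_range, frozen)
  if (is.null(run)) return(NULL)
  src <- chrom_pieces[[run$chromosome_id]][run$lo:run$hi]
  orientation <- sample(c("same", "inverted"), 1L)
  copy <- lapply(src, function(p) {
    q <- p
    q$uid <- new_uid()
    if (p$kind == "gene") {
      q$gene$base <- p$gene$base
      q$gene$id <- paste0(p$gene$id, "_", copy_tag)
    }
    q
  })
  if (orientation == "inverted") {
    copy <- rev(lapply(copy, revcomp_piece))
  }
  # insert right after a random spacer outside the source run and outside
  # frozen pieces
  for (t in 1:30) {
    cid <- sample(names(chrom_pieces), 1L)
    pieces <- chrom_pieces[[cid]]
    kinds <- vapply(pieces, `[[`, character(1L), "kind")
    uids <- vapply(pieces, `[[`, character(1L), "uid")
    ok <- which(kinds == "spacer" & !(uids %in% c(frozen, run$uids)))
    if (length(ok) == 0L) next
    at <- sample_one(ok)
    chrom_pieces[[cid]] <- append(pieces, copy, after = at)
    return(list(chrom_pieces = chrom_pieces,
                src_uids = run$uids,
                copy_uids = vapply(copy, `[[`, character(1L), "uid"),
                orientation = orientation))
  }
  NULL
}

revcomp_piece <- function(p) {
  L <- nchar(p$seq)
  q <- p
  q$seq <- revcomp(p$seq)
  if (p$kind == "gene") {
    ex <- p$gene$exons_local
    ex2 <- cbind(L - ex[, 2L], L - ex[, 1L])
    q$gene$exons_local <- ex2[order(ex2[, 1L]), , drop = FALSE]
    q$gene$strand <- if (p$gene$strand == "+") "-" else "+"
  }
  if (p$kind == "subtelomere" && !is.null(p$features)) {
    q$features <- lapply(p$features, function(f) {
      ex <- cbind(L - f$exons_local[, 2L], L - f$exons_local[, 1L])
      f$exons_local <- ex
      f$strand <- if (f$strand == "+") "-" else "+"
      f
    })
    q$end <- if (identical(p$end, "left")) "right" else "left"
  }
  q
}

#' Generate a synthetic ancestor genome with planted truth
#'
#' Deterministic for a fixed seed. Genes are ATG..stop ORFs with planted
#' GT-AG ultrasmall introns and no in-frame stops in exons; intergenic
#' spacers, a telomeric tandem and an identical subtelomeric unit at every
#' end are placed as in real nucleomorph chromosome architecture.
#'
#' @param params a [sim_params()] object.
#' @return list of class `sim_truth` with genome, annotation, proteins
#'   (named vector), families (data.frame family_id, gene_id), telomeres,
#'   subtelomeres, fillers, spacer_lengths, duplications, pieces (internal,
#'   for [evolve_species()]), events (empty log), params.
#' @export
generate_ancestor <- function(params = sim_params()) {
  with_seed(params$seed, generate_ancestor_impl(params))
}

generate_ancestor_impl <- function(params, species = "ancestor") {
  pool <- sense_codon_pool(params$gc_target / 100)
  for (attempt in 1:3) {
    new_uid <- new_uid_factory()
    template <- make_subtel_template(params)
    tel_fwd <- strrep(params$telomere_motif, params$telomere_copies)
    gene_counter <- 0L
    chrom_pieces <- list()
    for (c in seq_len(params$n_chromosomes)) {
      cid <- sprintf("chr%d", c)
      pieces <- list()
      pieces[[1L]] <- list(kind = "telomere", uid = new_uid(), end = "left",
                           seq = revcomp(tel_fwd))
      pieces[[2L]] <- subtel_piece(template, "left", new_uid())
      body <- list()
      for (gi in seq_len(params$n_genes)) {
        gene_counter <- gene_counter + 1L
        sp_len <- round(stats::rnorm(1L, params$intergenic_mean,
                                     params$intergenic_sd))
        body[[length(body) + 1L]] <- list(
          kind = "spacer", uid = new_uid(),
          seq = make_spacer(sp_len, params$gc_target / 100))
        body[[length(body) + 1L]] <- make_gene_piece(
          sprintf("g%04d", gene_counter), species, params, pool, new_uid())
      }
      sp_len <- round(stats::rnorm(1L, params$intergenic_mean,
                                   params$intergenic_sd))
      body[[length(body) + 1L]] <- list(
        kind = "spacer", uid = new_uid(),
        seq = make_spacer(sp_len, params$gc_target / 100))
      fixed <- 2L * nchar(tel_fwd) + 2L * nchar(template$seq)
      body_len <- sum(vapply(body, function(p) nchar(p$seq), integer(1L)))
      filler_len <- params$chromosome_length - fixed - body_len
      if (filler_len < 0L) {
        stop("infeasible packing: genes exceed chromosome length")
      }
      if (filler_len > 0L) {
        body[[length(body) + 1L]] <- list(
          kind = "filler", uid = new_uid(),
          seq = random_dna(filler_len, params$gc_target / 100))
      }
      pieces <- c(pieces, body)
      pieces[[length(pieces) + 1L]] <- subtel_piece(template, "right",
                                                    new_uid())
      pieces[[length(pieces) + 1L]] <- list(kind = "telomere",
                                            uid = new_uid(), end = "right",
                                            seq = tel_fwd)
      chrom_pieces[[cid]] <- pieces
    }

    pending_dups <- list()
    frozen <- character(0)
    if (params$n_duplications > 0L) {
      for (d in seq_len(params$n_duplications)) {
        res <- apply_duplication(chrom_pieces, species,
                                 params$duplication_length_range, frozen,
                                 new_uid, sprintf("dup%d", d))
        if (is.null(res)) next
        chrom_pieces <- res$chrom_pieces
        pending_dups[[length(pending_dups) + 1L]] <- res
        frozen <- c(frozen, res$src_uids, res$copy_uids)
      }
    }

    asm <- assemble_pieces(species, chrom_pieces)
    dups <- resolve_duplications(pending_dups, asm$piece_map)
    truth <- structure(list(
      species = species, genome = asm$genome, annotation = asm$annotation,
      proteins = asm$proteins,
      families = data.frame(
        family_id = vapply(asm$annotation$genes, function(g) {
          b <- attr(g, "base")
          if (is.null(b)) NA_character_ else b
        }, character(1L)),
        gene_id = vapply(asm$annotation$genes, `[[`, character(1L), "id"),
        stringsAsFactors = FALSE),
      telomeres = asm$telomeres, subtelomeres = asm$subtelomeres,
      fillers = asm$fillers, spacer_lengths = asm$spacer_lengths,
      duplications = dups, dup_runs = pending_dups,
      pieces = chrom_pieces, frozen = frozen,
      events = data.frame(event = character(), detail = character(),
                          stringsAsFactors = FALSE),
      params = params), class = "sim_truth")
    truth$families <- truth$families[!is.na(truth$families$family_id), ,
                                     drop = FALSE]
    if (!params$verify_unique || no_unintended_duplicates(truth)) {
      return(truth)
    }
  }
  stop("could not generate a genome free of unintended exact duplicates")
}

# check for exact repeats >= 1 kb that were not planted
no_unintended_duplicates <- function(truth, min_len = 1000L) {
  excl <- rbind(
    truth$subtelomeres[, c("chromosome_id", "start", "stop")],
    truth$telomeres[, c("chromosome_id", "start", "stop")])
  # identical spacer guard zones let subtelomeric matches extend a few dozen
  # bp past the planted span; pad the exclusion accordingly
  excl$start <- pmax(0L, excl$start - 60L)
  excl$stop <- excl$stop + 60L
  found <- find_duplicated_regions(truth$genome, min_len = min_len,
                                   exclude = excl)
  if (nrow(found) == 0L) return(TRUE)
  planted <- truth$duplications
  if (is.null(planted) || nrow(planted) == 0L) return(FALSE)
  overlaps <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 & s1 < e2 & e1 > s2
  }
  covered <- vapply(seq_len(nrow(found)), function(i) {
    any((overlaps(found$chrom_a[i], found$start_a[i], found$end_a[i],
                  planted$chrom_a, planted$start_a, planted$end_a) &
           overlaps(found$chrom_b[i], found$start_b[i], found$end_b[i],
                    planted$chrom_b, planted$start_b, planted$end_b)) |
          (overlaps(found$chrom_a[i], found$start_a[i], found$end_a[i],
                    planted$chrom_b, planted$start_b, planted$end_b) &
             overlaps(found$chrom_b[i], found$start_b[i], found$end_b[i],
                      planted$chrom_a, planted$start_a, planted$end_a)))
  }, logical(1L))
  all(covered)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d chromosome(s), %d gene(s), %d event(s)\n",
              x$species, length(x$genome$chromosomes),
              length(x$annotation$genes), nrow(x$events)))
  invisible(x)
}

#' Specification of evolution events for [evolve_species()]
#'
#' @param divergence per-codon substitution probability inside exons and
#'   per-site rate in spacer middles (default 0).
#' @param gene_loss number of genes to delete (default 0).
#' @param duplications number of exact segmental duplications (default 0).
#' @param duplication_length_range length range of duplications in bp.
#' @param inversions number of segmental inversions (default 0).
#' @param inversion_genes range of genes per inversion (default c(4, 8)).
#' @param intron_gain,intron_loss numbers of intron gain/loss events
#'   (default 0).
#' @return a list of class `evolve_events`.
#' @export
evolve_events <- function(divergence = 0, gene_loss = 0L, duplications = 0L,
                          duplication_length_range = c(1500L, 3000L),
                          inversions = 0L, inversion_genes = c(4L, 8L),
                          intron_gain = 0L, intron_loss = 0L) {
  structure(list(divergence = divergence, gene_loss = as.integer(gene_loss),
                 duplications = as.integer(duplications),
                 duplication_length_range = as.integer(duplication_length_range),
                 inversions = as.integer(inversions),
                 inversion_genes = as.integer(inversion_genes),
                 intron_gain = as.integer(intron_gain),
                 intron_loss = as.integer(intron_loss)),
            class = "evolve_events")
}

# codon-aware divergence of one gene piece (exons only; introns untouched)
diverge_gene_piece <- function(p, rate, pool) {
  if (rate <= 0) return(p)
  g <- p$gene
  # operate in transcript orientation
  seq_t <- if (g$strand == "-") revcomp(p$seq) else p$seq
  L <- nchar(p$seq)
  ex_t <- if (g$strand == "-") {
    ex <- cbind(L - g$exons_local[, 2L], L - g$exons_local[, 1L])
    ex[order(ex[, 1L]), , drop = FALSE]
  } else {
    g$exons_local
  }
  v <- seq_chars(seq_t)
  cds_pos <- unlist(lapply(seq_len(nrow(ex_t)), function(i) {
    (ex_t[i, 1L] + 1L):ex_t[i, 2L]
  }))
  n_cod <- length(cds_pos) %/% 3L
  # keep codons near splice junctions untouched so the clean donor/acceptor
  # windows planted by the generator survive divergence
  widths <- ex_t[, 2L] - ex_t[, 1L]
  junctions <- if (nrow(ex_t) > 1L) cumsum(widths)[-nrow(ex_t)] else integer(0)
  # skip the start and stop codons
  for (ci in 2:(n_cod - 1L)) {
    if (stats::runif(1L) >= rate) next
    lo <- 3L * (ci - 1L) + 1L
    hi <- 3L * ci
    if (length(junctions) > 0L &&
        any(junctions >= lo - 7L & junctions <= hi + 7L)) next
    new_cod <- sample(pool$codons, 1L, prob = pool$weights)
    idx <- cds_pos[lo:hi]
    v[idx] <- seq_chars(new_cod)
  }
  new_t <- paste(v, collapse = "")
  p$seq <- if (g$strand == "-") revcomp(new_t) else new_t
  p$gene$protein <- translate_cds(paste(substring(new_t, ex_t[, 1L] + 1L,
                                                  ex_t[, 2L]),
                                        collapse = ""))
  p
}

diverge_spacer_piece <- function(p, rate, gc) {
  if (rate <= 0) return(p)
  zone <- nchar(GUARD_ZONE)
  v <- seq_chars(p$seq)
  L <- length(v)
  if (L <= 2L * zone) return(p)
  idx <- (zone + 1L):(L - zone)
  hit <- idx[stats::runif(length(idx)) < rate]
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in hit) {
    if (stats::runif(1L) < 0.75) {
      v[i] <- transitions[[v[i]]]
    } else {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(v[i], transitions[[v[i]]])), 1L)
    }
  }
  p$seq <- paste(v, collapse = "")
  p
}

#' Evolve a species genome from an ancestor
#'
#' Applies, in order: sequence divergence (codon-aware in exons, skipping
#' planted introns; transition-biased in spacer middles), gene losses, exact
#' segmental duplications, segmental inversions, and intron gains/losses.
#' Telomeres and subtelomeric units are never touched (events that would
#' touch them are rejected and logged), and pieces participating in a
#' recorded duplication are frozen so the exact-identity truth is preserved.
#'
#' @param ancestor a `sim_truth` from [generate_ancestor()].
#' @param events an [evolve_events()] object.
#' @param seed RNG seed for this species.
#' @param species species label for the derived genome.
#' @return a `sim_truth` for the derived species; `families` keeps the
#'   ancestral gene identity so cross-species family truth is the shared
#'   `family_id`.
#' @export
evolve_species <- function(ancestor, events = evolve_events(), seed = 1L,
                           species = "species1") {
  with_seed(seed, evolve_species_impl(ancestor, events, species))
}

evolve_species_impl <- function(ancestor, events, species) {
  params <- ancestor$params
  pool <- sense_codon_pool(params$gc_target / 100)
  chrom_pieces <- ancestor$pieces
  frozen <- ancestor$frozen
  log <- ancestor$events
  note <- function(event, detail) {
    log <<- rbind(log, data.frame(event = event, detail = detail,
                                  stringsAsFactors = FALSE))
  }

  # relabel gene ids for the new species
  for (cid in names(chrom_pieces)) {
    for (pi in seq_along(chrom_pieces[[cid]])) {
      p <- chrom_pieces[[cid]][[pi]]
      if (p$kind == "gene") {
        suffix <- sub(paste0("^", ancestor$species, "_"), "", p$gene$id)
        chrom_pieces[[cid]][[pi]]$gene$id <- paste0(species, "_", suffix)
      }
    }
  }

  # 1. divergence
  if (events$divergence > 0) {
    for (cid in names(chrom_pieces)) {
      for (pi in seq_along(chrom_pieces[[cid]])) {
        p <- chrom_pieces[[cid]][[pi]]
        if (p$uid %in% frozen) next
        if (p$kind == "gene") {
          chrom_pieces[[cid]][[pi]] <-
            diverge_gene_piece(p, events$divergence, pool)
        } else if (p$kind %in% c("spacer", "filler")) {
          chrom_pieces[[cid]][[pi]] <-
            diverge_spacer_piece(p, events$divergence,
                                 params$gc_target / 100)
        }
      }
    }
    note("divergence", sprintf("rate=%g", events$divergence))
  }

  # 2. gene losses
  if (events$gene_loss > 0L) {
    all_genes <- list()
    for (cid in names(chrom_pieces)) {
      for (pi in seq_along(chrom_pieces[[cid]])) {
        p <- chrom_pieces[[cid]][[pi]]
        if (p$kind == "gene" && !(p$uid %in% frozen)) {
          all_genes[[length(all_genes) + 1L]] <- c(cid, pi)
        }
      }
    }
    if (length(all_genes) > 0L) {
      take <- sample(length(all_genes), min(events$gene_loss,
                                            length(all_genes)))
      for (t in take) {
        cid <- all_genes[[t]][1L]
        pi <- as.integer(all_genes[[t]][2L])
        p <- chrom_pieces[[cid]][[pi]]
        note("gene_loss", p$gene$id)
        chrom_pieces[[cid]][[pi]] <- list(
          kind = "lost_gene", uid = p$uid,
          seq = make_spacer(nchar(p$seq), params$gc_target / 100))
      }
    }
  }

  # 3. duplications (exact, applied after divergence)
  pending_dups <- list()
  if (events$duplications > 0L) {
    for (d in seq_len(events$duplications)) {
      res <- apply_duplication(chrom_pieces, species,
                               events$duplication_length_range, frozen,
                               new_uid_factory_offset(chrom_pieces),
                               sprintf("dup%d", d))
      if (is.null(res)) {
        note("duplication_rejected", sprintf("event %d: no placement", d))
        next
      }
      chrom_pieces <- res$chrom_pieces
      pending_dups[[length(pending_dups) + 1L]] <- res
      frozen <- c(frozen, res$src_uids, res$copy_uids)
      note("duplication", paste(res$src_uids[1L], res$orientation))
    }
  }

  # 4. inversions
  inverted_gene_sets <- list()
  if (events$inversions > 0L) {
    for (iv in seq_len(events$inversions)) {
      done <- FALSE
      for (t in 1:30) {
        cid <- sample(names(chrom_pieces), 1L)
        pieces <- chrom_pieces[[cid]]
        kinds <- vapply(pieces, `[[`, character(1L), "kind")
        uids <- vapply(pieces, `[[`, character(1L), "uid")
        gene_idx <- which(kinds == "gene")
        k <- sample_one(events$inversion_genes[1L]:events$inversion_genes[2L])
        if (length(gene_idx) < k) next
        s <- sample_one(seq_len(length(gene_idx) - k + 1L))
        lo <- gene_idx[s]
        hi <- gene_idx[s + k - 1L]
        if (any(uids[lo:hi] %in% frozen)) next
        if (any(!kinds[lo:hi] %in% c("gene", "spacer", "lost_gene"))) next
        run <- rev(lapply(pieces[lo:hi], revcomp_piece))
        gene_ids <- vapply(Filter(function(p) p$kind == "gene",
                                  pieces[lo:hi]),
                           function(p) p$gene$id, character(1L))
        chrom_pieces[[cid]] <- append(pieces[-(lo:hi)], run, after = lo - 1L)
        inverted_gene_sets[[length(inverted_gene_sets) + 1L]] <- gene_ids
        note("inversion", paste(gene_ids, collapse = ","))
        done <- TRUE
        break
      }
      if (!done) note("inversion_rejected", sprintf("event %d", iv))
    }
  }

  # 5. intron gain / loss
  mutate_intron <- function(gain) {
    for (t in 1:50) {
      cid <- sample(names(chrom_pieces), 1L)
      pieces <- chrom_pieces[[cid]]
      idx <- which(vapply(pieces, function(p) {
        p$kind == "gene" && !(p$uid %in% frozen)
      }, logical(1L)))
      if (length(idx) == 0L) return(FALSE)
      pi <- sample_one(idx)
      p <- pieces[[pi]]
      g <- p$gene
      L <- nchar(p$seq)
      seq_t <- if (g$strand == "-") revcomp(p$seq) else p$seq
      ex_t <- if (g$strand == "-") {
        ex <- cbind(L - g$exons_local[, 2L], L - g$exons_local[, 1L])
        ex[order(ex[, 1L]), , drop = FALSE]
      } else {
        g$exons_local
      }
      if (gain) {
        if (nrow(ex_t) - 1L >= 8L) next
        cdslen <- sum(ex_t[, 2L] - ex_t[, 1L])
        off <- sample_one(seq(6L, cdslen - 17L))
        ilen <- sample_one(params$intron_length_range[1L]:
                             params$intron_length_range[2L])
        cds_chars <- unlist(lapply(seq_len(nrow(ex_t)), function(i) {
          seq_chars(substr(seq_t, ex_t[i, 1L] + 1L, ex_t[i, 2L]))
        }))
        if (!splice_windows_clean(cds_chars, off, ilen,
                                  params$intron_length_range[2L])) next
        new_intron <- make_intron(ilen)
        # map CDS offset to transcript-piece position; keep clear of
        # existing exon boundaries so introns never become adjacent
        pos <- cds_offset_to_piece(ex_t, off)
        if (any(abs(pos - as.vector(ex_t)) < 3L)) next
        seq_t2 <- paste0(substr(seq_t, 1L, pos), new_intron,
                         substr(seq_t, pos + 1L, nchar(seq_t)))
        ex_t2 <- shift_exons_insert(ex_t, pos, ilen)
        note("intron_gain", sprintf("%s@%d", g$id, off))
      } else {
        if (nrow(ex_t) < 2L) next
        i <- sample_one(seq_len(nrow(ex_t) - 1L))
        d <- ex_t[i, 2L]
        a <- ex_t[i + 1L, 1L]
        seq_t2 <- paste0(substr(seq_t, 1L, d), substr(seq_t, a + 1L,
                                                      nchar(seq_t)))
        ex_t2 <- ex_t
        ex_t2[i, 2L] <- ex_t[i + 1L, 2L] - (a - d)
        if (i + 2L <= nrow(ex_t)) {
          sel <- (i + 2L):nrow(ex_t)
          ex_t2[sel, ] <- ex_t[sel, ] - (a - d)
        }
        ex_t2 <- ex_t2[-(i + 1L), , drop = FALSE]
        note("intron_loss", sprintf("%s#%d", g$id, i))
      }
      L2 <- nchar(seq_t2)
      if (g$strand == "-") {
        p$seq <- revcomp(seq_t2)
        ex2 <- cbind(L2 - ex_t2[, 2L], L2 - ex_t2[, 1L])
        p$gene$exons_local <- ex2[order(ex2[, 1L]), , drop = FALSE]
      } else {
        p$seq <- seq_t2
        p$gene$exons_local <- ex_t2
      }
      chrom_pieces[[cid]][[pi]] <<- p
      return(TRUE)
    }
    FALSE
  }
  if (events$intron_gain > 0L) {
    for (i in seq_len(events$intron_gain)) mutate_intron(TRUE)
  }
  if (events$intron_loss > 0L) {
    for (i in seq_len(events$intron_loss)) mutate_intron(FALSE)
  }

  asm <- assemble_pieces(species, chrom_pieces)
  all_runs <- c(ancestor$dup_runs, pending_dups)
  dups <- resolve_duplications(all_runs, asm$piece_map)
  truth <- structure(list(
    species = species, genome = asm$genome, annotation = asm$annotation,
    proteins = asm$proteins,
    families = data.frame(
      family_id = vapply(asm$annotation$genes, function(g) {
        b <- attr(g, "base")
        if (is.null(b)) NA_character_ else b
      }, character(1L)),
      gene_id = vapply(asm$annotation$genes, `[[`, character(1L), "id"),
      stringsAsFactors = FALSE),
    telomeres = asm$telomeres, subtelomeres = asm$subtelomeres,
    fillers = asm$fillers, spacer_lengths = asm$spacer_lengths,
    duplications = dups, dup_runs = all_runs,
    pieces = chrom_pieces, frozen = frozen,
    events = log, params = params,
    inverted_gene_sets = inverted_gene_sets), class = "sim_truth")
  truth$families <- truth$families[!is.na(truth$families$family_id), ,
                                   drop = FALSE]
  truth
}

# continue uid numbering past the largest existing uid
new_uid_factory_offset <- function(chrom_pieces) {
  uids <- unlist(lapply(chrom_pieces, function(ps) {
    vapply(ps, `[[`, character(1L), "uid")
  }))
  counter <- max(as.integer(sub("^p", "", uids)))
  function() {
    counter <<- counter + 1L
    sprintf("p%06d", counter)
  }
}

cds_offset_to_piece <- function(ex_t, off) {
  remaining <- off
  for (i in seq_len(nrow(ex_t))) {
    w <- ex_t[i, 2L] - ex_t[i, 1L]
    if (remaining <= w) return(ex_t[i, 1L] + remaining)
    remaining <- remaining - w
  }
  ex_t[nrow(ex_t), 2L]
}

shift_exons_insert <- function(ex_t, pos, ilen) {
  out <- NULL
  for (i in seq_len(nrow(ex_t))) {
    s <- ex_t[i, 1L]; e <- ex_t[i, 2L]
    if (e <= pos) {
      out <- rbind(out, c(s, e))
    } else if (s >= pos) {
      out <- rbind(out, c(s + ilen, e + ilen))
    } else {
      out <- rbind(out, c(s, pos), c(pos + ilen, e + ilen))
    }
  }
  out
}

#' Score predictions against planted truth
#'
#' Genes match on exact structure (chromosome, strand, full exon
#' coordinates); introns on exact (chromosome, strand, donor, acceptor);
#' planted duplications are recovered when a predicted region contains both
#' planted copies with the same orientation.
#'
#' @param truth a `sim_truth`.
#' @param predicted an `nm_annotation` of predicted genes (protein-coding
#'   categories are scored).
#' @param predicted_dups optional data.frame from
#'   [find_duplicated_regions()].
#' @return list with gene_recall, gene_precision, protein_exact (fraction of
#'   matched genes whose predicted protein equals the planted protein),
#'   intron_recall, intron_precision, duplication_recall (NA when nothing
#'   was planted), and the underlying counts.
#' @export
score_predictions <- function(truth, predicted, predicted_dups = NULL) {
  gene_key <- function(ann, categories = PROTEIN_CATEGORIES) {
    keep <- Filter(function(g) g$category %in% categories, ann$genes)
    keys <- vapply(keep, function(g) {
      paste(g$chromosome_id, g$strand,
            paste(t(g$exons), collapse = ","), sep = "|")
    }, character(1L))
    stats::setNames(keys, vapply(keep, `[[`, character(1L), "id"))
  }
  tk <- gene_key(truth$annotation)
  pk <- gene_key(predicted)
  matched_truth <- tk %in% pk
  matched_pred <- pk %in% tk
  # protein identity on matched structures
  prot_ok <- NA_real_
  if (any(matched_truth)) {
    pred_prot <- attr(predicted, "proteins")
    if (!is.null(pred_prot)) {
      inv <- stats::setNames(names(pk), pk)
      ok <- vapply(names(tk)[matched_truth], function(tid) {
        pid <- inv[[tk[[tid]]]]
        identical(unname(truth$proteins[[tid]]), unname(pred_prot[[pid]]))
      }, logical(1L))
      prot_ok <- mean(ok)
    }
  }
  ikey <- function(ann) {
    d <- annotation_introns(ann)
    if (nrow(d) == 0L) return(character(0))
    paste(d$chromosome_id, d$strand, d$donor, d$acceptor, sep = "|")
  }
  ti <- ikey(truth$annotation)
  pi <- ikey(predicted)
  dup_recall <- NA_real_
  if (!is.null(truth$duplications) && nrow(truth$duplications) > 0L) {
    pd <- predicted_dups
    rec <- vapply(seq_len(nrow(truth$duplications)), function(i) {
      d <- truth$duplications[i, ]
      if (is.null(pd) || nrow(pd) == 0L) return(FALSE)
      hit <- (pd$chrom_a == d$chrom_a & pd$chrom_b == d$chrom_b &
                pd$start_a <= d$start_a & pd$end_a >= d$end_a &
                pd$start_b <= d$start_b & pd$end_b >= d$end_b) |
        (pd$chrom_a == d$chrom_b & pd$chrom_b == d$chrom_a &
           pd$start_a <= d$start_b & pd$end_a >= d$end_b &
           pd$start_b <= d$start_a & pd$end_b >= d$end_a)
      any(hit & pd$orientation == d$orientation)
    }, logical(1L))
    dup_recall <- mean(rec)
  }
  list(gene_recall = if (length(tk)) mean(matched_truth) else NA_real_,
       gene_precision = if (length(pk)) mean(matched_pred) else NA_real_,
       protein_exact = prot_ok,
       intron_recall = if (length(ti)) mean(ti %in% pi) else NA_real_,
       intron_precision = if (length(pi)) mean(pi %in% ti) else NA_real_,
       duplication_recall = dup_recall,
       n_truth_genes = length(tk), n_predicted_genes = length(pk),
       n_truth_introns = length(ti), n_predicted_introns = length(pi))
}
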