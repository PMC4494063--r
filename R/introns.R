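# Cross-genome intron comparison: size spectra, position conservation on a
# family protein alignment, and oversized (putatively fused) introns with
# relict internal AG boundaries.

#' Intron size histogram
#'
#' @param annotation an `nm_annotation`.
#' @return data.frame with columns length, count, proportion (percent),
#'   sorted by length; attribute `"total"` holds the intron count and
#'   attribute `"mode"` the most frequent length (NA when empty).
#' @export
intron_size_histogram <- function(annotation) {
  intr <- annotation_introns(annotation)
  if (nrow(intr) == 0L) {
    out <- data.frame(length = integer(), count = integer(),
                      proportion = numeric())
    attr(out, "total") <- 0L
    attr(out, "mode") <- NA_integer_
    return(out)
  }
  tab <- table(intr$length)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab),
                    proportion = 100 * as.integer(tab) / nrow(intr))
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(intr)
  attr(out, "mode") <- out$length[which.max(out$count)]
  out
}

# global pairwise alignment helper (affine gaps, BLOSUM62)
align_global_pair <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  list(score = as.numeric(Biostrings::score(aln)),
       a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Center-star multiple alignment of a homolog family
#'
#' Progressive center-star alignment built from pairwise global alignments
#' ("once a gap, always a gap"). The center is the member with the maximum
#' summed pairwise score (ties broken by id order), so the procedure is
#' fully deterministic.
#'
#' @param proteins named character vector of at least two member proteins.
#' @return list of class `nm_msa` with `ids`, `rows` (gapped strings of equal
#'   width), `center` (center member id) and `width`.
#' @export
align_family <- function(proteins) {
  if (length(proteins) < 2L) stop("a family alignment needs at least 2 members")
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  ord <- order(ids)
  proteins <- proteins[ord]
  ids <- ids[ord]
  n <- length(proteins)
  pair <- vector("list", n)
  sums <- numeric(n)
  for (i in seq_len(n)) pair[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_global_pair(proteins[[i]], proteins[[j]])
      pair[[i]][[j]] <- al
      sums[i] <- sums[i] + al$score
      sums[j] <- sums[j] + al$score
    }
  }
  center <- which.max(sums)  # ids sorted, so ties resolve by id order
  L <- nchar(proteins[[center]])

  # rows as char vectors; center residue i sits at column center_cols[i]
  rows <- list()
  rows[[ids[center]]] <- seq_chars(proteins[[center]])
  center_cols <- seq_len(L)
  width <- L

  insert_gap_cols <- function(at, k) {
    # insert k all-gap columns so that they occupy positions at..at+k-1
    for (nm in names(rows)) {
      v <- rows[[nm]]
      rows[[nm]] <<- append(v, rep("-", k), after = at - 1L)
    }
    center_cols <<- ifelse(center_cols >= at, center_cols + k, center_cols)
    width <<- width + k
  }

  for (m in seq_len(n)) {
    if (m == center) next
    al <- if (m < center) pair[[m]][[center]] else pair[[center]][[m]]
    if (m < center) {
      c_row <- seq_chars(al$b); m_row <- seq_chars(al$a)
    } else {
      c_row <- seq_chars(al$a); m_row <- seq_chars(al$b)
    }
    # slot s (0..L): member residues inserted before center residue s+1
    k_new <- integer(L + 1L)
    slot <- 0L
    for (p in seq_along(c_row)) {
      if (c_row[p] == "-") {
        k_new[slot + 1L] <- k_new[slot + 1L] + 1L
      } else {
        slot <- slot + 1L
      }
    }
    # existing insertion columns per slot
    bounds <- c(0L, center_cols, width + 1L)
    k_cur <- (bounds[-1L] - bounds[-length(bounds)]) - 1L
    k_cur[1L] <- center_cols[1L] - 1L
    k_cur[L + 1L] <- width - center_cols[L]
    for (s in seq_len(L + 1L)) {
      if (k_new[s] > k_cur[s]) {
        at <- if (s <= L) center_cols[s] else width + 1L
        insert_gap_cols(at, k_new[s] - k_cur[s])
        bounds <- c(0L, center_cols, width + 1L)
        k_cur <- (bounds[-1L] - bounds[-length(bounds)]) - 1L
        k_cur[1L] <- center_cols[1L] - 1L
        k_cur[L + 1L] <- width - center_cols[L]
      }
    }
    # lay the member into the expanded frame: insertions right-aligned
    # against the next center residue
    out <- rep("-", width)
    slot_chars <- vector("list", L + 1L)
    aligned_to <- rep(NA_character_, L)
    slot <- 0L
    for (p in seq_along(c_row)) {
      if (c_row[p] == "-") {
        slot_chars[[slot + 1L]] <- c(slot_chars[[slot + 1L]], m_row[p])
      } else {
        slot <- slot + 1L
        aligned_to[slot] <- m_row[p]
      }
    }
    for (i in seq_len(L)) out[center_cols[i]] <- aligned_to[i]
    for (s in seq_len(L + 1L)) {
      chars <- slot_chars[[s]]
      if (is.null(chars)) next
      hi <- if (s <= L) center_cols[s] - 1L else width
      out[(hi - length(chars) + 1L):hi] <- chars
    }
    rows[[ids[m]]] <- out
  }

  rows <- rows[ids]
  structure(list(ids = ids,
                 rows = vapply(rows, paste, character(1L), collapse = ""),
                 center = ids[center], width = width),
            class = "nm_msa")
}

#' @export
print.nm_msa <- function(x, ...) {
  cat(sprintf("<nm_msa> %d sequences, width %d (center %s)\n",
              length(x$ids), x$width, x$center))
  invisible(x)
}

#' Map intron positions of a family onto its protein alignment
#'
#' Each intron is located at the protein residue containing (phase 1/2) or
#' following (phase 0) the splice, then mapped through the member's aligned
#' row to an alignment column. Two introns are identical in position iff
#' they share both alignment column and phase.
#'
#' @param family_id family label for the output.
#' @param alignment an `nm_msa` over the family members (names = gene ids).
#' @param annotations named list of `nm_annotation` objects (names = genome
#'   labels); every aligned gene must belong to exactly one of them.
#' @return data.frame with columns family_id, genome, gene_id,
#'   alignment_column, phase.
#' @export
map_intron_positions <- function(family_id, alignment, annotations) {
  out <- list()
  for (gid in alignment$ids) {
    genome_label <- NULL
    gene <- NULL
    for (glab in names(annotations)) {
      g <- annotations[[glab]]$genes[[gid]]
      if (!is.null(g)) {
        genome_label <- glab
        gene <- g
        break
      }
    }
    if (is.null(gene)) stop(sprintf("gene '%s' absent from annotations", gid))
    row <- seq_chars(alignment$rows[[gid]])
    res_cols <- which(row != "-")
    intr <- gene_introns(gene)
    for (i in seq_len(nrow(intr))) {
      # spliced nt upstream of the splice, in transcript orientation
      offset <- sum(diff_exon_before(gene, i))
      residue <- offset %/% 3L + 1L
      phase <- offset %% 3L
      # an intron inside/before the stop codon maps past the last residue;
      # use a virtual end column so it never collides with a real position
      col <- if (residue > length(res_cols)) alignment$width + 1L else
        res_cols[residue]
      out[[length(out) + 1L]] <- data.frame(
        family_id = family_id, genome = genome_label, gene_id = gid,
        alignment_column = col, phase = phase,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(family_id = character(), genome = character(),
                      gene_id = character(), alignment_column = integer(),
                      phase = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# spliced exon lengths upstream of intron i (transcript orientation)
diff_exon_before <- function(gene, i) {
  ex <- gene$exons
  exlen <- ex[, 2L] - ex[, 1L]
  if (gene$strand == "+") {
    exlen[seq_len(i)]
  } else {
    rev(exlen)[seq_len(i)]
  }
}

#' Summarize cross-genome intron position conservation
#'
#' An intron site is a distinct (family, alignment column, phase) triple.
#' A site is identical-in-all when all `n_genomes` genomes carry an intron
#' there, and shared when at least two do. Percentages are over sites by
#' default; `unit = "occurrence"` weights every intron record instead
#' (the convention used when quoting "x% of introns").
#'
#' @param positions data.frame from [map_intron_positions()] (possibly
#'   concatenated over families).
#' @param n_genomes number of genomes compared.
#' @param unit "site" (default) or "occurrence".
#' @return list with n_introns_compared, n_sites, pct_identical_all,
#'   pct_shared_ge2, unit.
#' @export
conservation_summary <- function(positions, n_genomes,
                                 unit = c("site", "occurrence")) {
  unit <- match.arg(unit)
  if (nrow(positions) == 0L) {
    return(list(n_introns_compared = 0L, n_sites = 0L,
                pct_identical_all = NA_real_, pct_shared_ge2 = NA_real_,
                unit = unit))
  }
  key <- paste(positions$family_id, positions$alignment_column,
               positions$phase, sep = "|")
  genomes_per_site <- tapply(positions$genome, key,
                             function(g) length(unique(g)))
  site_of <- genomes_per_site[key]
  if (unit == "site") {
    denom <- length(genomes_per_site)
    ident <- sum(genomes_per_site >= n_genomes)
    shared <- sum(genomes_per_site >= 2L)
  } else {
    denom <- nrow(positions)
    ident <- sum(site_of >= n_genomes)
    shared <- sum(site_of >= 2L)
  }
  list(n_introns_compared = nrow(positions),
       n_sites = length(genomes_per_site),
       pct_identical_all = 100 * ident / denom,
       pct_shared_ge2 = 100 * shared / denom,
       unit = unit)
}

#' Detect oversized introns and relict internal AG boundaries
#'
#' Introns longer than `threshold` are flagged; each is scanned for internal
#' AG dinucleotides whose prefix (from the donor GT to the AG, inclusive)
#' has ultrasmall-intron length (18-23 nt). Such a relict AG at the center
#' is the footprint expected if the intron arose by fusion of two ultrasmall
#' introns.
#'
#' @param annotation an `nm_annotation`.
#' @param genome the matching `nm_genome`.
#' @param threshold maximum normal intron length (default 23 nt).
#' @param relict_range prefix lengths compatible with an ultrasmall intron
#'   (default c(18, 23)).
#' @return data.frame with columns gene_id, length, sequence, relict_ag
#'   (comma-separated prefix lengths at internal AGs in range; "" if none).
#' @export
detect_oversized_introns <- function(annotation, genome, threshold = 23L,
                                     relict_range = c(18L, 23L)) {
  intr <- annotation_introns(annotation, genome)
  out <- data.frame(gene_id = character(), length = integer(),
                    sequence = character(), relict_ag = character(),
                    stringsAsFactors = FALSE)
  big <- intr[intr$length > threshold, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    chrom <- genome$chromosomes[[big$chromosome_id[i]]]
    s <- substr(chrom, big$donor[i] + 1L, big$acceptor[i])
    if (big$strand[i] == "-") s <- revcomp(s)
    v <- seq_chars(s)
    L <- length(v)
    relict <- integer(0)
    for (p in seq_len(L - 1L)) {
      if (p + 1L == L) next  # terminal AG, not internal
      if (v[p] == "A" && v[p + 1L] == "G" &&
          p + 1L >= relict_range[1L] && p + 1L <= relict_range[2L]) {
        relict <- c(relict, p + 1L)
      }
    }
    out <- rbind(out, data.frame(
      gene_id = big$gene_id[i], length = big$length[i], sequence = s,
      relict_ag = paste(relict, collapse = ","), stringsAsFactors = FALSE))
  }
  out
}
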