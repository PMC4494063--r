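# Collinear synteny-block detection between two annotated genomes.
#
# Genes are ranked along each chromosome; family-matched gene pairs form
# match points, and a block is a chain of matches strictly monotonic in both
# genomes (ascending in A, ascending or descending in B) with at most
# `max_gap` unmatched intervening genes on either side. Chains are assigned
# non-overlapping: small instances are solved as an exact chain-set packing,
# larger instances greedily by descending chain size.

# per-genome gene ranks: all annotated genes, ordered by chromosome + start
ranked_genes <- function(annotation, families, exclude = NULL,
                         collapse_tandem = TRUE) {
  gt <- gene_table(annotation)
  if (nrow(gt) == 0L) return(gt)
  look <- family_lookup(families)
  gt$family_id <- ifelse(gt$id %in% names(look), look[gt$id], NA_character_)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    drop <- vapply(seq_len(nrow(gt)), function(i) {
      any(exclude$chromosome_id == gt$chromosome_id[i] &
            exclude$start <= gt$start[i] & exclude$stop >= gt$end[i])
    }, logical(1L))
    gt <- gt[!drop, , drop = FALSE]
  }
  gt <- gt[order(gt$chromosome_id, gt$start), , drop = FALSE]
  gt$rank <- stats::ave(seq_len(nrow(gt)), gt$chromosome_id,
                        FUN = seq_along)
  if (collapse_tandem && nrow(gt) > 1L) {
    same <- c(FALSE, !is.na(gt$family_id[-1L]) &
                gt$family_id[-1L] == gt$family_id[-nrow(gt)] &
                gt$chromosome_id[-1L] == gt$chromosome_id[-nrow(gt)])
    # drop the family label of tandem followers; they stay as rank fillers
    gt$family_id[same] <- NA_character_
  }
  rownames(gt) <- NULL
  gt
}

# all maximal-score chains on one chromosome pair via DP; returns the single
# best chain (for greedy assignment). m: data.frame ra, rb, idx (match ids).
best_chain_dp <- function(ra, rb, max_gap, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  M <- length(ra)
  if (M == 0L) return(NULL)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  f <- rep(1L, M)
  par <- rep(0L, M)
  step <- max_gap + 1L
  for (i in seq_len(M)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      if (da <= 0L || da > step) next
      db <- if (direction == "asc") rb[i] - rb[j] else rb[j] - rb[i]
      if (db <= 0L || db > step) next
      if (f[j] + 1L > f[i]) {
        f[i] <- f[j] + 1L
        par[i] <- j
      }
    }
  }
  best <- which.max(f)
  chain <- integer(0)
  i <- best
  while (i != 0L) {
    chain <- c(i, chain)
    i <- par[i]
  }
  list(size = f[best], members = ord[chain], direction = direction)
}

# enumerate every valid chain of length >= min_genes (DFS over successors)
enumerate_chains <- function(ra, rb, max_gap, min_genes) {
  M <- length(ra)
  step <- max_gap + 1L
  chains <- list()
  succ <- function(i, direction) {
    out <- integer(0)
    for (j in seq_len(M)) {
      da <- ra[j] - ra[i]
      if (da <= 0L || da > step) next
      db <- if (direction == "asc") rb[j] - rb[i] else rb[i] - rb[j]
      if (db <= 0L || db > step) next
      out <- c(out, j)
    }
    out
  }
  grow <- function(path, direction) {
    if (length(path) >= min_genes) {
      chains[[length(chains) + 1L]] <<- list(members = path,
                                             direction = direction)
    }
    for (j in succ(path[length(path)], direction)) {
      grow(c(path, j), direction)
    }
  }
  for (i in seq_len(M)) {
    for (direction in c("asc", "desc")) {
      grow(i, direction)
    }
  }
  chains
}

# exact maximum-coverage disjoint chain packing (small instances):
# branch and bound over enumerated chains, disjointness on both gene sides
pack_chains_exact <- function(ra, rb, max_gap, min_genes) {
  chains <- enumerate_chains(ra, rb, max_gap, min_genes)
  if (length(chains) == 0L) return(list())
  sizes <- vapply(chains, function(c) length(c$members), integer(1L))
  ord <- order(-sizes)
  chains <- chains[ord]
  sizes <- sizes[ord]
  n_ch <- length(chains)
  best_sel <- list()
  best_total <- -1L
  M <- length(ra)
  used_a <- logical(max(ra))
  used_b <- logical(max(rb))
  recurse <- function(start, total, sel) {
    if (total > best_total) {
      best_total <<- total
      best_sel <<- sel
    }
    if (start > n_ch) return()
    # bound: remaining chains can add at most sum of remaining sizes
    if (total + sum(sizes[start:n_ch]) <= best_total) return()
    for (ci in start:n_ch) {
      mem <- chains[[ci]]$members
      if (any(used_a[ra[mem]]) || any(used_b[rb[mem]])) next
      used_a[ra[mem]] <<- TRUE
      used_b[rb[mem]] <<- TRUE
      recurse(ci + 1L, total + sizes[ci], c(sel, list(chains[[ci]])))
      used_a[ra[mem]] <<- FALSE
      used_b[rb[mem]] <<- FALSE
    }
  }
  recurse(1L, 0L, list())
  best_sel
}

# greedy chain assignment (large instances)
pack_chains_greedy <- function(ra, rb, max_gap, min_genes) {
  sel <- list()
  avail <- rep(TRUE, length(ra))
  repeat {
    ids <- which(avail)
    if (length(ids) == 0L) break
    asc <- best_chain_dp(ra[ids], rb[ids], max_gap, "asc")
    desc <- best_chain_dp(ra[ids], rb[ids], max_gap, "desc")
    pick <- NULL
    if (!is.null(asc) && (is.null(desc) || asc$size >= desc$size)) pick <- asc
    else pick <- desc
    if (is.null(pick) || pick$size < min_genes) break
    members <- ids[pick$members]
    sel[[length(sel) + 1L]] <- list(members = members,
                                    direction = pick$direction)
    # block genes: no gene in more than one block per genome pair
    avail[ra %in% ra[members]] <- FALSE
    avail[rb %in% rb[members]] <- FALSE
  }
  sel
}

#' Detect collinear synteny blocks between two annotated genomes
#'
#' @param annotation_a,annotation_b `nm_annotation` objects.
#' @param families data.frame from [build_families()] covering both genomes.
#' @param min_genes minimum homologous genes per block (default 4).
#' @param max_gap maximum unmatched intervening genes on either genome
#'   (default 3).
#' @param exclude_a,exclude_b optional interval data.frames
#'   (chromosome_id, start, stop) masking e.g. subtelomeric repeat genes.
#' @param collapse_tandem collapse runs of same-family tandem neighbors to a
#'   single anchor (default TRUE).
#' @param exact_max_matches chromosome-pair instances with at most this many
#'   match points are solved by exact chain-set packing; larger ones
#'   greedily (default 20).
#' @return an object of class `nm_synteny`: list of blocks, each with
#'   genome_pair, chrom_a, chrom_b, orientation ("same"/"inverted"), size,
#'   and `pairs` (data.frame gene_a, gene_b in chain order).
#' @export
find_synteny_blocks <- function(annotation_a, annotation_b, families,
                                min_genes = 4L, max_gap = 3L,
                                exclude_a = NULL, exclude_b = NULL,
                                collapse_tandem = TRUE,
                                exact_max_matches = 20L) {
  ga <- ranked_genes(annotation_a, families, exclude_a, collapse_tandem)
  gb <- ranked_genes(annotation_b, families, exclude_b, collapse_tandem)
  blocks <- list()
  if (nrow(ga) == 0L || nrow(gb) == 0L) {
    return(structure(blocks, class = "nm_synteny"))
  }
  fa <- ga[!is.na(ga$family_id), , drop = FALSE]
  fb <- gb[!is.na(gb$family_id), , drop = FALSE]
  for (ca in unique(fa$chromosome_id)) {
    for (cb in unique(fb$chromosome_id)) {
      sa <- fa[fa$chromosome_id == ca, , drop = FALSE]
      sb <- fb[fb$chromosome_id == cb, , drop = FALSE]
      common <- intersect(sa$family_id, sb$family_id)
      if (length(common) == 0L) next
      # match points
      mm <- merge(sa[sa$family_id %in% common,
                     c("id", "family_id", "rank")],
                  sb[sb$family_id %in% common,
                     c("id", "family_id", "rank")],
                  by = "family_id", suffixes = c("_a", "_b"))
      if (nrow(mm) == 0L) next
      mm <- mm[order(mm$rank_a, mm$rank_b), , drop = FALSE]
      ra <- mm$rank_a; rb <- mm$rank_b
      sel <- if (nrow(mm) <= exact_max_matches) {
        pack_chains_exact(ra, rb, max_gap, min_genes)
      } else {
        pack_chains_greedy(ra, rb, max_gap, min_genes)
      }
      for (ch in sel) {
        mem <- ch$members
        # order members along genome A
        mem <- mem[order(ra[mem])]
        blocks[[length(blocks) + 1L]] <- list(
          genome_pair = c(annotation_a$species, annotation_b$species),
          chrom_a = ca, chrom_b = cb,
          orientation = if (ch$direction == "asc") "same" else "inverted",
          size = length(mem),
          pairs = data.frame(gene_a = mm$id_a[mem], gene_b = mm$id_b[mem],
                             stringsAsFactors = FALSE))
      }
    }
  }
  # deterministic block order: by size desc, then coordinates
  if (length(blocks) > 1L) {
    key <- vapply(blocks, function(b) {
      sprintf("%06d|%s|%s|%s", 999999L - b$size, b$chrom_a, b$chrom_b,
              b$pairs$gene_a[1L])
    }, character(1L))
    blocks <- blocks[order(key)]
  }
  structure(blocks, class = "nm_synteny")
}

#' @export
print.nm_synteny <- function(x, ...) {
  cat(sprintf("<nm_synteny> %d block(s)\n", length(x)))
  for (b in x) {
    cat(sprintf("  %s:%s ~ %s:%s  %d genes  %s\n",
                b$genome_pair[1L], b$chrom_a, b$genome_pair[2L], b$chrom_b,
                b$size, b$orientation))
  }
  invisible(x)
}

#' Summarize synteny blocks
#'
#' @param blocks an `nm_synteny` object (one genome pair).
#' @return named numeric vector `c(mean_genes, n_blocks)`; `c(0, 0)` when
#'   empty.
#' @export
block_summary <- function(blocks) {
  if (length(blocks) == 0L) return(c(mean_genes = 0, n_blocks = 0))
  sizes <- vapply(blocks, `[[`, numeric(1L), "size")
  c(mean_genes = mean(sizes), n_blocks = length(sizes))
}

#' Find ORFans occupying conserved syntenic positions
#'
#' Reports ORFans in genome A whose nearest family-matched neighbors flank,
#' in genome B, one gene (or two adjacent ORFans, a split correspondence)
#' outside the ORFan's own family. Such positional homology suggests the
#' ORFan arose by sequence divergence of the counterpart.
#'
#' @param blocks an `nm_synteny` object from [find_synteny_blocks()].
#' @param annotation_a,annotation_b the two annotations.
#' @param families family table used for the blocks.
#' @return data.frame with columns orfan_id, counterpart_id, left_family,
#'   right_family, split (logical).
#' @export
find_syntenic_orfans <- function(blocks, annotation_a, annotation_b,
                                 families) {
  out <- data.frame(orfan_id = character(), counterpart_id = character(),
                    left_family = character(), right_family = character(),
                    split = logical(), stringsAsFactors = FALSE)
  ga <- ranked_genes(annotation_a, families, collapse_tandem = FALSE)
  gb <- ranked_genes(annotation_b, families, collapse_tandem = FALSE)
  if (nrow(ga) == 0L || nrow(gb) == 0L) return(out)
  # gene pairs matched inside blocks
  matched_a <- unlist(lapply(blocks, function(b) b$pairs$gene_a))
  matched_b <- unlist(lapply(blocks, function(b) b$pairs$gene_b))
  counterpart <- stats::setNames(matched_b, matched_a)
  orfans <- ga[ga$category == "ORFan", , drop = FALSE]
  for (i in seq_len(nrow(orfans))) {
    o <- orfans[i, ]
    chr <- ga[ga$chromosome_id == o$chromosome_id, , drop = FALSE]
    pos <- which(chr$id == o$id)
    left <- chr[seq_len(pos - 1L), , drop = FALSE]
    right <- chr[-seq_len(pos), , drop = FALSE]
    left <- left[!is.na(left$family_id) & left$id %in% names(counterpart), ,
                 drop = FALSE]
    right <- right[!is.na(right$family_id) & right$id %in% names(counterpart), ,
                   drop = FALSE]
    if (nrow(left) == 0L || nrow(right) == 0L) next
    lg <- left[nrow(left), ]
    rg <- right[1L, ]
    lb <- counterpart[[lg$id]]
    rb <- counterpart[[rg$id]]
    bchr <- gb[gb$id %in% c(lb, rb), "chromosome_id"]
    if (length(unique(bchr)) != 1L) next
    bsub <- gb[gb$chromosome_id == bchr[1L], , drop = FALSE]
    p1 <- which(bsub$id == lb)
    p2 <- which(bsub$id == rb)
    if (length(p1) != 1L || length(p2) != 1L) next
    lo <- min(p1, p2); hi <- max(p1, p2)
    if (hi - lo < 2L) next
    between <- bsub[(lo + 1L):(hi - 1L), , drop = FALSE]
    # not the ORFan's own family
    between <- between[is.na(between$family_id) |
                         is.na(o$family_id) |
                         between$family_id != o$family_id, , drop = FALSE]
    if (nrow(between) == 1L) {
      out <- rbind(out, data.frame(
        orfan_id = o$id, counterpart_id = between$id[1L],
        left_family = lg$family_id, right_family = rg$family_id,
        split = FALSE, stringsAsFactors = FALSE))
    } else if (nrow(between) == 2L && all(between$category == "ORFan")) {
      out <- rbind(out, data.frame(
        orfan_id = o$id, counterpart_id = between$id,
        left_family = lg$family_id, right_family = rg$family_id,
        split = TRUE, stringsAsFactors = FALSE))
    }
  }
  out
}
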