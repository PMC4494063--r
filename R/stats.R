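# Genome summary statistics: GC, gene density, intergenic spacers, classical
# one-way ANOVA / two-sample t wrappers, cross-genome gene-content
# comparison and the per-genome summary record.

#' GC content of a genome
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from the
#' denominator.
#'
#' @param genome an `nm_genome`.
#' @return percent GC (full precision; round to 1 decimal for reports).
#' @export
gc_content <- function(genome) {
  if (total_bp(genome) == 0L) stop("zero-length genome")
  counts <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (s in genome$chromosomes) {
    tab <- table(factor(seq_chars(s), levels = names(counts)))
    counts <- counts + as.numeric(tab)
  }
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) stop("genome contains no A/C/G/T bases")
  100 * sum(counts[c("G", "C")]) / acgt
}

#' Gene density in genes per kb
#'
#' Total gene count (all categories) divided by genome size in kb.
#'
#' @param annotation an `nm_annotation` (or a plain gene count).
#' @param genome an `nm_genome` (or a plain genome size in bp).
#' @return genes per kb (full precision; round to 2 decimals for reports).
#' @export
gene_density <- function(annotation, genome) {
  n_genes <- if (inherits(annotation, "nm_annotation")) {
    length(annotation$genes)
  } else {
    as.numeric(annotation)
  }
  size <- if (inherits(genome, "nm_genome")) total_bp(genome) else as.numeric(genome)
  if (size <= 0) stop("genome size must be positive")
  n_genes / (size / 1000)
}

#' Intergenic spacer lengths
#'
#' Gaps between consecutive annotated feature spans per chromosome; terminal
#' flanks are excluded and overlapping or abutting features yield no gap.
#'
#' @param annotation an `nm_annotation`.
#' @param genome the matching `nm_genome` (used for chromosome membership
#'   only).
#' @param include_rna include RNA genes as features (default TRUE).
#' @param exclude optional data.frame (chromosome_id, start, stop) of
#'   intervals whose features are dropped first (e.g. to keep a single
#'   representative of collapsed subtelomeric repeats).
#' @return list with `lengths` (integer vector), `mean` and `n`.
#' @export
intergenic_lengths <- function(annotation, genome, include_rna = TRUE,
                               exclude = NULL) {
  gt <- gene_table(annotation)
  if (!include_rna) gt <- gt[!gt$category %in% RNA_CATEGORIES, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0L && nrow(gt) > 0L) {
    drop <- vapply(seq_len(nrow(gt)), function(i) {
      any(exclude$chromosome_id == gt$chromosome_id[i] &
            exclude$start <= gt$start[i] & exclude$stop >= gt$end[i])
    }, logical(1L))
    gt <- gt[!drop, , drop = FALSE]
  }
  lens <- integer(0)
  for (chr in unique(gt$chromosome_id)) {
    sub <- gt[gt$chromosome_id == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2L) next
    reach <- cummax(sub$end)
    gaps <- sub$start[-1L] - reach[-nrow(sub)]
    lens <- c(lens, gaps[gaps > 0L])
  }
  list(lengths = lens,
       mean = if (length(lens) > 0L) mean(lens) else NA_real_,
       n = length(lens))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with (k-1, N-k) degrees of
#' freedom, as computed by [stats::oneway.test()] with equal variances.
#' The degenerate all-identical case returns F = 0, p = 1.
#'
#' @param groups list of at least 2 numeric vectors, each of length >= 2.
#' @return named vector c(F, p).
#' @export
anova_one_way <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  res <- suppressWarnings(stats::oneway.test(value ~ grp, var.equal = TRUE))
  F <- unname(res$statistic)
  p <- unname(res$p.value)
  if (!is.finite(F)) {
    means <- vapply(groups, mean, numeric(1L))
    if (max(means) - min(means) < .Machine$double.eps^0.5) {
      F <- 0
      p <- 1
    }
  }
  c(F = F, p = p)
}

#' Two-sample Student t-test
#'
#' Pooled-variance two-sided t by default ([stats::t.test()] with
#' `var.equal = TRUE`); Welch's unequal-variance form via `welch = TRUE`.
#' The degenerate constant-data case returns t = 0, p = 1 when the means
#' are equal.
#'
#' @param a,b numeric vectors of length >= 2.
#' @param welch use Welch's t (default FALSE).
#' @return named vector c(t, p).
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (abs(mean(a) - mean(b)) < .Machine$double.eps^0.5) {
      return(c(t = 0, p = 1))
    }
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  c(t = unname(res$statistic), p = unname(res$p.value))
}

#' Compare gene content across genomes by family presence
#'
#' For every non-empty subset of genomes, counts homolog families present in
#' exactly that subset. Families shared by all genomes are split into
#' function-predicted (any member function-predicted) versus ORFan.
#'
#' @param annotations named list of family-labeled `nm_annotation` objects.
#' @return list with `presence` (named list of family-id sets),
#'   `subset_counts` (data.frame subset, count), `shared_all`,
#'   `shared_all_function_predicted`, `shared_all_orfan`,
#'   `pct_shared_of_union`.
#' @export
gene_content_comparison <- function(annotations) {
  stopifnot(length(annotations) >= 2L, !is.null(names(annotations)))
  presence <- lapply(annotations, function(ann) {
    fams <- vapply(ann$genes, `[[`, character(1L), "family_id")
    sort(unique(fams[!is.na(fams)]))
  })
  all_fams <- sort(unique(unlist(presence)))
  member_mask <- vapply(presence, function(s) all_fams %in% s,
                        logical(length(all_fams)))
  if (length(all_fams) == 1L) member_mask <- matrix(member_mask, nrow = 1L)
  subset_key <- apply(member_mask, 1L, function(r) {
    paste(names(annotations)[r], collapse = "+")
  })
  counts <- table(subset_key)
  subset_counts <- data.frame(subset = names(counts),
                              count = as.integer(counts),
                              stringsAsFactors = FALSE)
  shared_all_ids <- all_fams[rowSums(member_mask) == length(annotations)]
  # family category: function-predicted if any member gene is
  fam_cat <- new.env(parent = emptyenv(), hash = TRUE)
  for (ann in annotations) {
    for (g in ann$genes) {
      if (is.na(g$family_id)) next
      if (g$category == "function-predicted") fam_cat[[g$family_id]] <- TRUE
    }
  }
  n_fp <- sum(vapply(shared_all_ids, function(f) isTRUE(fam_cat[[f]]),
                     logical(1L)))
  list(presence = presence,
       subset_counts = subset_counts,
       shared_all = length(shared_all_ids),
       shared_all_function_predicted = n_fp,
       shared_all_orfan = length(shared_all_ids) - n_fp,
       pct_shared_of_union = if (length(all_fams) > 0L)
         100 * length(shared_all_ids) / length(all_fams) else NA_real_)
}

#' Per-genome summary report
#'
#' Assembles the genome-feature record: size, per-chromosome sizes, GC, gene
#' counts by category, intron count and introns per protein-coding gene
#' (duplicates included in the denominator), gene density, mean intergenic
#' length, and duplicated-sequence totals (internal and subtelomeric).
#'
#' @param genome an `nm_genome`.
#' @param annotation the matching `nm_annotation`.
#' @param subtelomere optional result of [find_shared_terminal_repeat()].
#' @param duplications optional data.frame from [find_duplicated_regions()].
#' @return a list of class `nm_summary` (rounded per reporting convention:
#'   GC 1 decimal, density 2 decimals, introns/gene 1 decimal, intergenic
#'   mean 1 decimal).
#' @export
summary_report <- function(genome, annotation, subtelomere = NULL,
                           duplications = NULL) {
  gt <- gene_table(annotation)
  n_protein <- sum(gt$category %in% PROTEIN_CATEGORIES)
  intr <- annotation_introns(annotation)
  inter <- intergenic_lengths(annotation, genome)
  dup_copies <- 0L
  internal_dup_bp <- 0L
  if (!is.null(duplications) && nrow(duplications) > 0L) {
    internal_dup_bp <- sum(duplications$length)
    # genes fully inside the second copy of a region count as duplicates
    for (i in seq_len(nrow(duplications))) {
      dup_copies <- dup_copies + sum(
        gt$chromosome_id == duplications$chrom_b[i] &
          gt$start >= duplications$start_b[i] &
          gt$end <= duplications$end_b[i] &
          gt$category %in% PROTEIN_CATEGORIES)
    }
  }
  subtel_bp <- 0L
  if (!is.null(subtelomere) && subtelomere$unit_length > 0L) {
    subtel_bp <- subtelomere$unit_length * nrow(subtelomere$occurrences)
  }
  structure(list(
    species = genome$species,
    genome_size = total_bp(genome),
    chromosome_sizes = chromosome_lengths(genome),
    gc_percent = round(gc_content(genome), 1L),
    n_genes = nrow(gt),
    n_protein_coding = n_protein,
    n_protein_coding_nonredundant = n_protein - dup_copies,
    n_rrna = sum(gt$category == "rRNA"),
    n_trna = sum(gt$category == "tRNA"),
    n_snrna = sum(gt$category == "snRNA"),
    n_introns = nrow(intr),
    introns_per_gene = if (n_protein > 0L)
      round(nrow(intr) / n_protein, 1L) else 0,
    gene_density = round(gene_density(annotation, genome), 2L),
    mean_intergenic = round(inter$mean, 1L),
    n_intergenic = inter$n,
    internal_duplicated_bp = internal_dup_bp,
    subtelomeric_duplicated_bp = subtel_bp), class = "nm_summary")
}

#' @export
print.nm_summary <- function(x, ...) {
  cat(sprintf("<nm_summary> %s\n", x$species))
  for (nm in setdiff(names(x), c("species", "chromosome_sizes"))) {
    cat(sprintf("  %-32s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.nm_summary <- function(x, ...) {
  flat <- x
  flat$chromosome_sizes <- paste(x$chromosome_sizes, collapse = "/")
  as.data.frame(flat[!vapply(flat, is.null, logical(1L))],
                stringsAsFactors = FALSE)
}
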