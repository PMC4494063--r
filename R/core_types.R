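# Domain containers. A genome is a named set of chromosome sequences; an
# annotation set is a gene table with exon structures. All internal
# coordinates are 0-based half-open on the forward strand; GFF3 files are
# read and written 1-based closed (see io.R).

PROTEIN_CATEGORIES <- c("function-predicted", "ORFan")
RNA_CATEGORIES <- c("rRNA", "tRNA", "snRNA")
GENE_CATEGORIES <- c(PROTEIN_CATEGORIES, RNA_CATEGORIES, "pseudogene-fragment")

#' Construct a genome object
#'
#' @param species species label.
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N, lowercase accepted and normalized). Names are chromosome ids
#'   and must be unique.
#' @return an object of class `nm_genome` with elements `species` and
#'   `chromosomes` (named character vector).
#' @export
nm_genome <- function(species, sequences) {
  if (length(sequences) < 1L) stop("no sequences")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every chromosome needs an id (sequence name)")
  }
  if (anyDuplicated(ids)) stop("duplicate chromosome id")
  sequences <- toupper(sequences)
  for (i in seq_along(sequences)) {
    bad <- regexpr("[^ACGTN]", sequences[[i]])
    if (bad > 0L) {
      stop(sprintf("illegal character in record '%s' at offset %d",
                   ids[i], as.integer(bad)))
    }
  }
  structure(list(species = species, chromosomes = sequences),
            class = "nm_genome")
}

#' @export
print.nm_genome <- function(x, ...) {
  cat(sprintf("<nm_genome> %s: %d chromosome(s), %s bp total\n",
              x$species, length(x$chromosomes),
              format(total_bp(x), big.mark = ",")))
  for (id in names(x$chromosomes)) {
    cat(sprintf("  %s  %s bp\n", id,
                format(nchar(x$chromosomes[[id]]), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome an `nm_genome`.
#' @return named integer vector of lengths in bp.
#' @export
chromosome_lengths <- function(genome) {
  vapply(genome$chromosomes, nchar, integer(1L))
}

#' Total genome size in bp
#' @param genome an `nm_genome`.
#' @return integer total.
#' @export
total_bp <- function(genome) {
  sum(chromosome_lengths(genome))
}

#' Construct a gene model
#'
#' Exons are given as a 2-column matrix of `[start, end)` intervals in
#' 0-based half-open chromosome-forward coordinates, sorted ascending and
#' non-overlapping.
#'
#' @param id gene identifier (unique within an annotation set).
#' @param chromosome_id chromosome the gene lies on.
#' @param strand "+" or "-".
#' @param exons 2-column numeric matrix (start, end), 0-based half-open.
#' @param category one of function-predicted, ORFan, rRNA, tRNA, snRNA,
#'   pseudogene-fragment.
#' @param product product description.
#' @param family_id optional homolog family label.
#' @return a list of class `nm_gene`.
#' @export
gene_model <- function(id, chromosome_id, strand, exons,
                       category = "ORFan", product = "hypothetical protein",
                       family_id = NA_character_) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene model needs at least one exon")
  if (any(exons[, 2L] <= exons[, 1L])) stop("exon with non-positive length")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L) {
    stop("exons must be sorted ascending by start")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("exons overlap")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!category %in% GENE_CATEGORIES) {
    stop(sprintf("unknown gene category '%s'", category))
  }
  structure(list(id = id, chromosome_id = chromosome_id, strand = strand,
                 exons = exons, category = category, product = product,
                 family_id = family_id),
            class = "nm_gene")
}

#' Construct an annotation set
#'
#' @param species species label matching the genome the annotation refers to.
#' @param genes list of `nm_gene` objects with unique ids.
#' @return an object of class `nm_annotation`.
#' @export
nm_annotation <- function(species, genes = list()) {
  ids <- vapply(genes, function(g) g$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate gene id")
  names(genes) <- ids
  structure(list(species = species, genes = genes), class = "nm_annotation")
}

#' @export
print.nm_annotation <- function(x, ...) {
  cats <- table(factor(vapply(x$genes, function(g) g$category, character(1L)),
                       levels = GENE_CATEGORIES))
  cat(sprintf("<nm_annotation> %s: %d gene(s)\n", x$species, length(x$genes)))
  for (nm in names(cats)) if (cats[[nm]] > 0L) {
    cat(sprintf("  %-20s %d\n", nm, cats[[nm]]))
  }
  invisible(x)
}

is_protein_coding <- function(gene) gene$category %in% PROTEIN_CATEGORIES

#' Gene table of an annotation set
#'
#' @param annotation an `nm_annotation`.
#' @return data.frame with one row per gene (id, chromosome_id, strand,
#'   start, end, n_exons, category, product, family_id), sorted by
#'   chromosome then start.
#' @export
gene_table <- function(annotation) {
  g <- annotation$genes
  if (length(g) == 0L) {
    return(data.frame(id = character(), chromosome_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_exons = integer(),
                      category = character(), product = character(),
                      family_id = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    id = vapply(g, `[[`, character(1L), "id"),
    chromosome_id = vapply(g, `[[`, character(1L), "chromosome_id"),
    strand = vapply(g, `[[`, character(1L), "strand"),
    start = vapply(g, function(x) x$exons[1L, 1L], integer(1L)),
    end = vapply(g, function(x) x$exons[nrow(x$exons), 2L], integer(1L)),
    n_exons = vapply(g, function(x) nrow(x$exons), integer(1L)),
    category = vapply(g, `[[`, character(1L), "category"),
    product = vapply(g, `[[`, character(1L), "product"),
    family_id = vapply(g, `[[`, character(1L), "family_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$chromosome_id, df$start), , drop = FALSE]
}

#' Introns of a single gene model
#'
#' Exon gaps of one gene as forward-strand `[donor, acceptor)` intervals
#' with transcript-orientation phase; rows appear in transcript order. With
#' a genome supplied, the 4-letter boundary string (first two + last two
#' intron nt, transcript orientation) is extracted from sequence.
#'
#' @param gene an `nm_gene`.
#' @param genome optional `nm_genome` for boundary extraction.
#' @return data.frame with columns gene_id, chromosome_id, strand, donor,
#'   acceptor, length, phase, boundary.
#' @export
gene_introns <- function(gene, genome = NULL) {
  ex <- gene$exons
  k <- nrow(ex) - 1L
  if (k < 1L) {
    return(data.frame(gene_id = character(), chromosome_id = character(),
                      strand = character(), donor = integer(),
                      acceptor = integer(), length = integer(),
                      phase = integer(), boundary = character(),
                      stringsAsFactors = FALSE))
  }
  donor <- ex[-nrow(ex), 2L]
  acceptor <- ex[-1L, 1L]
  exlen <- ex[, 2L] - ex[, 1L]
  # spliced nt upstream of each gap, in transcript orientation
  if (gene$strand == "+") {
    before <- cumsum(exlen)[-nrow(ex)]
  } else {
    before <- rev(cumsum(rev(exlen)))[-1L]
  }
  boundary <- rep(NA_character_, k)
  if (!is.null(genome)) {
    chrom <- genome$chromosomes[[gene$chromosome_id]]
    for (i in seq_len(k)) {
      s <- substr(chrom, donor[i] + 1L, acceptor[i])
      if (gene$strand == "-") s <- revcomp(s)
      boundary[i] <- paste0(substr(s, 1L, 2L),
                            substr(s, nchar(s) - 1L, nchar(s)))
    }
  }
  df <- data.frame(gene_id = gene$id, chromosome_id = gene$chromosome_id,
                   strand = gene$strand, donor = donor, acceptor = acceptor,
                   length = acceptor - donor, phase = before %% 3L,
                   boundary = boundary, stringsAsFactors = FALSE,
                   row.names = NULL)
  if (gene$strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Introns of an annotation set
#'
#' Introns are derived from exon gaps of multi-exon genes. Phase is the
#' number of spliced coding nucleotides upstream of the splice, modulo 3, in
#' transcript orientation; the boundary string is the first two plus last two
#' intron nucleotides in transcript orientation (e.g. "GTAG").
#'
#' @param annotation an `nm_annotation`.
#' @param genome optional `nm_genome`; if supplied, boundary strings are
#'   extracted from sequence, otherwise they are NA.
#' @param categories gene categories to include (default protein-coding).
#' @return data.frame with columns gene_id, chromosome_id, strand, donor,
#'   acceptor, length, phase, boundary. Introns of a gene appear in
#'   transcript order.
#' @export
annotation_introns <- function(annotation, genome = NULL,
                               categories = PROTEIN_CATEGORIES) {
  keep <- Filter(function(g) g$category %in% categories, annotation$genes)
  out <- lapply(keep, gene_introns, genome = genome)
  out <- out[vapply(out, nrow, integer(1L)) > 0L]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), chromosome_id = character(),
                      strand = character(), donor = integer(),
                      acceptor = integer(), length = integer(),
                      phase = integer(), boundary = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
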