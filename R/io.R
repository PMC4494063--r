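# File I/O. FASTA through Biostrings, GFF3 through rtracklayer, homology
# tables as BLAST-tabular TSV. GFF3 files use 1-based closed coordinates;
# everything in memory is 0-based half-open.

#' Load a genome from a multi-record FASTA file
#'
#' One chromosome per record, record order preserved, lowercase normalized to
#' uppercase. Only A/C/G/T/N are accepted; any other letter raises an error
#' naming the record and offset.
#'
#' @param path FASTA file.
#' @param species species label (default: file name without extension).
#' @return an `nm_genome`.
#' @export
load_genome <- function(path, species = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  if (is.null(species)) {
    species <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  }
  nm_genome(species, seqs)
}

#' Write a genome to FASTA
#'
#' @param genome an `nm_genome`.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write an annotation set to GFF3
#'
#' Genes are written as `gene` features with `exon` children; attributes ID,
#' Parent, product and category are used. Coordinates are converted to
#' 1-based closed.
#'
#' @param annotation an `nm_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  rows <- list()
  for (g in annotation$genes) {
    span <- c(g$exons[1L, 1L], g$exons[nrow(g$exons), 2L])
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chromosome_id, type = "gene",
      start = span[1L] + 1L, end = span[2L], strand = g$strand,
      ID = g$id, Parent = NA_character_, product = g$product,
      category = g$category, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(g$exons))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = g$chromosome_id, type = "exon",
        start = g$exons[i, 1L] + 1L, end = g$exons[i, 2L],
        strand = g$strand, ID = sprintf("%s.exon%d", g$id, i),
        Parent = g$id, product = NA_character_, category = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$product <- df$product
  S4Vectors::mcols(gr)$category <- df$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load an annotation set from GFF3
#'
#' Accepts a gene/exon or gene/mRNA/exon feature hierarchy. Coordinates are
#' converted to 0-based half-open and a validation pass is run; the report is
#' attached as attribute `"validation"`.
#'
#' @param path GFF3 file.
#' @param genome the `nm_genome` the annotation refers to.
#' @return an `nm_annotation`.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(mc)) {
    pl <- mc$Parent
    parents <- vapply(seq_along(gr), function(i) {
      p <- pl[[i]]
      if (length(p) == 0L || identical(p, "")) NA_character_ else as.character(p[1L])
    }, character(1L))
  }
  parents[!is.na(parents) & parents == ""] <- NA_character_

  is_gene <- type == "gene"
  gene_idx <- which(is_gene)
  if (length(gene_idx) == 0L) stop("GFF3 contains no gene features")
  id_of <- ids
  # resolve each feature to its ancestral gene (gene/exon or gene/mRNA/exon)
  parent_gene <- function(i) {
    p <- parents[i]
    for (step in 1:3) {
      if (is.na(p)) return(NA_character_)
      j <- match(p, id_of)
      if (is.na(j)) return(p)  # dangling parent id; let caller decide
      if (is_gene[j]) return(id_of[j])
      p <- parents[j]
    }
    NA_character_
  }

  chrom_len <- chromosome_lengths(genome)
  genes <- list()
  exon_sets <- list()
  for (i in gene_idx) {
    gid <- ids[i]
    if (is.na(gid)) gid <- sprintf("gene_%d", i)
    exon_sets[[gid]] <- NULL
    genes[[gid]] <- list(
      idx = i,
      chromosome_id = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      start = GenomicRanges::start(gr)[i] - 1L,
      end = GenomicRanges::end(gr)[i],
      product = if ("product" %in% names(mc) && !is.na(mc$product[i]))
        as.character(mc$product[i]) else "hypothetical protein",
      category = if ("category" %in% names(mc) && !is.na(mc$category[i]))
        as.character(mc$category[i]) else "ORFan")
  }
  for (i in which(type == "exon")) {
    gid <- parent_gene(i)
    if (is.na(gid) || is.null(genes[[gid]])) next
    exon_sets[[gid]] <- rbind(exon_sets[[gid]],
                              c(GenomicRanges::start(gr)[i] - 1L,
                                GenomicRanges::end(gr)[i]))
  }

  models <- list()
  for (gid in names(genes)) {
    info <- genes[[gid]]
    if (!info$chromosome_id %in% names(chrom_len)) {
      stop(sprintf("gene '%s' refers to unknown chromosome '%s'",
                   gid, info$chromosome_id))
    }
    ex <- exon_sets[[gid]]
    if (is.null(ex)) ex <- matrix(c(info$start, info$end), ncol = 2L)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] < 0L) || any(ex[, 2L] > chrom_len[[info$chromosome_id]])) {
      stop(sprintf("exon of gene '%s' outside chromosome '%s' bounds",
                   gid, info$chromosome_id))
    }
    strand <- if (info$strand %in% c("+", "-")) info$strand else "+"
    models[[gid]] <- gene_model(gid, info$chromosome_id, strand, ex,
                                category = info$category,
                                product = info$product)
  }
  ann <- nm_annotation(genome$species, unname(models))
  attr(ann, "validation") <- validate_annotation(genome, ann)
  ann
}

#' Read a pairwise homology table (BLAST-tabular dialect)
#'
#' Accepts either the 6-column dialect `query, subject, pident, aln_len,
#' bitscore, evalue` or full 12-column BLAST `-outfmt 6`.
#'
#' @param path TSV file without header.
#' @return data.frame with columns query_id, subject_id, pident, aln_len,
#'   score, evalue.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 12L) {
    out <- data.frame(query_id = df[[1L]], subject_id = df[[2L]],
                      pident = as.numeric(df[[3L]]),
                      aln_len = as.integer(df[[4L]]),
                      score = as.numeric(df[[12L]]),
                      evalue = as.numeric(df[[11L]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) >= 6L) {
    out <- data.frame(query_id = df[[1L]], subject_id = df[[2L]],
                      pident = as.numeric(df[[3L]]),
                      aln_len = as.integer(df[[4L]]),
                      score = as.numeric(df[[5L]]),
                      evalue = as.numeric(df[[6L]]),
                      stringsAsFactors = FALSE)
  } else {
    stop("homology table needs at least 6 tab-separated columns")
  }
  if (any(out$evalue < 0)) stop("negative e-value in homology table")
  out
}

#' Write a pairwise homology table
#'
#' @param hits data.frame as returned by [read_hits_tsv()] or
#'   [search_homologs()].
#' @param path output TSV (6-column dialect, no header).
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(hits$query_id, hits$subject_id,
                   if ("pident" %in% names(hits)) hits$pident else NA,
                   if ("aln_len" %in% names(hits)) hits$aln_len else NA,
                   hits$score, hits$evalue)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
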