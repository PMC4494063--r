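# Annotation validation: structural checks that report violations rather
# than raising, so a whole annotation set can be audited in one pass.

# spliced, strand-corrected coding sequence of a gene (includes stop codon)
spliced_cds <- function(gene, genome) {
  chrom <- genome$chromosomes[[gene$chromosome_id]]
  if (is.null(chrom)) {
    stop(sprintf("gene '%s' refers to unknown chromosome '%s'",
                 gene$id, gene$chromosome_id))
  }
  parts <- substring(chrom, gene$exons[, 1L] + 1L, gene$exons[, 2L])
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Validate an annotation set against its genome
#'
#' Checks, per gene: exon bounds; for protein-coding categories, spliced
#' length divisible by 3, absence of internal stop codons, presence of a
#' terminal stop; intron lengths within `intron_bounds` (unless listed in the
#' gene's `oversized_ok` field) and GT..AG boundaries; overlap with N bases.
#' Violations are reported, never raised.
#'
#' @param genome an `nm_genome`.
#' @param annotation an `nm_annotation` for the same genome.
#' @param intron_bounds accepted intron length range (default 18-23 nt).
#' @return an object of class `nm_validation`: a data.frame with columns
#'   `gene_id`, `check`, `message`; zero rows iff everything passes.
#' @export
validate_annotation <- function(genome, annotation, intron_bounds = c(18L, 23L)) {
  chrom_len <- chromosome_lengths(genome)
  rows <- list()
  note <- function(gene_id, check, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, check = check, message = message,
      stringsAsFactors = FALSE)
  }
  for (g in annotation$genes) {
    if (!g$chromosome_id %in% names(chrom_len)) {
      note(g$id, "bounds", sprintf("unknown chromosome '%s'", g$chromosome_id))
      next
    }
    n <- chrom_len[[g$chromosome_id]]
    if (any(g$exons[, 1L] < 0L) || any(g$exons[, 2L] > n)) {
      note(g$id, "bounds", "exon outside chromosome bounds")
      next
    }
    cds <- spliced_cds(g, genome)
    if (grepl("N", cds, fixed = TRUE)) {
      note(g$id, "n_bases", "gene model overlaps N bases")
    }
    if (is_protein_coding(g)) {
      if (nchar(cds) %% 3L != 0L) {
        note(g$id, "divisibility", sprintf(
          "spliced length %d not divisible by 3", nchar(cds)))
      } else if (!grepl("N", cds, fixed = TRUE)) {
        codons <- substring(cds, seq(1L, nchar(cds), 3L),
                            seq(3L, nchar(cds), 3L))
        stops <- which(codons %in% STOP_CODONS)
        if (length(stops) > 0L && any(stops < length(codons))) {
          note(g$id, "internal_stop", sprintf(
            "internal stop codon at codon %d", stops[stops < length(codons)][1L]))
        }
        if (!codons[length(codons)] %in% STOP_CODONS) {
          note(g$id, "terminal_stop", "spliced CDS does not end in a stop codon")
        }
      }
      intr <- gene_introns(g, genome)
      ok_oversized <- g$oversized_ok
      if (is.null(ok_oversized)) ok_oversized <- integer()
      for (i in seq_len(nrow(intr))) {
        len <- intr$length[i]
        if ((len < intron_bounds[1L] || len > intron_bounds[2L]) &&
            !(i %in% ok_oversized)) {
          note(g$id, "intron_length", sprintf(
            "intron %d has length %d outside [%d, %d]",
            i, len, intron_bounds[1L], intron_bounds[2L]))
        }
        if (!is.na(intr$boundary[i]) && intr$boundary[i] != "GTAG") {
          note(g$id, "intron_boundary", sprintf(
            "intron %d has boundary %s, expected GTAG", i, intr$boundary[i]))
        }
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(gene_id = character(), check = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("nm_validation", "data.frame")
  out
}

#' @export
print.nm_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<nm_validation> clean (no violations)\n")
  } else {
    cat(sprintf("<nm_validation> %d violation(s)\n", nrow(x)))
    print.data.frame(x, ...)
  }
  invisible(x)
}
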