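# Protein homology: local alignment (BLOSUM62, affine gaps), Karlin-Altschul
# e-values, a seeded all-vs-all search, and single-linkage family
# construction at an e-value cutoff.

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment under an affine gap model (BLAST-style
#' costs: a gap of length L costs `gap_open + L * gap_extend`).
#'
#' @param protein_a,protein_b non-empty protein strings.
#' @param matrix substitution matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @return list with elements score, aligned_a, aligned_b, start_a, end_a,
#'   start_b, end_b (1-based alignment footprint), pident.
#' @export
align_local <- function(protein_a, protein_b, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L) {
    stop("empty protein sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  list(score = as.numeric(Biostrings::score(aln)),
       aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       start_a = Biostrings::start(pat), end_a = Biostrings::end(pat),
       start_b = Biostrings::start(sub), end_b = Biostrings::end(sub),
       pident = Biostrings::pid(aln))
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with sequence lengths m, n and raw
#' score S. Default parameters approximate gapped BLOSUM62 with 11/1 gap
#' costs.
#'
#' @param score raw alignment score.
#' @param len_a,len_b sequence lengths.
#' @param K,lambda Karlin-Altschul parameters (defaults 0.041 and 0.267).
#' @return the expectation value.
#' @export
estimate_evalue <- function(score, len_a, len_b, K = 0.041, lambda = 0.267) {
  stopifnot(K > 0, lambda > 0)
  K * len_a * len_b * exp(-lambda * score)
}

# unique k-mers of a protein string
protein_kmers <- function(p, k) {
  n <- nchar(p)
  if (n < k) return(character(0))
  unique(substring(p, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' All-vs-all protein homology search
#'
#' Two-stage search in the BLAST mould: candidate pairs are seeded by shared
#' amino-acid k-mers, then scored by optimal local alignment with a
#' Karlin-Altschul e-value. The seed requirement doubles as a guard against
#' spurious low-complexity matches between composition-biased (AT-rich)
#' proteomes, for which the plain Karlin-Altschul e-value is optimistic.
#'
#' @param proteins_a,proteins_b named character vectors of protein sequences.
#' @param seed_k seed k-mer length (default 5).
#' @param min_seeds minimum number of shared k-mers to trigger an alignment
#'   (default 12; genuine homologs at up to ~40% divergence share hundreds).
#' @param max_evalue report hits with e-value at or below this (default 1).
#' @param K,lambda Karlin-Altschul parameters.
#' @return data.frame with columns query_id, subject_id, pident, aln_len,
#'   score, evalue (directional hits, a-vs-b).
#' @export
search_homologs <- function(proteins_a, proteins_b, seed_k = 5L,
                            min_seeds = 12L, max_evalue = 1,
                            K = 0.041, lambda = 0.267) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), aln_len = integer(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) return(empty)
  # k-mer index over subjects
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seq_along(proteins_b)) {
    for (km in protein_kmers(proteins_b[[j]], seed_k)) {
      idx[[km]] <- c(idx[[km]], j)
    }
  }
  rows <- list()
  for (i in seq_along(proteins_a)) {
    counts <- integer(length(proteins_b))
    for (km in protein_kmers(proteins_a[[i]], seed_k)) {
      js <- idx[[km]]
      if (!is.null(js)) counts[js] <- counts[js] + 1L
    }
    for (j in which(counts >= min_seeds)) {
      aln <- align_local(proteins_a[[i]], proteins_b[[j]])
      ev <- estimate_evalue(aln$score, nchar(proteins_a[[i]]),
                            nchar(proteins_b[[j]]), K = K, lambda = lambda)
      if (ev <= max_evalue) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(proteins_a)[i], subject_id = names(proteins_b)[j],
          pident = aln$pident,
          aln_len = nchar(aln$aligned_a),
          score = aln$score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build homolog families by single linkage
#'
#' Connected components over pairwise hits with `evalue < evalue_cutoff`.
#' Genes listed in `all_genes` but absent from any qualifying edge become
#' singleton families.
#'
#' @param hits data.frame with columns query_id, subject_id, evalue.
#' @param evalue_cutoff e-value cutoff (default 0.001, strict less-than).
#' @param all_genes optional character vector of every gene id to place.
#' @return data.frame with columns family_id and gene_id; family ids are
#'   assigned deterministically by the lexicographically smallest member.
#' @export
build_families <- function(hits, evalue_cutoff = 0.001, all_genes = NULL) {
  edges <- hits[hits$evalue < evalue_cutoff &
                  hits$query_id != hits$subject_id, , drop = FALSE]
  verts <- sort(unique(c(edges$query_id, edges$subject_id, all_genes)))
  if (length(verts) == 0L) {
    return(data.frame(family_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$query_id, to = edges$subject_id),
    directed = FALSE, vertices = verts)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  # deterministic family order: by smallest member id
  member <- member[order(vapply(member, min, character(1L)))]
  fam_ids <- sprintf("fam%04d", seq_along(member))
  data.frame(
    family_id = rep(fam_ids, lengths(member)),
    gene_id = unlist(lapply(member, sort), use.names = FALSE),
    stringsAsFactors = FALSE)
}

# family label lookup: named vector gene_id -> family_id
family_lookup <- function(families) {
  stats::setNames(families$family_id, families$gene_id)
}

#' Assign family labels to an annotation set
#'
#' @param annotation an `nm_annotation`.
#' @param families data.frame from [build_families()].
#' @return the annotation with `family_id` filled in on each gene.
#' @export
assign_families <- function(annotation, families) {
  look <- family_lookup(families)
  for (i in seq_along(annotation$genes)) {
    id <- annotation$genes[[i]]$id
    if (id %in% names(look)) {
      annotation$genes[[i]]$family_id <- look[[id]]
    }
  }
  annotation
}

#' Screen for genes transferred out of a genome
#'
#' Searches proteins missing from one genome against a user-supplied target
#' protein set (e.g. nuclear proteome or transcriptome translations); an
#' empty table means no evidence of transfer.
#'
#' @param missing_proteins named character vector of query proteins.
#' @param target_proteins named character vector of target proteins.
#' @param evalue_cutoff e-value cutoff (default 1e-5, strict less-than).
#' @return hit table as in [search_homologs()], restricted to the cutoff.
#' @export
screen_missing_genes <- function(missing_proteins, target_proteins,
                                 evalue_cutoff = 1e-5) {
  hits <- search_homologs(missing_proteins, target_proteins,
                          max_evalue = Inf)
  hits[hits$evalue < evalue_cutoff, , drop = FALSE]
}
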