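# Low-level sequence helpers shared by all stages. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; character vectors (one element
# per base) are used inside the scanning algorithms.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x a character scalar over A/C/G/T/N.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# revcomp on a per-base character vector (fast path inside scanners)
revcomp_chars <- function(v) {
  if (length(v) == 0L) return(v)
  unname(rev(COMPLEMENT[v]))
}

seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> amino acid, standard code (Biostrings table; '*' for stops)
codon_table <- function(code = "standard") {
  if (!identical(code, "standard")) {
    stop("only the standard genetic code table is provided")
  }
  Biostrings::GENETIC_CODE
}

#' Translate a coding DNA string
#'
#' Translates an in-frame coding sequence (length divisible by 3) with the
#' standard genetic code. A terminal stop codon, if present, is removed.
#' Internal stop codons raise an error naming the codon index.
#'
#' @param cds coding sequence (character scalar, length divisible by 3).
#' @param genetic_code genetic code identifier (only "standard").
#' @return protein string (one-letter amino acids, no terminal stop).
#' @export
translate_cds <- function(cds, genetic_code = "standard") {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3")
  if (n == 0L) return("")
  tab <- codon_table(genetic_code)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(tab[codons])
  if (anyNA(aa)) stop("coding sequence contains a non-ACGT codon")
  n_cod <- length(aa)
  if (aa[n_cod] == "*") aa <- aa[-n_cod]
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    stop(sprintf("internal stop codon at codon index %d", internal[1L]))
  }
  paste(aa, collapse = "")
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample a random DNA string at a target GC fraction (A=T, G=C)
random_dna <- function(n, gc = 0.28, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p <- p[alphabet]
  p <- p / sum(p)
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}
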