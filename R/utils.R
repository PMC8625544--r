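# Small shared helpers.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   readDNAStringSet writeXStringSet
NULL

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Trailing bases that do not complete a codon are ignored. Stop codons are
#' rendered as `*`.
#'
#' @param seq A DNA string (character scalar).
#' @return The amino-acid string (one-letter codes, `*` for stop).
#' @keywords internal
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n == 0L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n)),
    no.init.codon = TRUE
  )))
}

AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", "*" = "*", X = "Xaa"
)

aa_three <- function(aa1) {
  out <- AA3[strsplit(aa1, "")[[1]]]
  out[is.na(out)] <- "Xaa"
  paste0(out, collapse = "")
}

#' Round half away from zero
#'
#' Display rounding used in frequency tables (0.015 -> 0.02), unlike base
#' `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
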