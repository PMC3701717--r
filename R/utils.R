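#' @importFrom stats rnorm rpois rlnorm runif phyper ks.test setNames
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# ASCII -> base index lookup (A=1, C=2, G=3, T=4, N/other=5)
.base_code <- local({
  m <- rep(5L, 128L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

#' Encode a DNA string as base indices
#'
#' A, C, G, T map to 1..4; any other letter (N, IUPAC ambiguity) maps to 5.
#' @param x a single DNA string.
#' @return integer vector of codes, one per base.
#' @keywords internal
dna_codes <- function(x) {
  .base_code[utf8ToInt(x)]
}

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (character scalar).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random background DNA
#'
#' i.i.d. base model parameterized only by its GC fraction. Uses the
#' current RNG stream.
#'
#' @param n sequence length.
#' @param gc GC fraction in \[0,1\].
#' @return a character scalar of length-n DNA.
#' @export
random_dna <- function(n, gc = 0.41) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Derive a per-stage RNG seed from a master seed by a fixed integer offset,
# kept below 2^31.
derive_seed <- function(master, offset) {
  (as.integer(master) %% 1000000000L) + as.integer(offset)
}

# Substitute each position independently with probability p, uniformly to a
# different base. Operates on a code vector or a string.
mutate_bases <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
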