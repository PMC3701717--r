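#' The 25-nt Alu-DEIN core motif
#'
#' The validated core motif of the Alu-DEIN repeat class found depleted in
#' promoters of trans-regulated genes.
#' @return character scalar, 25 nt.
#' @export
alu_core <- function() "CACGCCTGTAATCCCAGCACTTTGG"

#' A 48-bp Alu motif containing the core
#'
#' Synthetic stand-in for the 48-bp Alu element used in motif-mutagenesis
#' experiments: the 25-nt core embedded in Alu-family consensus context
#' (core at 0-based offset 17). The exact 48-mer of the original
#' experiments is not public; this one is constructed to be
#' consensus-faithful to the Alu family.
#' @return character scalar, 48 nt.
#' @export
alu_motif_48 <- function() "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCC"

#' Bundled synthetic Alu-DEIN motif instances
#'
#' Thirty synthetic 25-nt instances of the core motif (0-2 substitutions
#' each, consensus equal to [alu_core()]); a stand-in for the instance set
#' a de-novo motif finder would report.
#' @return character vector of 25-nt DNA strings.
#' @export
alu_dein_instances <- function() {
  path <- system.file("extdata", "synthetic_alu_dein_instances.fa",
                      package = "aluscan", mustWork = TRUE)
  as.character(Biostrings::readDNAStringSet(path))
}

#' Default Alu-DEIN position weight matrix
#'
#' PWM built from the bundled synthetic instance set ([alu_dein_instances()]).
#' Its consensus equals the 25-nt core motif.
#' @param pseudocount per-cell pseudocount (default 0.1).
#' @param background length-4 background probabilities (default uniform).
#' @return a `pwm` object.
#' @export
default_alu_pwm <- function(pseudocount = 0.1, background = rep(0.25, 4)) {
  build_pwm(alu_dein_instances(), pseudocount = pseudocount,
            background = background)
}
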