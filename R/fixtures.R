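#' Packaged synthetic stand-in sequences
#'
#' The package ships two SYNTHETIC sequences emulating the statistical
#' structure of the studied wheat storage proteins (they are constructed
#' stand-ins, not the database accessions): an alpha-gliadin-like sequence
#' (268 residues = 20-residue signal peptide + 248 mature, six cysteines in
#' hydrophobic context, 7+/6- charges, net +1, accumulated window-15
#' Kyte-Doolittle index -0.98) and an LMW-glutenin-subunit-like sequence
#' (288 = 23 + 265, eight cysteines of which the intermolecular pair at
#' mature positions 2 and 210 sits in hydrophilic context, 9+/2- charges,
#' net +7, index -0.71). Construction: `data-raw/make_fixtures.R`.
#'
#' Experimentally characterised intramolecular disulfide pairs are
#' annotated in mature 1-based numbering: (108,138), (139,229), (151,237)
#' for the gliadin-like chain and (127,162), (135,155), (163,260) for the
#' glutenin-like chain.
#'
#' @param which `"alpha_gliadin"` or `"lmw_glutenin"`.
#' @return A list with components `full` (the untrimmed
#'   [protein_sequence()]), `mature` (signal peptide removed),
#'   `signal_peptide_length`, `restraint_pairs` (list of mature cysteine
#'   index pairs forming intramolecular disulfides), and
#'   `intermolecular_cys` (mature positions of cysteines that crosslink
#'   between molecules; empty for the gliadin).
#' @examples
#' fx <- gluten_fixture("alpha_gliadin")
#' length(fx$mature)  # 248
#' @export
gluten_fixture <- function(which = c("alpha_gliadin", "lmw_glutenin")) {
  which <- match.arg(which)
  info <- switch(which,
    alpha_gliadin = list(
      file = "synthetic_alpha_gliadin.fasta",
      signal = 20L,
      pairs = list(c(108L, 138L), c(139L, 229L), c(151L, 237L)),
      inter = integer(0)),
    lmw_glutenin = list(
      file = "synthetic_lmw_glutenin.fasta",
      signal = 23L,
      pairs = list(c(127L, 162L), c(135L, 155L), c(163L, 260L)),
      inter = c(2L, 210L)))
  path <- system.file("extdata", info$file, package = "glutensim",
                      mustWork = TRUE)
  full <- read_fasta(path)[[1]]
  full$signal_peptide_length <- info$signal
  list(full = full,
       mature = trim_signal_peptide(full, info$signal),
       signal_peptide_length = info$signal,
       restraint_pairs = info$pairs,
       intermolecular_cys = info$inter)
}
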