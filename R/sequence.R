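#' Protein sequence objects
#'
#' A `protein_sequence` is a validated string of one-letter amino-acid codes
#' with an identifier, an optional annotation of how many N-terminal residues
#' form a signal (transport) peptide, and the 1-based positions of its
#' cysteines (always recomputed, never stored stale).
#'
#' @param residues Character scalar or vector of one-letter codes. Lowercase
#'   is accepted and uppercased; `*` stop symbols are stripped with a warning.
#' @param id Sequence identifier.
#' @param signal_peptide_length Number of N-terminal residues annotated as a
#'   signal peptide (not yet removed; see [trim_signal_peptide()]).
#' @return An object of class `protein_sequence` with fields `id`, `residues`
#'   (character vector, one element per residue), `signal_peptide_length`,
#'   and `cys_positions`.
#' @examples
#' s <- protein_sequence("MKTLLILAVLCIA", id = "toy")
#' s$cys_positions
#' @export
protein_sequence <- function(residues, id = "seq",
                             signal_peptide_length = 0L) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- as.character(residues)
  if (any(residues == "*")) {
    warning("stripping ", sum(residues == "*"), " stop symbol(s) '*' from ",
            id)
    residues <- residues[residues != "*"]
  }
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AA_CODES)
  if (length(bad) > 0L) {
    stop("record '", id, "' contains non-amino-acid symbol(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(residues) == 0L) stop("empty sequence for record '", id, "'")
  signal_peptide_length <- as.integer(signal_peptide_length)
  if (signal_peptide_length < 0L || signal_peptide_length >= length(residues)) {
    stop("signal_peptide_length must be in [0, length - 1]")
  }
  structure(list(
    id = id,
    residues = residues,
    signal_peptide_length = signal_peptide_length,
    cys_positions = which(residues == "C")
  ), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("Protein sequence '", x$id, "': ", length(x$residues), " residues, ",
      length(x$cys_positions), " Cys", sep = "")
  if (x$signal_peptide_length > 0L) {
    cat(" (signal peptide: ", x$signal_peptide_length, " residues)", sep = "")
  }
  cat("\n")
  s <- paste(x$residues, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @export
as.character.protein_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' Read protein sequences from a FASTA file
#'
#' Parses through `Biostrings::readBStringSet()` and validates every record
#' against the 20 standard one-letter codes. The header token before the
#' first whitespace becomes the id; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  lapply(seq_along(set), function(i) {
    protein_sequence(as.character(set[[i]]), id = ids[i])
  })
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A `protein_sequence` or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, as.character, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Remove an N-terminal signal peptide
#'
#' Wheat storage proteins carry an N-terminal transport peptide (20 residues
#' for the alpha-gliadin studied here, 23 for the LMW glutenin subunit) that
#' is cleaved during synthesis; simulations and profiles use the mature
#' sequence. Cysteine positions are re-indexed to the mature sequence.
#'
#' @param seq A [protein_sequence()].
#' @param n Number of N-terminal residues to remove. Defaults to the
#'   sequence's `signal_peptide_length` annotation.
#' @return A mature `protein_sequence` of length `length(seq) - n`.
#' @export
trim_signal_peptide <- function(seq, n = seq$signal_peptide_length) {
  stopifnot(inherits(seq, "protein_sequence"))
  n <- as.integer(n)
  if (n < 0L || n >= length(seq$residues)) {
    stop("signal peptide length n must satisfy 0 <= n < sequence length (",
         length(seq$residues), "), got ", n)
  }
  if (n == 0L) return(seq)
  protein_sequence(seq$residues[-seq_len(n)], id = seq$id,
                   signal_peptide_length = 0L)
}
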