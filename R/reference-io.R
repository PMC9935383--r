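#' Read construct reference sequences from a FASTA file
#'
#' Sequences are returned as an uppercased [Biostrings::DNAStringSet] in file
#' order. The record identifier is the first whitespace-delimited token of the
#' FASTA header.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  refs <- Biostrings::readDNAStringSet(path)
  if (length(refs) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  names(refs) <- sub("\\s.*$", "", names(refs))
  dup <- unique(names(refs)[duplicated(names(refs))])
  if (length(dup) > 0L) {
    stop("duplicate reference id(s) in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  # uppercase so downstream comparisons are case-insensitive
  Biostrings::DNAStringSet(toupper(as.character(refs)))
}

#' Combine construct and decoy references into one reference set
#'
#' Builds the alignment reference as the union of the vector construct
#' sequences and decoy "host" sequences, constructs first. Each input sequence
#' remains its own record (its own chromosome to the aligner); sequences are
#' never joined end-to-end. Aligning against constructs plus a host decoy lets
#' background transcription be absorbed by the decoy instead of piling onto
#' the constructs.
#'
#' @param constructs [Biostrings::DNAStringSet] of construct sequences.
#' @param decoy [Biostrings::DNAStringSet] of decoy sequences (may be empty).
#' @param path Optional path; when given the combined set is written as a
#'   multi-record FASTA.
#' @return The combined [Biostrings::DNAStringSet].
#' @export
concatenate_references <- function(constructs, decoy = Biostrings::DNAStringSet(),
                                   path = NULL) {
  shared <- intersect(names(constructs), names(decoy))
  if (length(shared) > 0L) {
    stop("reference id(s) present in both constructs and decoy: ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  combined <- c(constructs, decoy)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(combined, filepath = path)
  }
  combined
}
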