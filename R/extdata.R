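#' Read a coding transcript from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return A [Biostrings::DNAString].
#' @export
readTranscript <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (!length(s)) stop("no sequence in ", path)
  s[[1]]
}

#' The POLE coding sequence bundled with the package
#'
#' A synthetic coding sequence of 2,286 codons plus stop, constructed from
#' sense codons with the residues quoted in the analyses (the 20 driver
#' residues and the variant positions discussed for Groups 3 and 4) fixed
#' to their reference amino acids.  It stands in for the RefSeq POLE coding
#' transcript so that coding-level operations run self-contained; channel
#' *availability* is realistic (every trinucleotide context occurs many
#' times) but position-specific context does not match the real gene.
#' Substitute a real transcript via [readTranscript()] for
#' position-faithful work.
#'
#' @return A [Biostrings::DNAString] of length 6,861.
#' @export
poleTranscript <- function() {
  readTranscript(system.file("extdata", "pole_cds_synthetic.fa",
                             package = "poleSig", mustWork = TRUE))
}
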