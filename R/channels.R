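## 96-channel single-base-substitution (SBS) machinery.
## A channel types a substitution by its pyrimidine-normalized reference
## base plus 5' and 3' flanks, written "T[C>A]T".

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## standard one-letter amino acids (stop handled separately as "*")
AA_STANDARD_1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The 96 trinucleotide substitution channels in COSMIC order
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank, then 3' flank, matching the row order of COSMIC signature
#' tables.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, `"T[T>G]T"`.
#' @examples
#' head(sbsChannels())
#' @export
sbsChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(.BASES, .BASES, function(f, t)
      paste0(f, "[", s, "]", t))))))
}

#' Compose a channel label from its parts
#'
#' @param five,ref,alt,three Single bases (vectorized).
#' @return Character vector of channel labels (not normalized; see
#'   [normalizeToPyrimidine()]).
#' @keywords internal
channelLabel <- function(five, ref, alt, three) {
  paste0(five, "[", ref, ">", alt, "]", three)
}

#' Split channel labels into their parts
#'
#' @param channel Character vector of labels such as `"T[C>A]T"`.
#' @return data.frame with columns `five`, `ref`, `alt`, `three`.
#' @keywords internal
splitChannel <- function(channel) {
  m <- regmatches(channel,
                  regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$",
                          channel))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed channel label: ",
         paste(channel[bad], collapse = ", "))
  out <- do.call(rbind, m)
  data.frame(five = out[, 2], ref = out[, 3], alt = out[, 4],
             three = out[, 5], stringsAsFactors = FALSE)
}

#' Normalize a stranded trinucleotide substitution to its pyrimidine channel
#'
#' SBS channels are reported with a pyrimidine (C or T) reference base.  A
#' substitution observed with a purine reference is mapped to the reverse
#' complement: flanks are swapped and complemented, and the reference and
#' alternate bases are complemented.  The operation is idempotent, and a
#' context and its reverse complement map to the identical channel, so
#' coding-strand and genome-strand observations agree after normalization.
#'
#' @param five,ref,alt,three Single bases A/C/G/T (vectorized, recycled to a
#'   common length); `alt` must differ from `ref`.
#' @return Character vector of canonical channel labels, e.g. `"T[C>A]T"`.
#' @examples
#' normalizeToPyrimidine("T", "C", "A", "T")  # "T[C>A]T"
#' normalizeToPyrimidine("C", "G", "A", "A")  # "T[C>T]G"
#' @export
normalizeToPyrimidine <- function(five, ref, alt, three) {
  n <- max(length(five), length(ref), length(alt), length(three))
  five <- rep_len(toupper(five), n); ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n); three <- rep_len(toupper(three), n)
  ok <- five %in% .BASES & ref %in% .BASES & alt %in% .BASES &
    three %in% .BASES
  if (!all(ok))
    stop("non-ACGT base in trinucleotide context")
  if (any(alt == ref))
    stop("alternate base must differ from reference base")
  flip <- ref %in% c("A", "G")
  out <- character(n)
  out[!flip] <- channelLabel(five[!flip], ref[!flip], alt[!flip],
                             three[!flip])
  if (any(flip))
    out[flip] <- channelLabel(.COMP[three[flip]], .COMP[ref[flip]],
                              .COMP[alt[flip]], .COMP[five[flip]])
  unname(out)
}

#' Trinucleotide channel of a coding substitution
#'
#' Looks up the bases flanking a 1-based transcript position, checks the
#' stated reference base against the transcript, and returns the
#' pyrimidine-normalized channel.
#'
#' @param cdnaPos Integer vector of 1-based transcript coordinates.
#' @param refBase,altBase Character vectors of single bases.
#' @param transcript A [Biostrings::DNAString] (or string) with the coding
#'   sequence.
#' @return Character vector of channel labels.
#' @examples
#' channelOf(2, "C", "A", "TCT")  # "T[C>A]T"
#' @export
channelOf <- function(cdnaPos, refBase, altBase, transcript) {
  seqc <- as.character(transcript)
  L <- nchar(seqc)
  cdnaPos <- as.integer(cdnaPos)
  if (any(is.na(cdnaPos)))
    stop("cdnaPos must be integer positions")
  edge <- cdnaPos <= 1L | cdnaPos >= L
  if (any(edge))
    stop("position at transcript edge has no trinucleotide context: ",
         paste(cdnaPos[edge], collapse = ", "))
  at <- function(i) substring(seqc, i, i)
  obs <- at(cdnaPos)
  bad <- obs != toupper(refBase)
  if (any(bad))
    stop("reference base mismatch at transcript position ",
         paste0(cdnaPos[bad], " (stated ", toupper(refBase)[bad],
                ", transcript ", obs[bad], ")", collapse = "; "))
  normalizeToPyrimidine(at(cdnaPos - 1L), refBase, altBase, at(cdnaPos + 1L))
}

#' Index transcript positions by realizable channel
#'
#' For every interior transcript position and every possible alternate base,
#' records the pyrimidine-normalized channel the substitution would produce.
#' Used by the cohort simulator to draw coding changes that realize a channel
#' sampled from a signature.
#'
#' @param transcript Coding sequence ([Biostrings::DNAString] or string).
#' @return data.frame with columns `pos`, `ref`, `alt`, `channel`.
#' @export
channelPositionIndex <- function(transcript) {
  seqc <- as.character(transcript)
  L <- nchar(seqc)
  pos <- 2:(L - 1L)
  ref <- substring(seqc, pos, pos)
  five <- substring(seqc, pos - 1L, pos - 1L)
  three <- substring(seqc, pos + 1L, pos + 1L)
  alts <- lapply(ref, function(r) setdiff(.BASES, r))
  n <- rep(3L, length(pos))
  out <- data.frame(
    pos = rep(pos, n),
    ref = rep(ref, n),
    alt = unlist(alts),
    stringsAsFactors = FALSE)
  out$channel <- normalizeToPyrimidine(rep(five, n), out$ref, out$alt,
                                       rep(three, n))
  out
}
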