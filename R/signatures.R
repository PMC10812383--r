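## POLE-proofreading signature context sets.  Each of SBS10a/10b/14/28 has a
## described hotspot channel; beyond the hotspot, every channel holding >1%
## of the signature's mass is counted as part of the signature's context.

.SBS_HOTSPOTS <- list(
  SBS10a = "T[C>A]T",
  SBS10b = "T[C>T]G",
  # "NCT" hotspot: C>A in NCT context, N any base
  SBS14 = c("A[C>A]T", "C[C>A]T", "G[C>A]T", "T[C>A]T"),
  SBS28 = "T[T>G]T")

#' Hotspot channels of the POLE-proofreading signatures
#'
#' SBS10a: C>A in TCT; SBS10b: C>T in TCG; SBS14: C>A in NCT (N any base);
#' SBS28: T>G in TTT.
#'
#' @return Named list of character vectors of channel labels.
#' @export
sbsHotspots <- function() .SBS_HOTSPOTS

#' Read a 96-row signature probability table
#'
#' COSMIC-format TSV: a `Type` column with channel labels (`"T[C>A]T"`) and
#' one numeric column per signature.  Each signature column must hold 96
#' non-negative probabilities summing to 1 (tolerance 1e-6).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, 96 rows (rownames = channels in COSMIC order),
#'   one column per signature.
#' @export
readSignatureMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"Type" %in% colnames(d))
    stop("signature table must have a 'Type' column")
  chans <- sbsChannels()
  if (nrow(d) != 96 || !setequal(d$Type, chans))
    stop("signature table must have exactly the 96 SBS channels")
  m <- as.matrix(d[, setdiff(colnames(d), "Type"), drop = FALSE])
  rownames(m) <- d$Type
  m <- m[chans, , drop = FALSE]
  if (any(m < 0)) stop("signature probabilities must be non-negative")
  s <- colSums(m)
  if (any(abs(s - 1) > 1e-6))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[abs(s - 1) > 1e-6], collapse = ", "))
  m
}

#' The signature table bundled with the package
#'
#' A synthetic emulation of the four POLE-proofreading COSMIC signatures
#' (SBS10a, SBS10b, SBS14, SBS28), constructed so that each signature has
#' its described hotspot channel, the minor channels named in the
#' literature (e.g. `G[C>T]G` shared by SBS10a/10b, `C[C>T]G` in SBS14) and
#' a sub-threshold tail, with the >1% channels capturing 88--89% of the
#' mass.  It is *not* a COSMIC release; substitute a real COSMIC TSV via
#' [readSignatureMatrix()] for release-accurate channel probabilities.
#'
#' @return 96 x 4 probability matrix.
#' @export
poleSignatureMatrix <- function() {
  readSignatureMatrix(system.file(
    "extdata", "sbs_pole_signatures_synthetic.tsv",
    package = "poleSig", mustWork = TRUE))
}

#' Build a signature context set by the >1% rule
#'
#' Includes every channel whose probability exceeds `inclusionThreshold`
#' and records the captured mass (`coverage`).  The hotspot channel(s) are
#' attached from the fixed table ([sbsHotspots()]) when the signature id is
#' one of the four POLE signatures; hotspots falling below the threshold
#' are dropped from the primary set with a warning.
#'
#' @param probs Named numeric vector of 96 channel probabilities, or a
#'   single column of [readSignatureMatrix()] output.
#' @param signatureId Signature label, e.g. `"SBS10b"`.
#' @param inclusionThreshold Fraction in (0, 1); default 0.01.
#' @return A [SignatureContextSet-class].
#' @examples
#' m <- poleSignatureMatrix()
#' coverage(buildContextSet(m[, "SBS10b"], "SBS10b"))
#' @export
buildContextSet <- function(probs, signatureId,
                            inclusionThreshold = 0.01) {
  if (length(inclusionThreshold) != 1 || !is.finite(inclusionThreshold) ||
      inclusionThreshold <= 0 || inclusionThreshold >= 1)
    stop("inclusionThreshold must lie in (0, 1)")
  if (is.null(names(probs)) || !setequal(names(probs), sbsChannels()))
    stop("probs must be named by the 96 SBS channels")
  keep <- probs > inclusionThreshold
  primary <- .SBS_HOTSPOTS[[signatureId]]
  if (is.null(primary)) primary <- character()
  dropped <- setdiff(primary, names(probs)[keep])
  if (length(dropped)) {
    warning("hotspot channel(s) below inclusion threshold for ",
            signatureId, ": ", paste(dropped, collapse = ", "))
    primary <- setdiff(primary, dropped)
  }
  new("SignatureContextSet",
      signatureId = signatureId,
      included = names(probs)[keep],
      probs = probs[keep],
      coverage = sum(probs[keep]),
      primary = primary,
      threshold = inclusionThreshold)
}

#' Context sets for all four POLE signatures
#'
#' @param sigMatrix 96 x k signature matrix; default
#'   [poleSignatureMatrix()].
#' @param inclusionThreshold Passed to [buildContextSet()].
#' @return Named list of [SignatureContextSet-class] objects.
#' @export
poleContextSets <- function(sigMatrix = poleSignatureMatrix(),
                            inclusionThreshold = 0.01) {
  sets <- lapply(colnames(sigMatrix), function(id)
    buildContextSet(sigMatrix[, id], id, inclusionThreshold))
  names(sets) <- colnames(sigMatrix)
  sets
}

#' Classify variants against POLE signature context sets
#'
#' For every variant carrying a coding single-nucleotide change, computes
#' its pyrimidine-normalized trinucleotide channel on the transcript and
#' records which signature context sets include it.  Non-SNV records
#' (frameshift, delins, splice, or rows without coding columns) get no
#' channel and are never in a POLE context.
#'
#' @param variants `DataFrame` with columns `raw_label`, `kind` and, for
#'   SNVs, `cdna_pos`, `ref_base`, `alt_base` (1-based transcript
#'   coordinates).
#' @param sets List of [SignatureContextSet-class]; default
#'   [poleContextSets()].
#' @param transcript Coding sequence (string or
#'   [Biostrings::DNAString]); default [poleTranscript()].
#' @return `DataFrame`: `raw_label`, `channel` (`NA` for non-SNV),
#'   `in_pole_context`, `matching_signatures` (comma-joined),
#'   `hotspot_hit` (comma-joined ids whose primary channel matched).
#' @export
classifyVariantContext <- function(variants, sets = poleContextSets(),
                                   transcript = poleTranscript()) {
  n <- nrow(variants)
  snv <- !is.na(variants$kind) &
    !variants$kind %in% c("frameshift", "delins", "inframe_deletion",
                          "inframe_insertion", "duplication", "splice")
  if ("cdna_pos" %in% colnames(variants))
    snv <- snv & !is.na(variants$cdna_pos)
  else
    snv <- rep(FALSE, n)
  channel <- rep(NA_character_, n)
  if (any(snv))
    channel[snv] <- channelOf(variants$cdna_pos[snv],
                              variants$ref_base[snv],
                              variants$alt_base[snv], transcript)
  match1 <- function(ch, field) {
    if (is.na(ch)) return("")
    ids <- names(sets)[vapply(sets, function(s)
      ch %in% slot(s, field), logical(1))]
    paste(ids, collapse = ",")
  }
  matching <- vapply(channel, match1, "", field = "included")
  hotspot <- vapply(channel, match1, "", field = "primary")
  S4Vectors::DataFrame(
    raw_label = variants$raw_label,
    channel = channel,
    in_pole_context = !is.na(channel) & nzchar(matching),
    matching_signatures = matching,
    hotspot_hit = hotspot)
}

#' Fraction of variants in POLE proofreading contexts
#'
#' The headline fraction uses SNV-resolvable variants as the denominator
#' (non-SNVs are excluded and reported separately); the alternative
#' convention with all variants in the denominator is also returned, since
#' published percentages do not always state which was used.
#'
#' @param calls Output of [classifyVariantContext()].
#' @return List with `fraction` (in-context / variants with a channel;
#'   `NA` if no variant resolves to a channel, with `undefined = TRUE`),
#'   `fraction_all_variants`, `n_in_context`, `n_with_channel`, `n_total`,
#'   `denominator` (a note recording the convention) and `breakdown`
#'   (data.frame: channel, count, percent, signatures).
#' @export
fractionInContext <- function(calls) {
  calls <- as.data.frame(calls)
  nTot <- nrow(calls)
  withCh <- !is.na(calls$channel)
  nCh <- sum(withCh)
  nIn <- sum(calls$in_pole_context)
  frac <- if (nCh == 0) NA_real_ else nIn / nCh
  bd <- data.frame()
  if (nCh) {
    tab <- table(calls$channel[withCh])
    bd <- data.frame(channel = names(tab), count = as.integer(tab),
                     percent = round(100 * as.integer(tab) / nCh, 1),
                     stringsAsFactors = FALSE)
    sigs <- calls$matching_signatures[withCh]
    bd$signatures <- vapply(bd$channel, function(ch)
      sigs[match(ch, calls$channel[withCh])], "")
    bd <- bd[order(-bd$count, bd$channel), ]
    rownames(bd) <- NULL
  }
  list(fraction = frac,
       fraction_all_variants = if (nTot) nIn / nTot else NA_real_,
       n_in_context = nIn, n_with_channel = nCh, n_total = nTot,
       undefined = nCh == 0,
       denominator = "SNV-resolvable variants (non-SNVs excluded)",
       breakdown = bd)
}
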