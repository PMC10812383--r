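## Parsing of short-form protein-level variant labels (P286R, R1125X,
## F285_P286delinsLR, ...).  Full HGVS grammar (intronic, UTR, complex
## rearrangements) is out of scope; labels are parsed case-insensitively and
## normalized to upper-case one-letter codes with "*" for stop.

.VARIANT_KINDS <- c("missense", "nonsense", "frameshift", "inframe_deletion",
                    "inframe_insertion", "delins", "duplication", "splice",
                    "other")

.emptyVariantRow <- function(raw) {
  list(raw_label = raw, ref_aa = NA_character_, position = NA_integer_,
       end_ref_aa = NA_character_, end_position = NA_integer_,
       alt_aa = NA_character_, inserted = NA_character_,
       kind = NA_character_)
}

.checkPos <- function(pos, raw) {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE))
    stop("invalid residue position in variant label '", raw, "'")
  pos
}

.parseOneVariant <- function(raw) {
  lab <- toupper(trimws(raw))
  lab <- sub("^P\\.", "", lab)
  out <- .emptyVariantRow(trimws(raw))
  reSpan <- "([A-Z])(\\d+)(?:_([A-Z])(\\d+))?"

  grab <- function(pattern) {
    m <- regexec(pattern, lab)
    g <- regmatches(lab, m)[[1]]
    if (length(g)) g else NULL
  }
  setSpan <- function(g) {
    out$ref_aa <<- g[2]
    out$position <<- .checkPos(g[3], raw)
    if (length(g) >= 5 && nzchar(g[4])) {
      out$end_ref_aa <<- g[4]
      out$end_position <<- .checkPos(g[5], raw)
      if (out$end_position <= out$position)
        stop("interval end must follow start in variant label '", raw, "'")
    } else {
      out$end_ref_aa <<- out$ref_aa
      out$end_position <<- out$position
    }
  }

  if (grepl("SPLICE", lab)) {
    out$kind <- "splice"
    g <- grab(paste0("^", reSpan))
    if (!is.null(g)) setSpan(g)
    return(out)
  }
  if (!is.null(g <- grab(paste0("^", reSpan, "DELINS([A-Z*]+)$")))) {
    setSpan(g)
    out$inserted <- g[6]
    out$kind <- "delins"
    return(out)
  }
  if (!is.null(g <- grab(paste0("^", reSpan, "DEL$")))) {
    setSpan(g)
    out$kind <- "inframe_deletion"
    return(out)
  }
  if (!is.null(g <- grab(paste0("^", reSpan, "INS([A-Z*]+)$")))) {
    setSpan(g)
    out$inserted <- g[6]
    out$kind <- "inframe_insertion"
    return(out)
  }
  if (!is.null(g <- grab(paste0("^", reSpan, "DUP$")))) {
    setSpan(g)
    out$kind <- "duplication"
    return(out)
  }
  if (!is.null(g <- grab("^([A-Z])(\\d+)[A-Z*]?FS.*$"))) {
    out$ref_aa <- g[2]
    out$position <- out$end_position <- .checkPos(g[3], raw)
    out$end_ref_aa <- g[2]
    out$kind <- "frameshift"
    return(out)
  }
  if (!is.null(g <- grab("^([A-Z])(\\d+)(X|\\*)$"))) {
    out$ref_aa <- g[2]
    out$position <- out$end_position <- .checkPos(g[3], raw)
    out$end_ref_aa <- g[2]
    out$alt_aa <- "*"
    out$kind <- "nonsense"
    return(out)
  }
  if (!is.null(g <- grab("^([A-Z])(\\d+)([A-Z])$"))) {
    ref <- g[2]; alt <- g[4]
    if (!ref %in% AA_STANDARD_1 || !alt %in% AA_STANDARD_1)
      stop("non-standard amino acid code in variant label '", raw, "'")
    out$ref_aa <- ref
    out$position <- out$end_position <- .checkPos(g[3], raw)
    out$end_ref_aa <- ref
    out$alt_aa <- alt
    out$kind <- if (alt == ref) "other" else "missense"
    return(out)
  }
  stop("cannot parse variant label '", raw, "'")
}

#' Parse short-form protein variant labels
#'
#' Accepts the label styles used in clinical variant reports: missense
#' (`P286R`), nonsense (`R1125X` or `R1125*`), frameshift (`T457fs`,
#' `L500Pfs*12`), in-frame deletion/insertion/duplication
#' (`A100del`, `A100_C101insS`, `G120dup`), deletion-insertion
#' (`F285_P286delinsLR`) and splice annotations (any label containing
#' `splice`).  A leading `p.` is tolerated; parsing is case-insensitive and
#' output is normalized to upper-case one-letter codes with `*` for stop.
#'
#' @param labels Character vector of variant labels.
#' @return A `DataFrame` with one row per label and columns `raw_label`,
#'   `ref_aa`, `position`, `end_ref_aa`, `end_position` (equal to `position`
#'   for single-residue events), `alt_aa` (`*` for stop; `NA` unless the
#'   event has a single alternate residue), `inserted` (replacement peptide
#'   for delins/insertion) and `kind`.
#' @examples
#' parsePoleVariants(c("P286R", "R1125X", "F285_P286delinsLR", "T457fs"))
#' @seealso [formatPoleVariant()], [annotateDomains()], [flagDrivers()]
#' @export
parsePoleVariants <- function(labels) {
  if (!length(labels) || any(!nzchar(trimws(labels))) || anyNA(labels))
    stop("variant labels must be non-empty strings")
  rows <- lapply(labels, .parseOneVariant)
  S4Vectors::DataFrame(do.call(rbind.data.frame,
                               c(rows, stringsAsFactors = FALSE)))
}

#' Format parsed variants back to canonical labels
#'
#' Inverse of [parsePoleVariants()] on the fields it retains:
#' `parsePoleVariants(formatPoleVariant(v))` reproduces `v` (up to the
#' original spelling in `raw_label`) for every supported kind.
#'
#' @param v A `DataFrame`/data.frame as returned by [parsePoleVariants()].
#' @return Character vector of canonical labels.
#' @export
formatPoleVariant <- function(v) {
  v <- as.data.frame(v)
  span <- ifelse(
    !is.na(v$end_position) & v$end_position != v$position,
    paste0(v$ref_aa, v$position, "_", v$end_ref_aa, v$end_position),
    paste0(v$ref_aa, v$position))
  out <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    out[i] <- switch(v$kind[i],
      missense = paste0(v$ref_aa[i], v$position[i], v$alt_aa[i]),
      other = paste0(v$ref_aa[i], v$position[i], v$alt_aa[i]),
      nonsense = paste0(v$ref_aa[i], v$position[i], "*"),
      frameshift = paste0(v$ref_aa[i], v$position[i], "fs"),
      inframe_deletion = paste0(span[i], "del"),
      inframe_insertion = paste0(span[i], "ins", v$inserted[i]),
      delins = paste0(span[i], "delins", v$inserted[i]),
      duplication = paste0(span[i], "dup"),
      splice = if (is.na(v$position[i])) "splice"
               else paste0(span[i], "splice"),
      stop("unsupported kind: ", v$kind[i]))
  }
  out
}
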