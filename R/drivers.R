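#' Expand driver-catalog shorthand to single alleles
#'
#' Driver lists are conventionally written with slash-separated alternates
#' (`"S297F/Y"` means S297F and S297Y).  Each shorthand entry is expanded to
#' one catalog row per alternate residue; the default shorthand of 12
#' entries expands to exactly 20 alleles.
#'
#' @param shorthand Character vector, each element `"<ref><pos><alt1>[/alt2...]"`.
#' @return A [DriverCatalog-class]; duplicates raise a validity error.
#' @examples
#' length(expandDriverCatalog(c("S297F/Y", "F367C/L/V")))  # 5
#' length(defaultDriverCatalog())                          # 20
#' @export
expandDriverCatalog <- function(shorthand) {
  if (!length(shorthand)) stop("empty driver shorthand list")
  rows <- lapply(shorthand, function(s) {
    g <- regmatches(s, regexec("^([A-Za-z])(\\d+)([A-Za-z/]+)$",
                               trimws(s)))[[1]]
    if (!length(g))
      stop("cannot parse driver shorthand '", s, "'")
    ref <- toupper(g[2])
    pos <- as.integer(g[3])
    alts <- toupper(strsplit(g[4], "/", fixed = TRUE)[[1]])
    if (pos < 1) stop("invalid position in driver shorthand '", s, "'")
    if (!all(nchar(alts) == 1) || !all(alts %in% AA_STANDARD_1) ||
        !ref %in% AA_STANDARD_1)
      stop("non-standard amino acid in driver shorthand '", s, "'")
    data.frame(ref_aa = ref, position = pos, alt_aa = alts,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  new("DriverCatalog", entries = S4Vectors::DataFrame(entries),
      shorthand = as.character(shorthand))
}

#' Read a driver catalog from JSON
#'
#' Expects `{"drivers": ["D275G", "P286R", "S297F/Y", ...]}`.
#'
#' @param path Path to a JSON file.
#' @return A [DriverCatalog-class].
#' @export
readDriverCatalog <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (is.null(j$drivers)) stop("catalog JSON must have a 'drivers' field")
  expandDriverCatalog(j$drivers)
}

#' The default catalog of 20 POLE ExoD driver alleles
#'
#' The established exonuclease-domain proofreading drivers used for tumor
#' stratification: D275G, P286R, S297F/Y, F367C/L/V, V411L, L424F, P436R/S/Y,
#' M444K/L, A456P, S459F/Y, S461L/P, A465V -- 20 alleles after shorthand
#' expansion.
#'
#' @return A [DriverCatalog-class] with 20 entries.
#' @export
defaultDriverCatalog <- function() {
  readDriverCatalog(system.file("extdata", "pole_exod_drivers.json",
                                package = "poleSig", mustWork = TRUE))
}

#' Flag catalog driver alleles among parsed variants
#'
#' A variant is a driver only on an exact (ref, position, alt) missense
#' match against the expanded catalog.  Everything else -- non-catalog ExoD
#' missense, truncating variants, delins events even when they overlap a
#' driver residue -- is flagged `FALSE`.
#'
#' @param variants `DataFrame` from [parsePoleVariants()].
#' @param catalog A [DriverCatalog-class]; defaults to
#'   [defaultDriverCatalog()].
#' @return `variants` with a logical `is_exod_driver` column added.
#' @examples
#' v <- parsePoleVariants(c("V411L", "M444I", "F285_P286delinsLR"))
#' flagDrivers(v)$is_exod_driver  # TRUE FALSE FALSE
#' @export
flagDrivers <- function(variants, catalog = defaultDriverCatalog()) {
  e <- driverEntries(catalog)
  keys <- paste0(e$ref_aa, e$position, e$alt_aa)
  vkey <- paste0(variants$ref_aa, variants$position, variants$alt_aa)
  variants$is_exod_driver <- variants$kind == "missense" & vkey %in% keys
  variants$is_exod_driver[is.na(variants$is_exod_driver)] <- FALSE
  variants
}
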