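#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Driver allele entries of a catalog
#'
#' @param x A [DriverCatalog-class] object.
#' @return A `DataFrame` with columns `ref_aa`, `position`, `alt_aa`.
#' @export
setGeneric("driverEntries", function(x) standardGeneric("driverEntries"))

#' Protein length recorded in a domain map
#'
#' @param x A [DomainMap-class] object.
#' @return Integer scalar, the protein length in residues.
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' Channels retained by the >1% inclusion rule
#'
#' @param x A [SignatureContextSet-class] object.
#' @return Character vector of channel labels, e.g. `"T[C>A]T"`.
#' @export
setGeneric("includedChannels", function(x) standardGeneric("includedChannels"))

#' Signature mass captured by the included channels
#'
#' @param x A [SignatureContextSet-class] object.
#' @return Numeric scalar in (0, 1].
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' Hotspot (primary) channels of a signature
#'
#' @param x A [SignatureContextSet-class] object.
#' @return Character vector of primary channel labels.
#' @export
setGeneric("primaryChannels", function(x) standardGeneric("primaryChannels"))

#' Per-tumor clinical rows of a cohort
#'
#' @param x A [PoleCohort-class] object.
#' @return A `DataFrame`, one row per tumor.
#' @export
setGeneric("tumorProfiles", function(x) standardGeneric("tumorProfiles"))

#' Parsed POLE variant calls of a cohort
#'
#' @param x A [PoleCohort-class] object.
#' @return A `DataFrame`, one row per variant call, keyed by `tumor_id`.
#' @export
setGeneric("poleVariants", function(x) standardGeneric("poleVariants"))

#' Rows rejected while reading a cohort file
#'
#' @param x A [PoleCohort-class] object.
#' @return A `DataFrame` of rejected records with a `reason` column.
#' @export
setGeneric("cohortRejects", function(x) standardGeneric("cohortRejects"))
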