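#' Curated catalog of POLE exonuclease-domain driver alleles
#'
#' Holds the expanded set of (reference residue, position, alternate residue)
#' driver alleles used to stratify POLE-mutated tumors.  The default catalog
#' bundled with the package expands to 20 alleles; see
#' [defaultDriverCatalog()] and [expandDriverCatalog()].
#'
#' @slot entries `DataFrame` with character columns `ref_aa`, `alt_aa` and
#'   integer column `position`; one row per allele, no duplicates.
#' @slot shorthand Character vector with the original shorthand list the
#'   catalog was expanded from (e.g. `"S297F/Y"`).
#'
#' @seealso [expandDriverCatalog()], [flagDrivers()]
#' @export
setClass("DriverCatalog",
  representation(entries = "DataFrame", shorthand = "character"))

setValidity("DriverCatalog", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("ref_aa", "position", "alt_aa")
  if (!all(need %in% colnames(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  key <- paste0(e$ref_aa, e$position, e$alt_aa)
  if (anyDuplicated(key))
    msg <- c(msg, paste("duplicate catalog entries:",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  if (nrow(e) && any(e$position < 1))
    msg <- c(msg, "positions must be >= 1")
  if (nrow(e) && !all(e$ref_aa %in% AA_STANDARD_1))
    msg <- c(msg, "ref_aa must be standard one-letter amino acids")
  if (length(msg)) msg else TRUE
})

#' @describeIn DriverCatalog-class number of expanded driver alleles
#' @param x,object A `DriverCatalog`.
#' @export
setMethod("length", "DriverCatalog", function(x) nrow(x@entries))

#' @rdname driverEntries
#' @export
setMethod("driverEntries", "DriverCatalog", function(x) x@entries)

setMethod("show", "DriverCatalog", function(object) {
  cat("DriverCatalog with", nrow(object@entries), "expanded alleles\n")
  cat("  shorthand:", paste(object@shorthand, collapse = ", "), "\n")
})

#' Domain map of the POLE catalytic subunit
#'
#' A tiered interval map over protein residues.  The `lobe` tier partitions
#' the protein into the N-terminal lobe (NTL, residues 1--1,183 by default,
#' holding the exonuclease and polymerase domains) and the C-terminal lobe
#' (CTL); it must cover every residue exactly once.  The `domain` and
#' `subdomain` tiers are optional refinements (ExoD, polymerase
#' palm/fingers/thumb, CTD, ...); intervals within a tier may not overlap.
#'
#' @slot proteinLength Integer scalar; 2,286 residues for human POLE.
#' @slot intervals `DataFrame` with columns `name` (character),
#'   `start`, `end` (integer, 1-based inclusive) and
#'   `tier` (one of `"lobe"`, `"domain"`, `"subdomain"`).
#'
#' @seealso [defaultDomainMap()], [annotateDomains()]
#' @export
setClass("DomainMap",
  representation(proteinLength = "integer", intervals = "DataFrame"))

setValidity("DomainMap", function(object) {
  iv <- object@intervals
  msg <- character()
  need <- c("name", "start", "end", "tier")
  if (!all(need %in% colnames(iv)))
    return(paste("intervals must have columns", paste(need, collapse = ", ")))
  if (!all(iv$tier %in% c("lobe", "domain", "subdomain")))
    msg <- c(msg, "tier must be lobe, domain or subdomain")
  if (any(iv$start < 1) || any(iv$end > object@proteinLength) ||
      any(iv$start > iv$end))
    msg <- c(msg, "intervals must satisfy 1 <= start <= end <= proteinLength")
  for (t in unique(iv$tier)) {
    sub <- iv[iv$tier == t, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    if (length(ir) > 1 &&
        any(IRanges::countOverlaps(ir, ir) > 1))
      msg <- c(msg, paste0("overlapping intervals in tier '", t, "'"))
  }
  lobes <- iv[iv$tier == "lobe", , drop = FALSE]
  if (nrow(lobes) == 0) {
    msg <- c(msg, "a lobe tier (NTL/CTL) is required")
  } else {
    cov <- sum(lobes$end - lobes$start + 1)
    if (cov != object@proteinLength)
      msg <- c(msg, "lobe tier must cover every residue exactly once")
    if (!all(c("NTL", "CTL") %in% lobes$name))
      msg <- c(msg, "lobe tier must name NTL and CTL")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname proteinLength
#' @export
setMethod("proteinLength", "DomainMap", function(x) x@proteinLength)

setMethod("show", "DomainMap", function(object) {
  cat("DomainMap over", object@proteinLength, "residues\n")
  iv <- object@intervals
  for (t in c("lobe", "domain", "subdomain")) {
    sub <- iv[iv$tier == t, , drop = FALSE]
    if (nrow(sub))
      cat(sprintf("  %-9s %s\n", t,
                  paste0(sub$name, " ", sub$start, "-", sub$end,
                         collapse = ", ")))
  }
})

#' Context set of a mutational signature under the >1% rule
#'
#' The set of 96-channel trinucleotide mutation types that individually carry
#' more than the inclusion threshold (1% by default) of a signature's
#' probability mass, together with the captured mass (`coverage`) and the
#' signature's hotspot channel(s).  For the four POLE-proofreading signatures
#' the included channels capture 88--90% of each signature.
#'
#' @slot signatureId Character scalar, e.g. `"SBS10b"`.
#' @slot included Character vector of channel labels with probability above
#'   the threshold.
#' @slot probs Named numeric vector: the probabilities of the included
#'   channels.
#' @slot coverage Numeric scalar, the summed included probability.
#' @slot primary Character vector of hotspot channel(s); always a subset of
#'   `included`.
#' @slot threshold Numeric scalar, the inclusion threshold used.
#'
#' @seealso [buildContextSet()], [classifyVariantContext()]
#' @export
setClass("SignatureContextSet",
  representation(signatureId = "character", included = "character",
                 probs = "numeric", coverage = "numeric",
                 primary = "character", threshold = "numeric"))

setValidity("SignatureContextSet", function(object) {
  msg <- character()
  if (length(object@signatureId) != 1)
    msg <- c(msg, "signatureId must be a single string")
  if (!setequal(names(object@probs), object@included) ||
      length(object@probs) != length(object@included))
    msg <- c(msg, "probs must be named by exactly the included channels")
  if (any(object@probs <= object@threshold))
    msg <- c(msg, "every included channel must exceed the inclusion threshold")
  if (length(object@coverage) != 1 ||
      object@coverage <= 0 || object@coverage > 1 + 1e-9)
    msg <- c(msg, "coverage must lie in (0, 1]")
  if (abs(object@coverage - sum(object@probs)) > 1e-9)
    msg <- c(msg, "coverage must equal the sum of included probabilities")
  if (!all(object@primary %in% object@included))
    msg <- c(msg, "primary channels must be included channels")
  if (length(msg)) msg else TRUE
})

#' @rdname includedChannels
#' @export
setMethod("includedChannels", "SignatureContextSet", function(x) x@included)

#' @rdname coverage
#' @export
setMethod("coverage", "SignatureContextSet", function(x) x@coverage)

#' @rdname primaryChannels
#' @export
setMethod("primaryChannels", "SignatureContextSet", function(x) x@primary)

setMethod("show", "SignatureContextSet", function(object) {
  cat(sprintf(
    "SignatureContextSet %s: %d channels > %.3g, coverage %.3f\n",
    object@signatureId, length(object@included), object@threshold,
    object@coverage))
  cat("  primary:", paste(object@primary, collapse = ", "), "\n")
})

#' A cohort of POLE-mutated tumor genomic profiles
#'
#' Container pairing per-tumor clinical rows (TMB in mut/Mb, MSI status,
#' cancer type, age, sex) with the parsed POLE variant calls of each tumor.
#' Every tumor in the cohort carries at least one POLE variant; profiles
#' without a variant do not enter the analysis.
#'
#' @slot profiles `DataFrame`, one row per tumor, with columns `tumor_id`,
#'   `cancer_type` (`CRC`, `EC`, `OC` or `other`), `tmb` (non-negative,
#'   mut/Mb), `msi_status` (`MSS`, `MSI-H` or `unknown`), `age`, `sex`.
#' @slot variants `DataFrame`, one row per variant call, with `tumor_id` and
#'   the columns produced by [parsePoleVariants()]; optionally
#'   coding-level columns `cdna_pos`, `ref_base`, `alt_base`.
#' @slot rejects `DataFrame` of input records that failed validation when the
#'   cohort was read from file (empty for simulated cohorts).
#'
#' @seealso [readCohort()], [simulateCohort()], [assignGroups()]
#' @export
setClass("PoleCohort",
  representation(profiles = "DataFrame", variants = "DataFrame",
                 rejects = "DataFrame"))

.MSI_LEVELS <- c("MSS", "MSI-H", "unknown")
.CANCER_TYPES <- c("CRC", "EC", "OC", "other")

setValidity("PoleCohort", function(object) {
  p <- object@profiles
  v <- object@variants
  msg <- character()
  need <- c("tumor_id", "cancer_type", "tmb", "msi_status")
  if (!all(need %in% colnames(p)))
    return(paste("profiles must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(p$tumor_id))
    msg <- c(msg, "duplicate tumor_id in profiles")
  if (nrow(p) && any(p$tmb < 0, na.rm = TRUE))
    msg <- c(msg, "tmb must be non-negative")
  if (nrow(p) && !all(p$msi_status %in% .MSI_LEVELS))
    msg <- c(msg, "msi_status must be one of MSS, MSI-H, unknown")
  if (nrow(p) && !all(p$cancer_type %in% .CANCER_TYPES))
    msg <- c(msg, "cancer_type must be one of CRC, EC, OC, other")
  if (!"tumor_id" %in% colnames(v))
    msg <- c(msg, "variants must have a tumor_id column")
  else {
    if (nrow(p) && !all(p$tumor_id %in% v$tumor_id))
      msg <- c(msg, "every tumor must carry at least one POLE variant")
    if (nrow(v) && !all(v$tumor_id %in% p$tumor_id))
      msg <- c(msg, "variants reference unknown tumor_id")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname tumorProfiles
#' @export
setMethod("tumorProfiles", "PoleCohort", function(x) x@profiles)

#' @rdname poleVariants
#' @export
setMethod("poleVariants", "PoleCohort", function(x) x@variants)

#' @rdname cohortRejects
#' @export
setMethod("cohortRejects", "PoleCohort", function(x) x@rejects)

#' @describeIn PoleCohort-class number of tumors in the cohort
#' @param x,object A `PoleCohort`.
#' @export
setMethod("length", "PoleCohort", function(x) nrow(x@profiles))

setMethod("show", "PoleCohort", function(object) {
  p <- object@profiles
  cat("PoleCohort:", nrow(p), "tumors,", nrow(object@variants),
      "POLE variant calls\n")
  if (nrow(p)) {
    tab <- table(factor(p$cancer_type, levels = .CANCER_TYPES))
    tab <- tab[tab > 0]
    cat("  cancer types:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  TMB: median %.1f, range %.0f-%.0f mut/Mb\n",
                stats::median(p$tmb), min(p$tmb), max(p$tmb)))
  }
  if (nrow(object@rejects))
    cat("  (", nrow(object@rejects), "rejected input records )\n")
})

#' Construct a PoleCohort from profile and variant tables
#'
#' @param profiles A data.frame or `DataFrame` of per-tumor rows; see
#'   [PoleCohort-class] for required columns.  `msi_status` entries are
#'   normalized with [normalizeMsiStatus()]; missing `age`/`sex` columns are
#'   added as `NA`/`"unknown"`.
#' @param variants A data.frame or `DataFrame` of parsed variant calls with a
#'   `tumor_id` column.
#' @param rejects Optional `DataFrame` of rejected input records.
#' @return A validated [PoleCohort-class] object.
#' @examples
#' prof <- data.frame(tumor_id = "T1", cancer_type = "CRC", tmb = 115,
#'                    msi_status = "MSS")
#' vars <- cbind(tumor_id = "T1", as.data.frame(parsePoleVariants("P286R")))
#' PoleCohort(prof, vars)
#' @export
PoleCohort <- function(profiles, variants,
                       rejects = S4Vectors::DataFrame()) {
  profiles <- S4Vectors::DataFrame(profiles)
  variants <- S4Vectors::DataFrame(variants)
  if (!"age" %in% colnames(profiles)) profiles$age <- NA_real_
  if (!"sex" %in% colnames(profiles)) profiles$sex <- "unknown"
  profiles$msi_status <- normalizeMsiStatus(profiles$msi_status)
  profiles$cancer_type <- as.character(profiles$cancer_type)
  profiles$tumor_id <- as.character(profiles$tumor_id)
  new("PoleCohort", profiles = profiles, variants = variants,
      rejects = S4Vectors::DataFrame(rejects))
}

#' Normalize microsatellite-status vocabulary
#'
#' Collapses the spellings seen in clinical exports onto the fixed
#' vocabulary `MSS` / `MSI-H` / `unknown`.  MSI-low is collapsed into `MSS`,
#' matching the dichotomized MSS/MSI reporting used in group summaries.
#'
#' @param x Character vector of raw status strings.
#' @return Character vector over `c("MSS", "MSI-H", "unknown")`.
#' @examples
#' normalizeMsiStatus(c("MSI-High", "ms-stable", "MSI-L", "equivocal"))
#' @export
normalizeMsiStatus <- function(x) {
  x0 <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x0))
  out[x0 %in% c("MSI", "MSI-H", "MSI-HIGH", "MSI HIGH", "HIGH")] <- "MSI-H"
  out[x0 %in% c("MSS", "MS-STABLE", "STABLE", "MSI-L", "MSI-LOW")] <- "MSS"
  out[is.na(x)] <- "unknown"
  out
}
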