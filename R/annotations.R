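## Rule-based annotation layers: ddG stability classes, neoantigen
## categories with the dual 0.5 threshold, and the Group-3-exclusive
## mutation filter.

#' Classify a predicted stability change
#'
#' ddG is the predicted folding free-energy change of the mutant versus the
#' wild-type protein in kcal/mol (Rosetta energy units calibrated to
#' kcal/mol); positive values destabilize.  Boundaries are inclusive:
#' `ddg >= +cutoff` is destabilizing, `ddg <= -cutoff` stabilizing, the rest
#' neutral.
#'
#' @param ddg Numeric vector of ddG values (finite).
#' @param cutoff Significance cutoff in kcal/mol; default 1.45.
#' @return Character vector over
#'   `c("stabilizing", "neutral", "destabilizing")`.
#' @examples
#' classifyStability(c(4.2, 0, -1.45))
#' @export
classifyStability <- function(ddg, cutoff = 1.45) {
  if (any(!is.finite(ddg))) stop("ddg values must be finite")
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  ifelse(ddg >= cutoff, "destabilizing",
  ifelse(ddg <= -cutoff, "stabilizing", "neutral"))
}

.NEO_CATEGORIES <- c("immunogenic", "nonimmunogenic",
                     "no_biological_significance", "none")

#' Categorize a predicted neoantigen
#'
#' Dual-threshold rule on MHC-binding and T-cell-reactivity scores, both in
#' \[0, 1\] with inclusive boundaries at the threshold: both >= 0.5 is an
#' immunogenic neoantigen; binding >= 0.5 with reactivity < 0.5 a
#' nonimmunogenic neoantigen; binding < 0.5 with reactivity >= 0.5 no
#' biological significance; both < 0.5 no neoantigen.  The four categories
#' partition the unit square.
#'
#' @param mhc,tcr Numeric vectors of scores in \[0, 1\].
#' @param threshold Decision threshold; default 0.5.
#' @return Character vector over the four categories.
#' @examples
#' categorizeNeoantigen(c(0.7, 0.7, 0.3, 0.5), c(0.6, 0.3, 0.7, 0.5))
#' @export
categorizeNeoantigen <- function(mhc, tcr, threshold = 0.5) {
  if (any(!is.finite(mhc)) || any(!is.finite(tcr)) ||
      any(mhc < 0 | mhc > 1) || any(tcr < 0 | tcr > 1))
    stop("scores must lie in [0, 1]")
  ifelse(mhc >= threshold & tcr >= threshold, "immunogenic",
  ifelse(mhc >= threshold, "nonimmunogenic",
  ifelse(tcr >= threshold, "no_biological_significance", "none")))
}

#' Modified neoantigen burden
#'
#' The number of immunogenic neoantigens predicted for each tumor.
#'
#' @param scores data.frame with columns `tumor_id`, `mhc_binding`,
#'   `tcell_reactivity` (or a precomputed `category` column).
#' @param threshold Passed to [categorizeNeoantigen()].
#' @return data.frame with columns `tumor_id`, `neoantigen_burden`; tumors
#'   present in `scores` but with no immunogenic peptide get 0.
#' @export
neoantigenBurden <- function(scores, threshold = 0.5) {
  scores <- as.data.frame(scores)
  if (!nrow(scores))
    return(data.frame(tumor_id = character(),
                      neoantigen_burden = integer()))
  if (!"category" %in% colnames(scores))
    scores$category <- categorizeNeoantigen(scores$mhc_binding,
                                            scores$tcell_reactivity,
                                            threshold)
  tab <- tapply(scores$category == "immunogenic", scores$tumor_id, sum)
  data.frame(tumor_id = names(tab),
             neoantigen_burden = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select mutations effectively exclusive to Group 3
#'
#' Keeps mutations that appeared at most once in Group 2 (including not at
#' all) and at least twice in Group 3.  Counts are keyed by
#' (gene, protein change) identity.
#'
#' @param countsG2,countsG3 Named non-negative integer vectors of mutation
#'   occurrence counts; names are mutation keys.  Keys absent from a vector
#'   count as 0.
#' @return Sorted character vector of selected mutation keys.
#' @examples
#' selectGroup3Exclusive(c(A = 1, B = 2), c(A = 2, B = 5, C = 1))  # "A"
#' @export
selectGroup3Exclusive <- function(countsG2, countsG3) {
  if (is.null(countsG2)) countsG2 <- stats::setNames(numeric(), character())
  if (is.null(countsG3)) countsG3 <- stats::setNames(numeric(), character())
  if (any(countsG2 < 0) || any(countsG3 < 0) ||
      any(countsG2 != floor(countsG2)) || any(countsG3 != floor(countsG3)))
    stop("counts must be non-negative integers")
  keys <- union(names(countsG2), names(countsG3))
  g2 <- ifelse(keys %in% names(countsG2), countsG2[keys], 0L)
  g3 <- ifelse(keys %in% names(countsG3), countsG3[keys], 0L)
  sort(keys[g2 <= 1 & g3 >= 2])
}

#' Cross-tabulate stability classes by lobe and model
#'
#' Parses the protein labels of missense ddG records, assigns each to the
#' NTL or CTL via the domain map, classifies stability, and cross-tabulates
#' lobe x class x model.  ddG on the DNA-bound model is only defined for
#' NTL residues (the DNA-bound structure covers the N-terminal half), so
#' dna_bound records at CTL residues raise an error.
#'
#' @param records data.frame with columns `variant` (protein label),
#'   `model` (`"dna_bound"`/`"dna_unbound"`), `ddg`.
#' @param map A [DomainMap-class]; default [defaultDomainMap()].
#' @param cutoff Passed to [classifyStability()].
#' @return List with `census` (3-way `table`: lobe x stability class x
#'   model) and `records` (the annotated per-record data.frame).
#' @export
stabilityCensus <- function(records, map = defaultDomainMap(),
                            cutoff = 1.45) {
  records <- as.data.frame(records)
  stopifnot(all(c("variant", "model", "ddg") %in% colnames(records)))
  if (!all(records$model %in% c("dna_bound", "dna_unbound")))
    stop("model must be dna_bound or dna_unbound")
  v <- parsePoleVariants(records$variant)
  if (!all(v$kind == "missense"))
    stop("stability census is defined for missense records only; got: ",
         paste(unique(records$variant[v$kind != "missense"]),
               collapse = ", "))
  v <- annotateDomains(v, map)
  records$lobe <- v$lobe
  records$stability_class <- classifyStability(records$ddg, cutoff)
  bad <- records$model == "dna_bound" & records$lobe != "NTL"
  if (any(bad))
    stop("dna_bound ddG supplied for CTL residue(s): ",
         paste(records$variant[bad], collapse = ", "))
  census <- table(
    lobe = factor(records$lobe, levels = c("NTL", "CTL")),
    stability_class = factor(records$stability_class,
                             levels = c("stabilizing", "neutral",
                                        "destabilizing")),
    model = factor(records$model,
                   levels = c("dna_unbound", "dna_bound")))
  list(census = census, records = records)
}
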