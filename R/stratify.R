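## Four-group taxonomy of POLE-mutated tumors:
##   G1  TMB-L (< threshold), any POLE variant, no requirement on drivers
##   G2  TMB-H, >=1 catalog ExoD driver, no additional POLE variant
##   G3  TMB-H, >=1 catalog ExoD driver plus >=1 additional POLE variant
##   G4  TMB-H, POLE variant(s) but no catalog driver
## The TMB-H cutoff is >= 10 mut/Mb (KEYNOTE-158 convention).

#' Assign POLE-mutated tumors to Groups 1-4
#'
#' Applies the TMB threshold and driver co-occurrence taxonomy to every
#' tumor of a cohort.  Group membership keys on driver *presence*, not
#' count: the few tumors carrying two catalog drivers are G2 when no
#' additional non-driver variant co-occurs, else G3.  A TMB-low profile that
#' nevertheless carries a catalog driver is assigned G1 with the anomaly
#' flag `driver_with_low_tmb`.  Substatus is `MSI` exactly when the profile
#' is MSI-H; unknown status is treated as MSS (the group tables dichotomize
#' MSS/MSI) with a warning.
#'
#' @param cohort A [PoleCohort-class].
#' @param catalog A [DriverCatalog-class]; default [defaultDriverCatalog()].
#' @param tmbThreshold TMB-high cutoff in mut/Mb; the boundary value is
#'   TMB-high.  Default 10.
#' @return A `DataFrame` with one row per tumor: `tumor_id`, `group`
#'   (`G1`..`G4`), `substatus` (`MSS`/`MSI`), `n_drivers`,
#'   `n_additional_variants`, `anomaly_flags`.
#' @examples
#' prof <- data.frame(tumor_id = c("a", "b"), cancer_type = "CRC",
#'                    tmb = c(6, 115), msi_status = "MSS")
#' vars <- data.frame(tumor_id = c("a", "b"),
#'                    as.data.frame(parsePoleVariants(c("A252V", "P286R"))))
#' assignGroups(PoleCohort(prof, vars))$group  # "G1" "G2"
#' @export
assignGroups <- function(cohort, catalog = defaultDriverCatalog(),
                         tmbThreshold = 10) {
  stopifnot(is(cohort, "PoleCohort"))
  p <- tumorProfiles(cohort)
  v <- poleVariants(cohort)
  if (!nrow(p)) stop("empty cohort")
  if (any(is.na(p$tmb)))
    stop("missing TMB for tumor(s): ",
         paste(p$tumor_id[is.na(p$tmb)], collapse = ", "))
  if (!"is_exod_driver" %in% colnames(v))
    v <- flagDrivers(v, catalog)
  nd <- table(factor(v$tumor_id[v$is_exod_driver], levels = p$tumor_id))
  na <- table(factor(v$tumor_id[!v$is_exod_driver], levels = p$tumor_id))
  nDrivers <- as.integer(nd[p$tumor_id])
  nAdd <- as.integer(na[p$tumor_id])
  if (any(nDrivers + nAdd == 0))
    stop("tumor(s) without POLE variants cannot be grouped")

  high <- p$tmb >= tmbThreshold
  group <- ifelse(!high, "G1",
           ifelse(nDrivers >= 1 & nAdd == 0, "G2",
           ifelse(nDrivers >= 1, "G3", "G4")))
  anomaly <- ifelse(!high & nDrivers >= 1, "driver_with_low_tmb", "")
  if (any(p$msi_status == "unknown"))
    warning("unknown MSI status treated as MSS for ",
            sum(p$msi_status == "unknown"), " tumor(s)")
  substatus <- ifelse(p$msi_status == "MSI-H", "MSI", "MSS")
  S4Vectors::DataFrame(tumor_id = p$tumor_id, group = group,
                       substatus = substatus, n_drivers = nDrivers,
                       n_additional_variants = nAdd,
                       anomaly_flags = anomaly)
}

#' Summarize groups per cancer type
#'
#' Produces the per-(cancer type, group) summary used in cohort tables:
#' n, median TMB (even-n median is the mean of the two central order
#' statistics), TMB range, MSS/MSI counts, age buckets (<50 vs >=50 years)
#' and sex counts.
#'
#' @param cohort A [PoleCohort-class].
#' @param assignments Output of [assignGroups()] for the same cohort.
#' @return data.frame with columns `cancer_type`, `group`, `n`,
#'   `median_tmb`, `tmb_min`, `tmb_max`, `n_MSS`, `n_MSI`, `n_under_50`,
#'   `n_50_plus`, `n_female`, `n_male`.  Groups with no members get `n = 0`
#'   and `NA` summary fields.
#' @export
summarizeGroups <- function(cohort, assignments) {
  p <- as.data.frame(tumorProfiles(cohort))
  a <- as.data.frame(assignments)
  d <- merge(p, a, by = "tumor_id")
  types <- intersect(.CANCER_TYPES, unique(d$cancer_type))
  out <- expand.grid(cancer_type = types, group = paste0("G", 1:4),
                     stringsAsFactors = FALSE)
  out <- out[order(out$cancer_type, out$group), ]
  rows <- lapply(seq_len(nrow(out)), function(i) {
    s <- d[d$cancer_type == out$cancer_type[i] & d$group == out$group[i], ]
    if (!nrow(s))
      return(data.frame(n = 0L, median_tmb = NA_real_, tmb_min = NA_real_,
                        tmb_max = NA_real_, n_MSS = NA_integer_,
                        n_MSI = NA_integer_, n_under_50 = NA_integer_,
                        n_50_plus = NA_integer_, n_female = NA_integer_,
                        n_male = NA_integer_))
    data.frame(
      n = nrow(s),
      median_tmb = stats::median(s$tmb),
      tmb_min = min(s$tmb), tmb_max = max(s$tmb),
      n_MSS = sum(s$substatus == "MSS"),
      n_MSI = sum(s$substatus == "MSI"),
      n_under_50 = sum(s$age < 50, na.rm = TRUE),
      n_50_plus = sum(s$age >= 50, na.rm = TRUE),
      n_female = sum(s$sex == "F", na.rm = TRUE),
      n_male = sum(s$sex == "M", na.rm = TRUE))
  })
  cbind(out, do.call(rbind, rows), row.names = NULL)
}

#' POLE mutation frequency in a profiled population
#'
#' @param nPoleMutated Number of POLE-mutated tumors.
#' @param nProfiled Number of profiled tumors (> 0).
#' @return Percentage reported to one decimal, e.g.
#'   `poleMutationFrequency(92, 1870)` is 4.9.
#' @export
poleMutationFrequency <- function(nPoleMutated, nProfiled) {
  if (any(nProfiled <= 0)) stop("nProfiled must be positive")
  if (any(nPoleMutated < 0) || any(nPoleMutated > nProfiled))
    stop("need 0 <= nPoleMutated <= nProfiled")
  round(100 * nPoleMutated / nProfiled, 1)
}
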