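## Seeded synthetic-cohort generator.  Defaults encode the study conditions
## of the discovery cohort: per-(cancer type, group) sizes, TMB
## median/range targets, MSS/MSI composition, age and sex structure,
## driver allele frequencies concentrated on P286R and V411L, and passenger
## POLE variants drawn from a mixture of the four proofreading signatures
## plus uniform noise.

#' Default per-(cancer type, group) cohort targets
#'
#' Group sizes, TMB medians and ranges (mut/Mb), MSI counts, under-50 age
#' counts and female counts for the three cancer types, as used by
#' [simulateCohort()].  Endometrial and ovarian groups are all-female.
#'
#' @return data.frame with one row per (cancer_type, group).
#' @export
defaultGroupTargets <- function() {
  tab <- rbind(
    c("CRC", "G1", 36,   6,   3,   9,  0,  6, 19),
    c("CRC", "G2", 11, 115,  61, 216,  0,  5,  1),
    c("CRC", "G3", 24, 264.5, 114, 414, 3, 14,  6),
    c("CRC", "G4", 21,  33,  10, 461, 10,  8,  8),
    c("EC",  "G1", 95,   7,   3,   9,  5,  6, 95),
    c("EC",  "G2", 37,  52,  21, 314,  2,  6, 37),
    c("EC",  "G3", 57, 219,  53, 520, 16, 10, 57),
    c("EC",  "G4", 118, 17.5, 10, 273, 95,  5, 118),
    c("OC",  "G1", 24,   5,   4,   9,  0,  4, 24),
    c("OC",  "G2", 12,  69,  31, 379,  0,  4, 12),
    c("OC",  "G3",  8, 145,  51, 394,  2,  5,  8),
    c("OC",  "G4",  4, 14.5, 10,  21,  2,  3,  4))
  out <- data.frame(cancer_type = tab[, 1], group = tab[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:9], 2, as.numeric)
  colnames(num) <- c("n", "tmb_median", "tmb_min", "tmb_max", "n_msi",
                     "n_under_50", "n_female")
  cbind(out, num)
}

#' Default driver allele frequencies
#'
#' P286R 0.40 and V411L 0.27 -- together about two thirds of driver-bearing
#' tumors -- with the remaining mass spread evenly over the other 18
#' catalog alleles.
#'
#' @param catalog A [DriverCatalog-class].
#' @return Named numeric vector over driver labels, summing to 1.
#' @export
defaultDriverWeights <- function(catalog = defaultDriverCatalog()) {
  e <- driverEntries(catalog)
  labs <- paste0(e$ref_aa, e$position, e$alt_aa)
  w <- stats::setNames(rep(NA_real_, length(labs)), labs)
  w["P286R"] <- 0.40
  w["V411L"] <- 0.27
  rest <- setdiff(labs, c("P286R", "V411L"))
  w[rest] <- (1 - 0.67) / length(rest)
  w
}

#' Build and validate a synthetic-cohort configuration
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param groups Per-(cancer type, group) targets; default
#'   [defaultGroupTargets()].
#' @param driverWeights Named weights over catalog driver labels; default
#'   [defaultDriverWeights()].
#' @param signatureMixture Named weights over
#'   `c("SBS10a","SBS10b","SBS14","SBS28","noise")` for passenger-variant
#'   generation; must sum to 1.  The default puts 80% of passengers on the
#'   proofreading signatures and 20% on uniform noise.
#' @param nAdditionalDist Distribution of the number of passenger POLE
#'   variants per tumor (names = counts >= 1).
#' @param pSecondDriver Probability a driver-bearing tumor carries a second
#'   catalog driver.
#' @param tmbThreshold TMB-high cutoff used for feasibility checks.
#' @param ddgParams List: mean/sd of driver and passenger ddG draws
#'   (kcal/mol).
#' @param neoParams List: `rate` peptides per mut/Mb and Beta shape
#'   parameters for the two scores.
#' @return A validated list of class `"SyntheticCohortConfig"`.
#' @export
syntheticCohortConfig <- function(
    seed = 1L,
    groups = defaultGroupTargets(),
    driverWeights = defaultDriverWeights(),
    signatureMixture = c(SBS10a = 0.28, SBS10b = 0.32, SBS14 = 0.12,
                         SBS28 = 0.08, noise = 0.20),
    nAdditionalDist = c("1" = 0.60, "2" = 0.25, "3" = 0.10, "4" = 0.05),
    pSecondDriver = 0.03,
    tmbThreshold = 10,
    ddgParams = list(driver_mean = 2.8, driver_sd = 1.2,
                     passenger_mean = -1.0, passenger_sd = 1.5),
    neoParams = list(rate = 0.05, shape1 = 1.2, shape2 = 1.2)) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  groups <- as.data.frame(groups)
  need <- c("cancer_type", "group", "n", "tmb_median", "tmb_min",
            "tmb_max", "n_msi", "n_under_50", "n_female")
  if (!all(need %in% colnames(groups)))
    stop("groups must have columns ", paste(need, collapse = ", "))
  if (any(groups$n < 0)) stop("group sizes must be >= 0")
  with(groups, {
    if (any(tmb_min > tmb_median | tmb_median > tmb_max))
      stop("need tmb_min <= tmb_median <= tmb_max")
    if (any(tmb_min <= 0)) stop("TMB targets must be positive")
  })
  g1 <- groups$group == "G1"
  if (any(groups$tmb_max[g1] >= tmbThreshold))
    stop("infeasible config: G1 TMB distribution reaches the TMB-H ",
         "threshold (", tmbThreshold, ")")
  if (any(groups$tmb_min[!g1] < tmbThreshold))
    stop("infeasible config: TMB-H group with TMB mass below the threshold")
  if (any(groups$n_msi > groups$n) || any(groups$n_under_50 > groups$n) ||
      any(groups$n_female > groups$n))
    stop("subgroup counts cannot exceed group n")
  if (abs(sum(signatureMixture) - 1) > 1e-6)
    stop("signatureMixture must sum to 1")
  if (!"noise" %in% names(signatureMixture))
    stop("signatureMixture must include a 'noise' component")
  if (abs(sum(driverWeights) - 1) > 1e-6)
    stop("driverWeights must sum to 1")
  if (abs(sum(nAdditionalDist) - 1) > 1e-6 ||
      any(as.integer(names(nAdditionalDist)) < 1))
    stop("nAdditionalDist must be a distribution over counts >= 1")
  structure(list(seed = as.integer(seed), groups = groups,
                 driverWeights = driverWeights,
                 signatureMixture = signatureMixture,
                 nAdditionalDist = nAdditionalDist,
                 pSecondDriver = pSecondDriver,
                 tmbThreshold = tmbThreshold,
                 ddgParams = ddgParams, neoParams = neoParams),
            class = "SyntheticCohortConfig")
}

## Median-anchored two-piece log-uniform: half the mass log-uniform on
## [min, median], half on [median, max], so the population median equals
## the target while the range is respected.  Values are rounded to whole
## mut/Mb, as clinically reported.
.rTmb <- function(n, lo, med, hi) {
  lo <- max(lo, 1e-3)
  upper <- stats::runif(n) < 0.5
  x <- ifelse(upper,
              exp(stats::runif(n, log(med), log(hi))),
              exp(stats::runif(n, log(lo), log(med))))
  pmin(pmax(round(x), ceiling(lo)), floor(hi))
}

.sampleChannel <- function(component, sigMatrix) {
  if (component == "noise")
    sample(sbsChannels(), 1L)
  else
    sample(rownames(sigMatrix), 1L, prob = sigMatrix[, component])
}

#' Draw passenger coding changes from a signature mixture
#'
#' Each variant is drawn by (1) choosing a mixture component
#' (a signature or uniform noise) by weight, (2) choosing a 96-channel
#' mutation type from that signature's probability vector (uniformly over
#' all 96 for noise), and (3) choosing uniformly among transcript positions
#' that realize the channel.  Draws producing a synonymous change, a stop
#' codon loss, or a catalog driver allele are rejected and the channel
#' redrawn within the same mixture component, so realized component counts
#' are exactly multinomial in the weights; channels unrealizable on the
#' transcript are resampled with a warning after bounded retries.
#'
#' @param k Number of variants to draw (0 gives an empty result).
#' @param mixture Named weights including a `noise` component, summing
#'   to 1.
#' @param sigMatrix 96 x k signature probability matrix
#'   ([poleSignatureMatrix()]).
#' @param transcript Coding sequence; default [poleTranscript()].
#' @param catalog Driver catalog whose alleles are never emitted as
#'   passengers.
#' @param index Optional precomputed [channelPositionIndex()] of
#'   `transcript`.
#' @param maxRetries Bounded retry count per draw.
#' @return data.frame with columns `raw_label` (derived protein label),
#'   `cdna_pos`, `ref_base`, `alt_base`, `channel`, `component` (the
#'   generating signature or `"noise"` -- the simulation truth).
#' @export
simulateVariantsFromSignature <- function(k, mixture,
                                          sigMatrix = poleSignatureMatrix(),
                                          transcript = poleTranscript(),
                                          catalog = defaultDriverCatalog(),
                                          index = NULL,
                                          maxRetries = 200L) {
  empty <- data.frame(raw_label = character(), cdna_pos = integer(),
                      ref_base = character(), alt_base = character(),
                      channel = character(), component = character(),
                      stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  if (abs(sum(mixture) - 1) > 1e-6) stop("mixture must sum to 1")
  seqc <- as.character(transcript)
  L <- nchar(seqc)
  if (is.null(index)) index <- channelPositionIndex(transcript)
  # keep clear of the initiator and stop codons
  index <- index[index$pos > 3L & index$pos <= L - 3L, ]
  byChannel <- split(index, index$channel)
  e <- driverEntries(catalog)
  driverKeys <- paste0(e$ref_aa, e$position, e$alt_aa)
  code <- Biostrings::GENETIC_CODE

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    # the component is drawn once per variant; rejection retries stay
    # within it, so component counts are exactly multinomial in the
    # mixture weights
    comp <- sample(names(mixture), 1L, prob = mixture)
    for (try in seq_len(maxRetries)) {
      ch <- .sampleChannel(comp, sigMatrix)
      cand <- byChannel[[ch]]
      if (is.null(cand) || !nrow(cand)) {
        warning("channel ", ch, " not realizable on the transcript; ",
                "resampling")
        next
      }
      j <- cand[sample.int(nrow(cand), 1L), ]
      codonIdx <- (j$pos - 1L) %/% 3L + 1L
      off <- (j$pos - 1L) %% 3L + 1L
      codon <- substring(seqc, 3L * codonIdx - 2L, 3L * codonIdx)
      mutCodon <- codon
      substring(mutCodon, off, off) <- j$alt
      refAa <- unname(code[codon])
      altAa <- unname(code[mutCodon])
      if (refAa == "*" || altAa == refAa) next  # synonymous / stop codon
      lab <- paste0(refAa, codonIdx, altAa)
      if (lab %in% driverKeys) next  # never emit a catalog driver allele
      rows[[i]] <- data.frame(raw_label = lab, cdna_pos = j$pos,
                              ref_base = j$ref, alt_base = j$alt,
                              channel = ch, component = comp,
                              stringsAsFactors = FALSE)
      break
    }
    if (is.null(rows[[i]]))
      stop("failed to draw a realizable variant after ", maxRetries,
           " retries")
  }
  do.call(rbind, rows)
}

#' Simulate a POLE-mutated tumor cohort
#'
#' Generates a cohort with the group structure the stratification assumes:
#' G1 tumors get TMB below the threshold and only non-driver variants, G2 a
#' catalog driver and no additional POLE variant, G3 a driver plus one or
#' more signature-drawn passengers, G4 TMB-high with non-driver variants
#' only.  TMB is drawn from a median-anchored log-uniform on each group's
#' target range.  Per-variant generating components, per-tumor true labels,
#' a ddG table for every missense variant and per-tumor neoantigen scores
#' are returned alongside the cohort; the whole draw is reproducible from
#' `config$seed`.
#'
#' @param config A [syntheticCohortConfig()].
#' @param catalog Driver catalog; default [defaultDriverCatalog()].
#' @param sigMatrix Signature matrix; default [poleSignatureMatrix()].
#' @param transcript Coding sequence; default [poleTranscript()].
#' @return List with elements `cohort` ([PoleCohort-class]), `truth`
#'   (list: `groups` data.frame of true labels, `variants` data.frame of
#'   generating components, `mixture` weights used), `ddg` (data.frame
#'   `variant`, `model`, `ddg`, `tumor_id`) and `neoantigens` (data.frame
#'   `tumor_id`, `mhc_binding`, `tcell_reactivity`).
#' @examples
#' cfg <- syntheticCohortConfig(seed = 7)
#' sim <- simulateCohort(cfg)
#' sim$cohort
#' @export
simulateCohort <- function(config,
                           catalog = defaultDriverCatalog(),
                           sigMatrix = poleSignatureMatrix(),
                           transcript = poleTranscript()) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  set.seed(config$seed)
  index <- channelPositionIndex(transcript)
  g <- config$groups
  e <- driverEntries(catalog)
  driverLabs <- paste0(e$ref_aa, e$position, e$alt_aa)
  dw <- config$driverWeights[driverLabs]

  profiles <- list(); variants <- list(); truthV <- list()
  ddg <- list(); neo <- list()
  for (r in seq_len(nrow(g))) {
    gr <- g[r, ]
    if (gr$n == 0) next
    ids <- sprintf("%s_%s_%03d", gr$cancer_type, gr$group, seq_len(gr$n))
    tmb <- .rTmb(gr$n, gr$tmb_min, gr$tmb_median, gr$tmb_max)
    msi <- rep("MSS", gr$n)
    if (gr$n_msi > 0) msi[sample.int(gr$n, gr$n_msi)] <- "MSI-H"
    under50 <- rep(FALSE, gr$n)
    if (gr$n_under_50 > 0) under50[sample.int(gr$n, gr$n_under_50)] <- TRUE
    age <- ifelse(under50, stats::runif(gr$n, 28, 49.99),
                  stats::runif(gr$n, 50, 88))
    sex <- rep("M", gr$n)
    if (gr$n_female > 0) sex[sample.int(gr$n, gr$n_female)] <- "F"
    profiles[[r]] <- data.frame(
      tumor_id = ids, cancer_type = gr$cancer_type, tmb = tmb,
      msi_status = msi, age = round(age), sex = sex,
      stringsAsFactors = FALSE)

    for (i in seq_len(gr$n)) {
      vlist <- list()
      if (gr$group %in% c("G2", "G3")) {
        labs <- sample(driverLabs, 1L, prob = dw)
        if (stats::runif(1) < config$pSecondDriver)
          labs <- c(labs, sample(setdiff(driverLabs, labs), 1L))
        dv <- as.data.frame(parsePoleVariants(labs))
        dv$cdna_pos <- NA_integer_; dv$ref_base <- NA_character_
        dv$alt_base <- NA_character_
        vlist$drivers <- dv
        truthV[[length(truthV) + 1L]] <- data.frame(
          tumor_id = ids[i], raw_label = labs, component = "driver",
          stringsAsFactors = FALSE)
      }
      if (gr$group != "G2") {
        kAdd <- as.integer(sample(names(config$nAdditionalDist), 1L,
                                  prob = config$nAdditionalDist))
        repeat {
          pv <- simulateVariantsFromSignature(
            kAdd, config$signatureMixture, sigMatrix, transcript,
            catalog, index = index)
          if (!anyDuplicated(pv$raw_label)) break
        }
        pp <- as.data.frame(parsePoleVariants(pv$raw_label))
        pp$cdna_pos <- pv$cdna_pos; pp$ref_base <- pv$ref_base
        pp$alt_base <- pv$alt_base
        vlist$passengers <- pp
        truthV[[length(truthV) + 1L]] <- data.frame(
          tumor_id = ids[i], raw_label = pv$raw_label,
          component = pv$component, stringsAsFactors = FALSE)
      }
      vv <- do.call(rbind, vlist)
      vv <- cbind(tumor_id = ids[i], vv, stringsAsFactors = FALSE)
      variants[[length(variants) + 1L]] <- vv

      mis <- vv[vv$kind == "missense", , drop = FALSE]
      if (nrow(mis)) {
        isDrv <- paste0(mis$ref_aa, mis$position, mis$alt_aa) %in%
          driverLabs
        dd <- with(config$ddgParams, ifelse(
          isDrv, stats::rnorm(nrow(mis), driver_mean, driver_sd),
          stats::rnorm(nrow(mis), passenger_mean, passenger_sd)))
        rowsD <- data.frame(tumor_id = ids[i], variant = mis$raw_label,
                            model = "dna_unbound", ddg = round(dd, 2),
                            stringsAsFactors = FALSE)
        ntl <- mis$position <= 1183
        if (any(ntl))
          rowsD <- rbind(rowsD, data.frame(
            tumor_id = ids[i], variant = mis$raw_label[ntl],
            model = "dna_bound",
            ddg = round(dd[ntl] + stats::rnorm(sum(ntl), 0, 0.5), 2),
            stringsAsFactors = FALSE))
        ddg[[length(ddg) + 1L]] <- rowsD
      }
      nPep <- stats::rpois(1L, 1 + config$neoParams$rate * tmb[i])
      if (nPep > 0)
        neo[[length(neo) + 1L]] <- data.frame(
          tumor_id = ids[i],
          mhc_binding = round(stats::rbeta(nPep, config$neoParams$shape1,
                                           config$neoParams$shape2), 3),
          tcell_reactivity = round(stats::rbeta(nPep,
                                                config$neoParams$shape1,
                                                config$neoParams$shape2),
                                   3),
          stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, profiles)
  vars <- do.call(rbind, variants)
  vars <- flagDrivers(S4Vectors::DataFrame(vars), catalog)
  cohort <- PoleCohort(prof, vars)
  truth <- list(
    groups = data.frame(tumor_id = prof$tumor_id,
                        true_group = rep(g$group, g$n)[
                          match(prof$tumor_id, prof$tumor_id)],
                        stringsAsFactors = FALSE),
    variants = do.call(rbind, truthV),
    mixture = config$signatureMixture)
  ## true group per tumor follows directly from the generating row
  truth$groups$true_group <- sub("^.*_(G[1-4])_.*$", "\\1", prof$tumor_id)
  list(cohort = cohort, truth = truth,
       ddg = do.call(rbind, ddg),
       neoantigens = if (length(neo)) do.call(rbind, neo) else
         data.frame(tumor_id = character(), mhc_binding = numeric(),
                    tcell_reactivity = numeric()))
}
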