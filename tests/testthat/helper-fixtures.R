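## Shared fixtures, built once per test run.

catalogFx <- defaultDriverCatalog()
domainMapFx <- defaultDomainMap()
sigMatrixFx <- poleSignatureMatrix()
setsFx <- poleContextSets(sigMatrixFx)
transcriptFx <- poleTranscript()
indexFx <- channelPositionIndex(transcriptFx)

## full default cohort (the study-sized configuration), simulated once
simFx <- simulateCohort(syntheticCohortConfig(seed = 101))

## a reduced, CRC-only configuration for tests that need repeated draws
crcOnlyConfig <- function(seed) {
  g <- defaultGroupTargets()
  syntheticCohortConfig(seed = seed, groups = g[g$cancer_type == "CRC", ])
}

## tiny cohort assembled by hand
makeCohort <- function(tmb, labels, msi = "MSS", cancer = "CRC") {
  n <- length(tmb)
  prof <- data.frame(tumor_id = paste0("T", seq_len(n)),
                     cancer_type = rep_len(cancer, n), tmb = tmb,
                     msi_status = rep_len(msi, n),
                     stringsAsFactors = FALSE)
  vars <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(tumor_id = paste0("T", i),
          as.data.frame(parsePoleVariants(labels[[i]])),
          stringsAsFactors = FALSE)))
  PoleCohort(prof, flagDrivers(S4Vectors::DataFrame(vars), catalogFx))
}

## exact Mann-Whitney p by full enumeration of rank assignments (no ties)
mwEnumerationOracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

## per-channel acceptance rate of the passenger rejection sampler:
## fraction of (position, alt) realizations that are non-synonymous,
## non-stop-loss and not a catalog driver allele (direct enumeration)
channelAcceptanceRates <- function(transcript = transcriptFx,
                                   catalog = catalogFx) {
  seqc <- as.character(transcript)
  L <- nchar(seqc)
  idx <- indexFx[indexFx$pos > 3L & indexFx$pos <= L - 3L, ]
  code <- Biostrings::GENETIC_CODE
  codonIdx <- (idx$pos - 1L) %/% 3L + 1L
  off <- (idx$pos - 1L) %% 3L + 1L
  codon <- substring(seqc, 3L * codonIdx - 2L, 3L * codonIdx)
  mut <- codon
  substring(mut, off, off) <- idx$alt
  refAa <- unname(code[codon]); altAa <- unname(code[mut])
  e <- driverEntries(catalog)
  keys <- paste0(e$ref_aa, e$position, e$alt_aa)
  lab <- paste0(refAa, codonIdx, altAa)
  accept <- refAa != "*" & altAa != refAa & !(lab %in% keys)
  tapply(accept, idx$channel, mean)
}
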