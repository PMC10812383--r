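test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- crcOnlyConfig(seed = 404)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(as.data.frame(tumorProfiles(s1$cohort)),
                   as.data.frame(tumorProfiles(s2$cohort)))
  expect_identical(as.data.frame(poleVariants(s1$cohort)),
                   as.data.frame(poleVariants(s2$cohort)))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$ddg, s2$ddg)
  # a different seed gives a different draw
  s3 <- simulateCohort(crcOnlyConfig(seed = 405))
  expect_false(identical(as.data.frame(tumorProfiles(s1$cohort)),
                         as.data.frame(tumorProfiles(s3$cohort))))
})

test_that("group assignment recovers the generating labels exactly", {
  a <- assignGroups(simFx$cohort, catalogFx)
  truth <- simFx$truth$groups
  expect_equal(a$group[match(truth$tumor_id, a$tumor_id)],
               truth$true_group)
})

test_that("the generator respects the group taxonomy by construction", {
  v <- as.data.frame(poleVariants(simFx$cohort))
  p <- as.data.frame(tumorProfiles(simFx$cohort))
  truth <- simFx$truth$groups
  nd <- tapply(v$is_exod_driver, v$tumor_id, sum)
  na <- tapply(!v$is_exod_driver, v$tumor_id, sum)
  for (g in paste0("G", 1:4)) {
    ids <- truth$tumor_id[truth$true_group == g]
    tmb <- p$tmb[match(ids, p$tumor_id)]
    if (g == "G1") expect_true(all(tmb < 10))
    else expect_true(all(tmb >= 10))
    if (g %in% c("G2", "G3")) expect_true(all(nd[ids] >= 1))
    else expect_true(all(nd[ids] == 0))
    if (g == "G2") expect_true(all(na[ids] == 0))
    if (g %in% c("G3")) expect_true(all(na[ids] >= 1))
  }
})

test_that("infeasible configurations are rejected up front", {
  g <- defaultGroupTargets()
  g$tmb_max[g$group == "G1"] <- 12
  expect_error(syntheticCohortConfig(groups = g), "infeasible")
  g2 <- defaultGroupTargets()
  g2$tmb_min[g2$group == "G4"] <- 5
  expect_error(syntheticCohortConfig(groups = g2), "infeasible")
  expect_error(syntheticCohortConfig(
    signatureMixture = c(SBS10b = 0.5, noise = 0.4)), "sum to 1")
})

test_that("per-channel passenger distribution matches the mixture oracle", {
  # draws are rejection-sampled (synonymous / stop / driver redraws), so
  # the expected channel law is the mixture re-weighted by the per-channel
  # acceptance rates enumerated directly from the transcript
  k <- 5000
  mix <- c(SBS10b = 0.8, noise = 0.2)
  set.seed(77)
  pv <- simulateVariantsFromSignature(k, mix, sigMatrixFx, transcriptFx,
                                      catalogFx, index = indexFx)
  expect_equal(nrow(pv), k)
  acc <- channelAcceptanceRates()
  chans <- sbsChannels()
  # per-component channel law after rejection, mixed by the exact weights
  norm1 <- function(x) x / sum(x)
  pExp <- 0.8 * norm1(sigMatrixFx[chans, "SBS10b"] * acc[chans]) +
    0.2 * norm1(rep(1 / 96, 96) * acc[chans])
  obs <- table(factor(pv$channel, levels = chans))
  keep <- pExp * k >= 5      # chi-square validity
  chi <- sum((as.vector(obs)[keep] - k * pExp[keep])^2 /
             (k * pExp[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  # component frequencies recover the weights within 3 binomial SE
  fNoise <- mean(pv$component == "noise")
  expect_lt(abs(fNoise - 0.2), 3 * sqrt(0.2 * 0.8 / k))
})

test_that("pure-signature draws land in their context set at coverage rate",
{
  k <- 1000
  set.seed(91)
  pv <- simulateVariantsFromSignature(k, c(SBS10b = 1, noise = 0),
                                      sigMatrixFx, transcriptFx,
                                      catalogFx, index = indexFx)
  inSet <- pv$channel %in% includedChannels(setsFx$SBS10b)
  # expectation: included-mass re-weighted by acceptance rates
  acc <- channelAcceptanceRates()
  chans <- sbsChannels()
  pCh <- sigMatrixFx[chans, "SBS10b"] * acc[chans]
  pCh <- pCh / sum(pCh)
  pIn <- sum(pCh[includedChannels(setsFx$SBS10b)])
  expect_lt(abs(mean(inSet) - pIn), 3 * sqrt(pIn * (1 - pIn) / k))
  expect_gt(mean(inSet), 0.85)   # close to the set's 88.5% coverage
})

test_that("k = 0 yields an empty draw and labels stay self-consistent", {
  pv0 <- simulateVariantsFromSignature(0, c(SBS10b = 1, noise = 0),
                                       sigMatrixFx, transcriptFx,
                                       catalogFx, index = indexFx)
  expect_equal(nrow(pv0), 0L)
  set.seed(2)
  pv <- simulateVariantsFromSignature(200, c(SBS10a = 0.5, noise = 0.5),
                                      sigMatrixFx, transcriptFx,
                                      catalogFx, index = indexFx)
  # emitted protein labels re-derive from the emitted coding change
  code <- Biostrings::GENETIC_CODE
  seqc <- as.character(transcriptFx)
  for (i in sample.int(nrow(pv), 20)) {
    ci <- (pv$cdna_pos[i] - 1) %/% 3 + 1
    codon <- substr(seqc, 3 * ci - 2, 3 * ci)
    expect_equal(substr(codon, (pv$cdna_pos[i] - 1) %% 3 + 1,
                        (pv$cdna_pos[i] - 1) %% 3 + 1), pv$ref_base[i])
    expect_true(startsWith(pv$raw_label[i],
                           paste0(unname(code[codon]), ci)))
  }
  # no passenger is ever a catalog driver allele
  e <- as.data.frame(driverEntries(catalogFx))
  expect_false(any(pv$raw_label %in%
                     paste0(e$ref_aa, e$position, e$alt_aa)))
})
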