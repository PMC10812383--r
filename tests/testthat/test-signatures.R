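test_that("pyrimidine normalization maps both strands to one channel", {
  expect_equal(normalizeToPyrimidine("T", "C", "A", "T"), "T[C>A]T")
  expect_equal(normalizeToPyrimidine("C", "G", "A", "A"), "T[C>T]G")
  expect_equal(normalizeToPyrimidine("T", "T", "G", "T"), "T[T>G]T")
  expect_error(normalizeToPyrimidine("T", "N", "A", "T"), "non-ACGT")
  expect_error(normalizeToPyrimidine("T", "C", "C", "T"), "differ")
})

test_that("normalization is idempotent and reverse-complement invariant", {
  set.seed(42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:200) {
    b <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    if (b[3] == b[2]) next
    ch <- normalizeToPyrimidine(b[1], b[2], b[3], b[4])
    # idempotent on the already-normalized parts
    p <- regmatches(ch, regexec(
      "^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", ch))[[1]][2:5]
    expect_equal(normalizeToPyrimidine(p[1], p[2], p[3], p[4]), ch)
    # reverse complement of the context yields the identical channel
    expect_equal(normalizeToPyrimidine(comp[b[4]], comp[b[2]], comp[b[3]],
                                       comp[b[1]]), ch)
  }
})

test_that("channelOf reads flanks off the transcript and checks the ref", {
  expect_equal(channelOf(2, "C", "A", "TCT"), "T[C>A]T")
  expect_equal(channelOf(2, "C", "T", "TCG"), "T[C>T]G")
  expect_error(channelOf(2, "G", "A", "TCT"), "mismatch.*position 2")
  expect_error(channelOf(1, "T", "A", "TCT"), "edge")
  expect_error(channelOf(3, "T", "A", "TCT"), "edge")
})

test_that("the >1% rule includes, covers and attaches hotspots", {
  chans <- sbsChannels()
  uni <- stats::setNames(rep(1 / 96, 96), chans)
  s <- buildContextSet(uni, "SBS10a")
  expect_equal(length(includedChannels(s)), 96L)   # 1/96 > 1%
  expect_equal(coverage(s), 1.0)
  spike <- stats::setNames(rep(0.005 / 95, 96), chans)
  spike["T[C>T]G"] <- 0.995
  s2 <- buildContextSet(spike, "SBS10b")
  expect_equal(includedChannels(s2), "T[C>T]G")
  expect_equal(coverage(s2), 0.995)
  expect_equal(primaryChannels(s2), "T[C>T]G")
  expect_error(buildContextSet(uni, "SBS10a", inclusionThreshold = 1.5),
               "lie in")
})

test_that("context sets match brute-force enumeration over all 96 channels",
{
  set.seed(7)
  chans <- sbsChannels()
  vectors <- c(lapply(1:10, function(i) {
    x <- stats::rexp(96)^2
    stats::setNames(x / sum(x), chans)
  }), lapply(colnames(sigMatrixFx), function(id) sigMatrixFx[, id]))
  for (p in vectors) {
    # random vectors may drop hotspots below threshold (warned); the
    # inclusion/coverage contract is what is under test here
    s <- suppressWarnings(buildContextSet(p, "SBS14"))
    # oracle: check each channel one by one
    inc <- character(); cov <- 0
    for (ch in chans) if (p[[ch]] > 0.01) {
      inc <- c(inc, ch); cov <- cov + p[[ch]]
    }
    expect_setequal(includedChannels(s), inc)
    expect_equal(coverage(s), cov)
  }
})

test_that("coverage is monotone non-increasing in the threshold", {
  p <- sigMatrixFx[, "SBS10a"]
  covs <- vapply(c(0.001, 0.005, 0.01, 0.02, 0.05, 0.2),
                 function(t) coverage(
                   suppressWarnings(buildContextSet(p, "SBS10a", t))),
                 numeric(1))
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("bundled proofreading sets carry their described hotspots", {
  expect_equal(primaryChannels(setsFx$SBS10a), "T[C>A]T")
  expect_equal(primaryChannels(setsFx$SBS10b), "T[C>T]G")
  expect_setequal(primaryChannels(setsFx$SBS14),
                  c("A[C>A]T", "C[C>A]T", "G[C>A]T", "T[C>A]T"))
  expect_equal(primaryChannels(setsFx$SBS28), "T[T>G]T")
})

test_that("variant context calls resolve channels and signature matches", {
  # pick transcript positions realizing the channels of interest
  pick <- function(ch) indexFx[indexFx$channel == ch, ][1, ]
  tcg <- pick("T[C>T]G"); gcg <- pick("G[C>T]G")
  v <- S4Vectors::DataFrame(
    raw_label = c("hot10b", "minor", "T457fs"),
    kind = c("missense", "missense", "frameshift"),
    cdna_pos = c(tcg$pos, gcg$pos, NA),
    ref_base = c(tcg$ref, gcg$ref, NA),
    alt_base = c(tcg$alt, gcg$alt, NA))
  calls <- as.data.frame(classifyVariantContext(v, setsFx, transcriptFx))
  expect_equal(calls$channel, c("T[C>T]G", "G[C>T]G", NA))
  expect_equal(calls$hotspot_hit[1], "SBS10b")
  # G[C>T]G is a minor channel of both SBS10a and SBS10b, hotspot of none
  expect_equal(calls$matching_signatures[2], "SBS10a,SBS10b")
  expect_equal(calls$hotspot_hit[2], "")
  expect_false(calls$in_pole_context[3])
  expect_true(all(calls$in_pole_context[1:2]))
})

test_that("fractions use the SNV denominator and report both conventions", {
  v <- S4Vectors::DataFrame(
    raw_label = c("a", "b", "fs"),
    kind = c("missense", "missense", "frameshift"),
    cdna_pos = c(indexFx$pos[indexFx$channel == "T[C>T]G"][1],
                 indexFx$pos[indexFx$channel == "T[C>G]T"][1], NA),
    ref_base = c("C", indexFx$ref[indexFx$channel == "T[C>G]T"][1], NA),
    alt_base = c("T", indexFx$alt[indexFx$channel == "T[C>G]T"][1], NA))
  v$ref_base[1] <- indexFx$ref[indexFx$channel == "T[C>T]G"][1]
  v$alt_base[1] <- indexFx$alt[indexFx$channel == "T[C>T]G"][1]
  f <- fractionInContext(classifyVariantContext(v, setsFx, transcriptFx))
  # T[C>G]T is in no proofreading set; frameshift excluded from the
  # SNV denominator
  expect_equal(f$fraction, 1 / 2)
  expect_equal(f$fraction_all_variants, 1 / 3)
  expect_equal(f$n_with_channel, 2L)
  expect_equal(f$n_total, 3L)
  # degenerate denominator flagged, not invented
  fs <- v[3, , drop = FALSE]
  f0 <- fractionInContext(classifyVariantContext(fs, setsFx, transcriptFx))
  expect_true(f0$undefined)
  expect_true(is.na(f0$fraction))
})

test_that("signature table reader validates shape and normalization", {
  tmp <- tempfile(fileext = ".tsv")
  d <- data.frame(Type = sbsChannels(), S1 = rep(1 / 96, 96),
                  check.names = FALSE)
  utils::write.table(d, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- readSignatureMatrix(tmp)
  expect_equal(dim(m), c(96L, 1L))
  d$S1[1] <- 2
  utils::write.table(d, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readSignatureMatrix(tmp), "sum to 1")
  utils::write.table(d[-1, ], tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(readSignatureMatrix(tmp), "96")
})
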