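test_that("stability classes use inclusive +/-1.45 boundaries", {
  expect_equal(classifyStability(c(4.2, 1.45, 1.44, 0, -1.44, -1.45, -3)),
               c("destabilizing", "destabilizing", "neutral", "neutral",
                 "neutral", "stabilizing", "stabilizing"))
  expect_error(classifyStability(c(1, NA)), "finite")
  expect_error(classifyStability(Inf), "finite")
})

test_that("stability classification mirrors under sign flip", {
  set.seed(3)
  x <- c(stats::rnorm(200, 0, 2), 1.45, -1.45, 0)
  cls <- classifyStability(x)
  neg <- classifyStability(-x)
  swap <- c(stabilizing = "destabilizing", neutral = "neutral",
            destabilizing = "stabilizing")
  expect_equal(neg, unname(swap[cls]))
})

test_that("neoantigen categories partition the unit square inclusively", {
  expect_equal(categorizeNeoantigen(0.7, 0.6), "immunogenic")
  expect_equal(categorizeNeoantigen(0.7, 0.3), "nonimmunogenic")
  expect_equal(categorizeNeoantigen(0.3, 0.7), "no_biological_significance")
  expect_equal(categorizeNeoantigen(0.3, 0.2), "none")
  expect_equal(categorizeNeoantigen(0.5, 0.5), "immunogenic")  # inclusive
  grid <- expand.grid(mhc = seq(0, 1, by = 0.05),
                      tcr = seq(0, 1, by = 0.05))
  cats <- categorizeNeoantigen(grid$mhc, grid$tcr)
  expect_true(all(cats %in% c("immunogenic", "nonimmunogenic",
                              "no_biological_significance", "none")))
  # exactly one category per point, consistent with the two indicators
  expect_equal(cats == "immunogenic", grid$mhc >= 0.5 & grid$tcr >= 0.5)
  expect_equal(cats == "none", grid$mhc < 0.5 & grid$tcr < 0.5)
  expect_error(categorizeNeoantigen(1.2, 0.5), "\\[0, 1\\]")
})

test_that("neoantigen burden counts immunogenic peptides per tumor", {
  sc <- data.frame(tumor_id = rep("T1", 4),
                   mhc_binding = c(0.7, 0.7, 0.3, 0.3),
                   tcell_reactivity = c(0.6, 0.3, 0.7, 0.2))
  expect_equal(neoantigenBurden(sc)$neoantigen_burden, 1L)
  expect_equal(nrow(neoantigenBurden(sc[0, ])), 0L)
  set.seed(11)
  sc2 <- data.frame(tumor_id = sample(c("a", "b"), 50, TRUE),
                    mhc_binding = round(stats::runif(50), 2),
                    tcell_reactivity = round(stats::runif(50), 2))
  got <- neoantigenBurden(sc2)
  for (id in c("a", "b")) {   # brute-force filter oracle
    s <- sc2[sc2$tumor_id == id, ]
    expect_equal(got$neoantigen_burden[got$tumor_id == id],
                 sum(s$mhc_binding >= 0.5 & s$tcell_reactivity >= 0.5))
  }
})

test_that("Group-3-exclusive selection applies the <=1 / >=2 rule", {
  expect_equal(selectGroup3Exclusive(c(KRAS_A146T = 1),
                                     c(KRAS_A146T = 2)), "KRAS_A146T")
  expect_equal(selectGroup3Exclusive(c(x = 2), c(x = 5)), character())
  expect_equal(selectGroup3Exclusive(c(x = 0), c(x = 1)), character())
  expect_equal(selectGroup3Exclusive(c(), c(y = 2, z = 1)), "y")
  expect_error(selectGroup3Exclusive(c(x = -1), c(x = 2)), "non-negative")
})

test_that("exclusivity is anti-monotone in G2 and monotone in G3 counts", {
  set.seed(8)
  keys <- paste0("m", 1:30)
  g2 <- stats::setNames(stats::rpois(30, 1), keys)
  g3 <- stats::setNames(stats::rpois(30, 2), keys)
  sel <- selectGroup3Exclusive(g2, g3)
  selLowerG2 <- selectGroup3Exclusive(pmax(g2 - 1, 0), g3)
  selHigherG3 <- selectGroup3Exclusive(g2, g3 + 1)
  expect_true(all(sel %in% selLowerG2))
  expect_true(all(sel %in% selHigherG3))
})

test_that("stability census tabulates lobe x class x model", {
  rec <- data.frame(
    variant = c("P286R", "A300V", "E1376D", "R1386W", "S461P"),
    model = c("dna_unbound", "dna_bound", "dna_unbound", "dna_unbound",
              "dna_unbound"),
    ddg = c(4.2, -2.0, 0.3, 1.45, -1.45))
  out <- stabilityCensus(rec, domainMapFx)
  cs <- out$census
  expect_equal(sum(cs), nrow(rec))  # conservation
  expect_equal(cs[["NTL", "destabilizing", "dna_unbound"]], 1L)
  expect_equal(cs[["NTL", "stabilizing", "dna_unbound"]], 1L)
  expect_equal(cs[["NTL", "stabilizing", "dna_bound"]], 1L)
  expect_equal(cs[["CTL", "neutral", "dna_unbound"]], 1L)
  expect_equal(cs[["CTL", "destabilizing", "dna_unbound"]], 1L)
  # boundary residues split by the lobe map at 1,183/1,184
  b <- stabilityCensus(data.frame(
    variant = c("A1183V", "A1184V"), model = "dna_unbound",
    ddg = c(2, 2)), domainMapFx)
  expect_equal(b$records$lobe, c("NTL", "CTL"))
  # DNA-bound values only exist for the N-terminal half
  expect_error(stabilityCensus(data.frame(
    variant = "E1376D", model = "dna_bound", ddg = 1), domainMapFx),
    "dna_bound.*CTL")
  expect_error(stabilityCensus(data.frame(
    variant = "R1125X", model = "dna_unbound", ddg = 1), domainMapFx),
    "missense")
})
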