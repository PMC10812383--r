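test_that("protein labels parse to the right kind and coordinates", {
  v <- as.data.frame(parsePoleVariants(c(
    "P286R", "R1125X", "F285_P286delinsLR", "T457fs", "L500Pfs*12",
    "A100del", "A100_C102del", "A100_C101insS", "G120dup", "p.S297y",
    "Q1475*", "c.100 splice")))
  expect_equal(v$kind[1], "missense")
  expect_equal(v[1, c("ref_aa", "position", "alt_aa")],
               data.frame(ref_aa = "P", position = 286L, alt_aa = "R",
                          row.names = 1L))
  expect_equal(v$kind[2], "nonsense")
  expect_equal(v$alt_aa[2], "*")  # X normalized to *
  expect_equal(v$kind[3], "delins")
  expect_equal(v$position[3], 285L)
  expect_equal(v$end_position[3], 286L)
  expect_equal(v$inserted[3], "LR")
  expect_equal(v$kind[4:5], c("frameshift", "frameshift"))
  expect_equal(v$kind[6:9], c("inframe_deletion", "inframe_deletion",
                              "inframe_insertion", "duplication"))
  # case-insensitive with optional p. prefix, normalized to upper case
  expect_equal(v[10, c("ref_aa", "alt_aa", "kind")],
               data.frame(ref_aa = "S", alt_aa = "Y", kind = "missense",
                          row.names = 10L))
  expect_equal(v$kind[11], "nonsense")
  expect_equal(v$kind[12], "splice")
})

test_that("malformed labels are rejected by name", {
  expect_error(parsePoleVariants("Q99"), "Q99")
  expect_error(parsePoleVariants("P0R"), "position")
  expect_error(parsePoleVariants(""), "non-empty")
  expect_error(parsePoleVariants("B123C"), "non-standard")
  expect_error(parsePoleVariants("P286_F285delinsLR"), "interval")
})

test_that("parsing is idempotent through formatPoleVariant", {
  labels <- c("P286R", "R1125X", "F285_P286delinsLR", "T457fs",
              "A100del", "A100_C101insS", "G120dup", "S459del",
              "N423_L424delinsKI", "Y1889X")
  v1 <- as.data.frame(parsePoleVariants(labels))
  v2 <- as.data.frame(parsePoleVariants(formatPoleVariant(v1)))
  cols <- setdiff(colnames(v1), "raw_label")
  expect_equal(v1[cols], v2[cols])
})

test_that("driver shorthand expands allele by allele", {
  expect_equal(length(expandDriverCatalog("S297F/Y")), 2L)
  expect_equal(length(expandDriverCatalog("F367C/L/V")), 3L)
  e <- driverEntries(expandDriverCatalog("S297F/Y"))
  expect_setequal(paste0(e$ref_aa, e$position, e$alt_aa),
                  c("S297F", "S297Y"))
  expect_error(expandDriverCatalog(c("P286R", "P286R")), "duplicate")
  expect_error(expandDriverCatalog("286R"), "shorthand")
})

test_that("domain annotation resolves innermost interval and lobe", {
  v <- annotateDomains(parsePoleVariants(
    c("P286R", "R680C", "E1376D", "R1125X", "S1930X")), domainMapFx)
  expect_equal(v$domain, c("ExoD", "Palm", "CTD", "Thumb", "CTD"))
  expect_equal(v$lobe, c("NTL", "NTL", "CTL", "NTL", "CTL"))
  expect_error(annotateDomains(parsePoleVariants("A3000V"), domainMapFx),
               "beyond protein length")
})

test_that("lobe assignment is total over all residues", {
  # every residue position belongs to exactly one lobe
  probe <- data.frame(raw_label = "x", ref_aa = "A",
                      position = c(1L, 267L, 268L, 471L, 472L, 1183L,
                                   1184L, 2286L),
                      end_ref_aa = "A", end_position = 1L,
                      alt_aa = "V", inserted = NA, kind = "missense")
  ann <- annotateDomains(S4Vectors::DataFrame(probe), domainMapFx)
  expect_false(any(is.na(ann$lobe)))
  expect_equal(ann$lobe, c(rep("NTL", 6), "CTL", "CTL"))
  # dense sweep
  pos <- seq(1L, proteinLength(domainMapFx), by = 37L)
  sweep <- probe[rep(1, length(pos)), ]
  sweep$position <- pos
  expect_false(any(is.na(
    annotateDomains(S4Vectors::DataFrame(sweep), domainMapFx)$lobe)))
})

test_that("driver flagging is exact-allele", {
  v <- flagDrivers(parsePoleVariants(
    c("V411L", "M444I", "A252V", "F285_P286delinsLR", "P286R",
      "P286X")), catalogFx)
  expect_equal(v$is_exod_driver,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("every expanded catalog allele round-trips to driver = TRUE and
           perturbed alleles do not", {
  e <- as.data.frame(driverEntries(catalogFx))
  labs <- paste0(e$ref_aa, e$position, e$alt_aa)
  v <- flagDrivers(parsePoleVariants(labs), catalogFx)
  expect_true(all(v$is_exod_driver))
  # perturb each alternate to a different residue
  swap <- ifelse(e$alt_aa == "G", "W", "G")
  pert <- paste0(e$ref_aa, e$position, swap)
  keys <- paste0(e$ref_aa, e$position, e$alt_aa)
  pert <- pert[!paste0(e$ref_aa, e$position, swap) %in% keys]
  v2 <- flagDrivers(parsePoleVariants(pert), catalogFx)
  expect_false(any(v2$is_exod_driver))
})

test_that("domain map validity catches broken maps", {
  iv <- data.frame(name = c("NTL", "CTL"), start = c(1, 1100),
                   end = c(1183, 2286), tier = "lobe")
  expect_error(DomainMap(iv, 2286), "overlap|exactly once")
  iv2 <- data.frame(name = "NTL", start = 1, end = 2286, tier = "lobe")
  expect_error(DomainMap(iv2, 2286), "NTL and CTL")
})
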