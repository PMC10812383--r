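## Generates the plain-text fixtures under inst/extdata/.
## Run from the repository root:  Rscript data-raw/make_fixtures.R
## The signature table and transcript are SYNTHETIC stand-ins (see the
## methods vignette): the signature vectors are built to the documented
## hotspot/minor-channel structure with >1% channels capturing 88.5% of
## mass; the transcript is a random sense-codon CDS with the residues
## quoted in the analyses fixed to their reference amino acids.

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## ---- driver catalog -------------------------------------------------
writeLines(paste0(
  '{"drivers": ["D275G", "P286R", "S297F/Y", "F367C/L/V", "V411L", ',
  '"L424F", "P436R/S/Y", "M444K/L", "A456P", "S459F/Y", "S461L/P", ',
  '"A465V"]}'), "inst/extdata/pole_exod_drivers.json")

## ---- domain map -----------------------------------------------------
dm <- list(
  protein_length = 2286L,
  intervals = data.frame(
    name = c("NTL", "CTL",
             "N-terminal", "ExoD", "Polymerase", "Linker", "CTD",
             "Palm", "Fingers", "Thumb"),
    start = c(1, 1184, 1, 268, 472, 1184, 1309, 612, 911, 1041),
    end   = c(1183, 2286, 267, 471, 1183, 1308, 2286, 910, 1040, 1183),
    tier  = c("lobe", "lobe", rep("domain", 5), rep("subdomain", 3))))
writeLines(jsonlite::toJSON(dm, pretty = TRUE, auto_unbox = TRUE),
           "inst/extdata/pole_domain_map.json")

## ---- synthetic POLE signature table ---------------------------------
subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
bases <- c("A", "C", "G", "T")
channels <- unlist(lapply(subs, function(s)
  as.vector(t(outer(bases, bases, function(f, t)
    paste0(f, "[", s, "]", t))))))
stopifnot(length(channels) == 96)

mkSig <- function(major) {       # named vector of >1% channels, sum 0.885
  stopifnot(abs(sum(major) - 0.885) < 1e-12, all(major > 0.01))
  v <- setNames(rep(0.115 / (96 - length(major)), 96), channels)
  stopifnot(all(v < 0.01))
  v[names(major)] <- major
  stopifnot(abs(sum(v) - 1) < 1e-12)
  v
}

sig <- cbind(
  SBS10a = mkSig(c("T[C>A]T" = 0.40, "A[C>A]T" = 0.09, "C[C>A]T" = 0.08,
                   "G[C>A]T" = 0.07, "T[C>A]A" = 0.05, "T[C>A]C" = 0.05,
                   "T[C>A]G" = 0.04, "T[C>T]T" = 0.05, "A[C>T]T" = 0.035,
                   "G[C>T]G" = 0.02)),
  SBS10b = mkSig(c("T[C>T]G" = 0.55, "G[C>T]G" = 0.08, "A[C>T]G" = 0.07,
                   "C[C>T]G" = 0.06, "T[C>T]T" = 0.05, "T[C>T]A" = 0.04,
                   "T[C>T]C" = 0.035)),
  SBS14 = mkSig(c("T[C>A]T" = 0.20, "A[C>A]T" = 0.15, "C[C>A]T" = 0.15,
                  "G[C>A]T" = 0.12, "C[C>T]G" = 0.06, "T[C>A]C" = 0.05,
                  "T[C>A]A" = 0.05, "A[C>A]A" = 0.04, "C[C>A]C" = 0.04,
                  "G[C>A]G" = 0.025)),
  SBS28 = mkSig(c("T[T>G]T" = 0.50, "T[T>G]G" = 0.10, "C[T>G]T" = 0.08,
                  "A[T>G]T" = 0.07, "G[T>G]T" = 0.06, "T[T>G]C" = 0.045,
                  "T[T>G]A" = 0.03)))
write.table(data.frame(Type = channels, sig, check.names = FALSE),
            "inst/extdata/sbs_pole_signatures_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- synthetic POLE coding sequence ---------------------------------
set.seed(20240126)
code <- Biostrings::GENETIC_CODE
sense <- names(code)[code != "*"]
nRes <- 2286L
codons <- sample(sense, nRes, replace = TRUE)
codons[1] <- "ATG"
## canonical codon per amino acid used to pin quoted residues
aaCodon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
             Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
             L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
             S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
pins <- c(D275 = "D", F285 = "F", P286 = "P", M295 = "M", S297 = "S",
          F320 = "F", F367 = "F", V411 = "V", N423 = "N", L424 = "L",
          P436 = "P", M444 = "M", A456 = "A", S459 = "S", S461 = "S",
          A465 = "A", A252 = "A", R680 = "R", R1125 = "R", E1376 = "E",
          R1386 = "R", Q1475 = "Q", P1547 = "P", Y1889 = "Y",
          S1930 = "S")
for (nm in names(pins)) {
  pos <- as.integer(sub("^[A-Z]", "", nm))
  codons[pos] <- aaCodon[[pins[[nm]]]]
}
cds <- paste0(paste(codons, collapse = ""), "TAA")
stopifnot(nchar(cds) == 3L * nRes + 3L)
## every trinucleotide context must occur away from the terminal codons
inner <- substr(cds, 4L, nchar(cds) - 3L)
tri <- substring(inner, 1:(nchar(inner) - 2), 3:nchar(inner))
stopifnot(length(unique(tri)) == 64L)
writeLines(c(">POLE_CDS_synthetic length=6861 note=synthetic stand-in",
             gsub("(.{60})", "\\1\n", cds, perl = TRUE)),
           "inst/extdata/pole_cds_synthetic.fa")
cat("fixtures written\n")
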