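---
title: "Stratifying POLE-mutated tumors and attributing co-occurring variants to proofreading signature contexts"
author: "poleSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying POLE-mutated tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poleSig)
```

## The scientific problem

The catalytic subunit of DNA polymerase epsilon (POLE) proofreads
replication errors through its exonuclease domain (ExoD). A small set of
recurrent somatic ExoD missense mutations -- P286R and V411L above all --
abolish proofreading and drive hypermutation: tumors carrying them are
typically hypermutated (10--100 mut/Mb) or ultra-hypermutated
(>100 mut/Mb). Many POLE-mutated tumors, however, carry *additional* POLE
variants of uncertain significance alongside the driver, and tumors with
such co-occurring variants reach substantially higher tumor mutational
burden (TMB) than tumors with the driver alone.

`poleSig` implements that analysis as a reusable pipeline:

1. **Variant model** -- parse short-form protein labels (`P286R`,
   `R1125X`, `F285_P286delinsLR`, `T457fs`), annotate them against a
   tiered domain map of the 2,286-residue protein, and flag exact-allele
   matches against the curated catalog of 20 ExoD driver alleles
   (D275G, P286R, S297F/Y, F367C/L/V, V411L, L424F, P436R/S/Y, M444K/L,
   A456P, S459F/Y, S461L/P, A465V).
2. **Stratification** -- assign each tumor to one of four groups:
   * **G1** TMB-low (< 10 mut/Mb) with POLE variant(s);
   * **G2** TMB-high with an ExoD driver only;
   * **G3** TMB-high with an ExoD driver *plus* additional POLE
     variant(s);
   * **G4** TMB-high with POLE variant(s) but no driver.
3. **Signature context** -- type each coding substitution into the 96
   pyrimidine-normalized trinucleotide channels, build context sets for
   the proofreading signatures SBS10a/10b/14/28 by the >1% channel rule,
   and measure what fraction of the additional variants in G3 tumors fall
   inside proofreading contexts (the evidence that they are secondary to
   the proofreading defect).
4. **Rule-based annotation** -- ddG stability classes at the
   ±1.45 kcal/mol cutoff, neoantigen categories at the dual 0.5
   threshold, and the "effectively exclusive to G3" mutation filter
   (at most once in G2, at least twice in G3).
5. **Statistics** -- Mann--Whitney comparisons (exact for small untied
   samples, refused below three datapoints), Benjamini--Hochberg FDR,
   Spearman correlation, midpoint medians with ranges.
6. **Synthetic cohorts** -- a seeded generator producing cohorts with the
   group structure, TMB distributions and signature-mixture composition
   the analysis assumes, so every stage runs and is testable without
   access to protected patient data.

## Group assignment: model and conventions

A tumor enters the cohort only if it carries at least one POLE variant.
Assignment uses two axes: clinically reported TMB against the
KEYNOTE-158-derived cutoff (10 mut/Mb, the boundary value counted as
TMB-high) and the presence of a catalog driver among the parsed variants.
Driver matching is exact-allele: M444I is not a driver (the catalog holds
M444K/L), and a delins spanning a driver residue is not a driver. Group
membership keys on driver *presence*, not count -- the occasional tumor
with two catalog drivers is G2 unless a non-driver variant co-occurs.
Two deliberate edge conventions:

* a TMB-low profile that carries a driver stays in G1 but is flagged
  `driver_with_low_tmb`, since it contradicts the expectation that
  drivers induce hypermutation and deserves manual review;
* MSI vocabulary is dichotomized: MSI-low collapses into MSS, and an
  unrecognized status is treated as MSS for the substatus (with a
  warning), matching the MSS/MSI two-column reporting of group tables.

Splice annotations within ±2 nucleotides of exon boundaries are counted
as POLE variants for grouping; they simply resolve to no trinucleotide
channel downstream.

## The 96-channel context model

A single-base substitution is typed by its reference base, alternate
base, and the 5' and 3' flanking bases, with purine-reference
observations reverse-complemented so the reference is always a pyrimidine
(`T[C>A]T` etc.); a context and its reverse complement map to the same
channel, so coding-strand and genome-strand observations agree.  Each
proofreading signature has a described hotspot -- SBS10a: C>A at TCT;
SBS10b: C>T at TCG; SBS14: C>A at NCT for any N; SBS28: T>G at TTT --
and beyond the hotspot every channel holding more than 1% of the
signature's mass is counted as part of its context set, which captures
88--90% of each signature.  A variant is "in a POLE context" when its
channel belongs to any of the four sets; multi-set matches count once in
the fraction and are reported per signature in the breakdown.

Because published percentages do not state whether non-SNV variants
(frameshifts, delins) were inside the denominator, `fractionInContext()`
computes both conventions and records which is which; the headline
`fraction` uses SNV-resolvable variants only.

```{r context}
sets <- poleContextSets()
sapply(sets, coverage)
```

## Bundled reference fixtures are synthetic

Two fixtures ship with the package, both **synthetic stand-ins**
constructed in `data-raw/make_fixtures.R`:

* `sbs_pole_signatures_synthetic.tsv` -- a 96 x 4 probability table with
  the documented qualitative structure of SBS10a/10b/14/28: the hotspot
  channels dominant, the literature-noted minor channels present
  (`G[C>T]G` shared by SBS10a/10b, `C[C>T]G` in SBS14), and a flat
  sub-threshold tail sized so the >1% channels capture 88.5% of each
  signature.  It is *not* a COSMIC release; channel probabilities of a
  real release differ, and context fractions are sensitive to them, so
  the signature table is a configuration input
  (`readSignatureMatrix()`) and its source is recorded in the run
  manifest.
* `pole_cds_synthetic.fa` -- a random sense-codon coding sequence of
  2,286 codons with the residues quoted in the analyses (all 20 driver
  residues, R680, R1125, the CTD positions, ...) pinned to their
  reference amino acids.  Channel *availability* is realistic (every
  trinucleotide occurs ~100 times) but position-specific context does
  not match the real gene; substitute the real coding sequence via
  `readTranscript()` for position-faithful work.

Consequently, passing tests certify the machinery -- parsing,
set construction, strand normalization, fraction computation -- on
inputs with the documented structure, not agreement with any specific
COSMIC release or with RefSeq coordinates.

## The synthetic-cohort generator

The generator's defaults are the study conditions of the published
discovery cohort and are not tuning knobs:

* **Group sizes** per cancer type: CRC 36/11/24/21 (n = 92),
  EC 95/37/57/118 (n = 307), OC 24/12/8/4 (n = 48).
* **TMB**: each group draws from a *median-anchored two-piece
  log-uniform* -- with probability 1/2 log-uniform between the target
  minimum and the target median, else between the median and the target
  maximum, rounded to whole mut/Mb.  The published tables give only
  median and range; this is the simplest distribution that reproduces
  both exactly in population (a plain log-uniform over the range would
  miss the medians badly, e.g. sqrt(53 x 520) = 166 against a 219
  target).  The n = 57 EC G3 sample median has a sampling SD near 15% of
  its target, which is why recovery is asserted on the mean of 20
  replicate medians.
* **MSI, age, sex** follow the published per-group counts exactly
  (sampled without replacement within group).
* **Drivers**: P286R 0.40, V411L 0.27, the other 18 alleles sharing the
  remainder -- so the two dominant drivers account for about two thirds
  of driver-bearing tumors; 3% of driver tumors get a second driver.
* **Passengers**: each additional variant picks a mixture component
  (defaults SBS10a 0.28, SBS10b 0.32, SBS14 0.12, SBS28 0.08, uniform
  noise 0.20 -- chosen once so that roughly three quarters of G3
  passengers fall in proofreading contexts, the regime the published
  fractions describe), then a channel from that signature's full
  96-channel vector, then a uniformly chosen transcript position
  realizing that channel.  Synonymous changes, stop-codon losses and
  catalog driver alleles are rejected and the channel redrawn *within
  the same component*, so realized component counts are exactly
  multinomial in the weights while the per-channel law is the
  acceptance-reweighted signature vector -- the property-based tests
  verify both against direct enumeration on the transcript.
* **ddG and neoantigen scores**: drivers draw ddG from N(2.8, 1.2)
  (mostly destabilizing, as reported for the hydrophobic-core drivers),
  passengers from N(-1.0, 1.5) (mostly stabilizing or neutral); DNA-bound
  values exist only for NTL residues.  Per-tumor peptide counts are
  Poisson with rate increasing in TMB and Beta(1.2, 1.2) scores, which
  induces the positive TMB-neoantigen-burden correlation the analysis
  expects to detect.

What the generator does **not** emulate: non-SNV passenger variants
(real G3 cohorts contain ~8% frameshift/nonsense-by-indel events;
simulated nonsense arises only through stop-gain SNVs), comutation
landscapes, MSI mutational processes, and any germline/somatic
ambiguity.  Tests passing on simulated cohorts therefore demonstrate
correctness of the taxonomy, context attribution and statistics, not
clinical generalization.

Reproducibility: one integer seed drives the entire draw through R's
RNG; identical config and seed give record-identical cohorts.

```{r simulate}
sim <- simulateCohort(syntheticCohortConfig(seed = 7))
sim$cohort
a <- assignGroups(sim$cohort)
table(assigned = a$group,
      truth = sim$truth$groups$true_group[
        match(a$tumor_id, sim$truth$groups$tumor_id)])
```

## Numerical and procedural choices

* **Mann--Whitney**: exact null distribution when both samples have at
  most 20 observations and no ties, otherwise tie-corrected normal
  approximation with continuity correction (the method is always
  reported).  Comparisons with two or fewer datapoints in a sample are
  *refused* with an explicit status -- not given a placeholder p-value.
  The exact branch is verified against full permutation enumeration for
  all sample sizes up to 10.
* **Benjamini--Hochberg** is the plain step-up procedure
  (`stats::p.adjust`), applied across the explicitly supplied family of
  performed comparisons.  (Note the step-up adjustment is not idempotent
  in general; the tests assert the hand-applied formula, monotonicity
  and the unit bound.)
* **Median** uses the midpoint convention (even n: mean of the two
  central order statistics), which is what produces ".5" medians in
  group tables.
* **Inclusive boundaries everywhere the rules state them**: TMB 10 is
  TMB-high; ddG exactly ±1.45 kcal/mol is significant; neoantigen scores
  exactly 0.5 count as above-threshold.
* **ExoD boundaries**: the default domain map places ExoD at residues
  268--471 -- the literature-standard interval containing all 20 driver
  residues (275--465).  The boundaries were not printed alongside the
  original group definitions, so they are a config default in the domain
  map JSON, and boundary-sensitive counts (ExoD vs non-ExoD splits) may
  shift under a different map.
* **Coordinates** are 1-based inclusive throughout, protein and
  transcript alike.

## Degenerate inputs

Empty variant lists exclude a profile from the cohort (an error at
construction); missing TMB is an error at assignment; a fraction with no
channel-resolvable variant is returned as `NA` with an `undefined` flag
rather than invented; malformed cohort rows are collected into a rejects
table and never silently dropped; infeasible simulator configurations
(e.g. G1 TMB mass reaching the threshold) fail validation before any
sampling.

## Interface

The package's functions are the interface; `runPipeline(runConfig(...))`
ties the stages together and writes the report bundle (assignments,
group summary, context calls and aggregate, stats report, stability
census, neoantigen burden) plus a JSON manifest recording seed,
thresholds, signature source and any skipped stages, from which a run
can be reproduced exactly.  `scripts/acceptance.R` recomputes the
headline quantities from scratch on a study-sized simulated cohort.

## Known limitations

* The bundled signature vectors and transcript are synthetic (above);
  release-accurate context fractions require real COSMIC vectors and the
  real coding sequence, supplied as files.
* The full HGVS grammar is out of scope: intronic/UTR notation, complex
  rearrangements and genome-coordinate liftover are not parsed.
* ddG values and neoantigen scores are consumed, never computed --
  structural modeling and neural immunogenicity scoring live outside the
  package.
* De novo signature extraction/refitting is a non-goal: the context
  module tests membership of variants in fixed signature contexts, it
  does not infer signatures.
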