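---
title: "Detecting selection on somatic mutations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on somatic mutations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsignal)
```

## The observation model

A coding single-base substitution is silent, missense or nonsense, and the
standard genetic code fixes the proportions a neutral process can produce.
Enumerating the 3 positions × 3 alternative bases of each of the 61 sense
codons gives 549 substitutions — 392 missense, 134 silent, 23 nonsense —
so a transcript with equal codon usage mutated uniformly at random and
kept without selection shows fractions

```{r}
uniform_code_expectation()
```

Selection perturbs these fractions in characteristic directions. Positive
selection for truncation (tumor suppressors) raises fN; positive selection
for activating amino-acid changes (oncogenes) raises fM while typically
depressing fN; purifying selection (tumor-essential genes) depresses both
fM and fN, leaving an excess of silent events. The package's metrics are
deliberately simple transforms of (fS, fM, fN): pairwise ratios (rSM, rNM,
rNS) and one-vs-rest ratios (rSMN, rMSN, rNSM). The one-vs-rest ratios are
the most interpretable axes: each class of selection dominates exactly one
of them.

Two biases must be removed before fractions are comparable across genes.

1. **Mutation bias.** Tumors do not mutate uniformly: substitution classes
   (named by the pyrimidine of the mutated pair: C>A, C>G, C>T, T>A, T>C,
   T>G) have very different probabilities, and transition-heavy spectra
   produce more silent changes (third-codon-position transitions are often
   synonymous) while C>G dominance favors missense changes. The
   expectation model weights every possible change of every codon by the
   class probability from a substitution profile. A pan-tumor average
   profile (C>T 0.3726, T>C 0.1842, C>A 0.1583, C>G 0.1162, T>G 0.0891,
   T>A 0.0796) is bundled; `collapse_96_to_6()`, `mix_profiles()` and
   `cohort_average_profile()` derive profiles from 96-channel SBS
   signature matrices and per-sample attribution tables. For germline
   comparisons the 0.1×SBS1 + 0.9×SBS5 mixture is used; the bundled
   SBS1/SBS5 stand-ins are synthetic constructions reproducing the salient
   class structure (CpG-concentrated C>T for SBS1, a flat C>T/T>C-tilted
   background for SBS5) so that no download is required.
2. **Codon composition.** A gene rich in tryptophan codons cannot produce
   silent hits at those positions. Expectations are computed per
   transcript from its CDS composition (initiator ATG included, stop codon
   excluded), and "starred" metrics divide each observed quantity by its
   expectation, with expected ratios built by the same formulas as the
   observed ones. Within a class, both strand-equivalent directed changes
   inherit the full class probability; the normalization over a
   transcript's possible changes makes this convention well defined.

Flanking-context information is discarded after the 96→6 collapse: the
expectation model is context-free by design, matching the six-class
resolution of the metrics. Transcription-strand asymmetry and
trinucleotide-level dN/dS corrections are out of scope.

## Filtering and tallying

Records are kept when they are confirmed somatic, not SNP-flagged, not
from cell lines / organoid cultures / xenografts (repeated deposition of
the same line creates spurious recurrences), and carry one of the five
coding effect categories; duplicate (sample, transcript, CDS-change)
triples are collapsed by default because repeated reports of one event in
one sample are artifacts, while genuine recurrence across samples is kept.
Unclassifiable records are rejected and reported, never silently dropped —
silent misclassification would bias the fractions that everything
downstream consumes.

The minimum-mutation threshold (default 100 per transcript) controls the
noise floor: with fewer events the multinomial noise on (fS, fM, fN)
swamps any selection signal and zero counts make the ratio metrics
degenerate. `sensitivity_scan()` repeats the analysis at 0/50/100/500 to
show how conclusions depend on this choice; high thresholds
disproportionately drop negatively selected genes, which tend to be
undermutated. Analysis is transcript-level throughout.

SSI mode folds subtle indels into the metrics (inframe → amino-acid
changing, frameshift → truncating); `indel_rNSM`, the SSI-mode rNSM, is
the TSG-like classification axis because truncation selection acts on
frameshifts as strongly as on nonsense substitutions.

## Candidate calling

Per parameter space (fractions, pairwise ratios, one-vs-rest ratios; SO
and SSI), the central passenger cluster is summarized by the unweighted
per-axis mean and SD over all transcripts with defined values — no
trimming and no iteration. A transcript is a passenger-cluster member when
every axis is within 1 SD (ties inward), and a candidate when at least one
axis deviates by more than 2 SD. The ANY-axis reading is the one under
which a single space can simultaneously flag OG-like transcripts (extreme
on rMSN only) and TSG-like transcripts (extreme on rNSM only); a joint
Euclidean z-distance rule is available behind `method = "euclidean"`.
Candidate sets are unioned across spaces with per-space provenance.
Undefined ratios are excluded from cluster statistics rather than imputed:
pseudocounts would distort exactly the extreme tails that drive candidate
calling, and the ≥100-mutation filter makes undefined entries rare.

Class thresholds (indel_rNSM > 0.125, rMSN > 3.00, rSMN > 0.5 unstarred;
rNSM\* > 3, rMSN\* > 1.5, rSMN\* > 1.5 starred) are applied to the union
list; a candidate meeting several thresholds keeps all labels with a
multi-label warning. No multiple-testing correction is applied anywhere in
candidate calling — it is a descriptive SD-cutoff procedure; the
comparative statistics report raw p-values against a 0.05 threshold, and
Welch's unequal-variance t-test is used for group contrasts (the group
variances differ by construction between a selected class and the
background).

**Silent-hotspot guard.** A high silent fraction can be mutational, not
selective: recurrent synonymous hits at a few CDS positions inflate fS and
mimic purifying selection. A transcript is flagged when its top recurrent
silent position has at least `min_hits = 10` hits and its top `top_k = 3`
positions carry at least `min_share = 0.5` of all silent hits; flagged
TEG-like calls are demoted to unclassified (flag retained). The guard is a
post-filter, on by default, and its thresholds are configuration-exposed
because no canonical values exist for them.

## The synthetic cohort generator

The generator is the package's test bed: it emulates a COSMIC-like
somatic table, a dbSNP-like germline table, CDS FASTA and essentiality
scores, with per-transcript truth labels. Selection is implemented as
event-level weighted sampling — each possible change's probability is the
profile weight of its class times the regime's acceptance multiplier for
its effect — which is distribution-equivalent to rejection sampling but
cheaper and exactly seedable. Default regimes: passengers (1, 1, 1); TSG
w_N = 8 with frameshift rate ×4; OG missense weight ×2.5 on 30% of codons
(driver sites) with w_N = 0.2 and frameshift ×0.2; TEG (1, 0.5, 0.3) with
frameshift ×0.3 and inframe ×0.5; 10% of transcripts per selected class.
Mutation counts are drawn uniformly on [100, 300] per transcript (a
negative-binomial option models heavy-tailed burden); CDS are stop-free
uniform-codon sequences of 100–300 codons beginning with ATG. Indel
records carry position and frame class only, since tallies consume nothing
else. Contaminant rows (cell-line, SNP-flagged) are added at binomial
rates 0.05 and 0.03 to exercise the filters. The hotspot regime boosts
silent changes at three silent-capable codons by ×300, which concentrates
roughly 75–90% of a gene's silent hits there across the default length
range — a planted hotspot is therefore unambiguously a ">50% of silent
hits" hotspot, the condition the guard is meant to detect.

What the generator does **not** emulate: chromatin- or replication-timing
covariation of mutation rate, trinucleotide-context fidelity, realistic
codon usage (uniform by default; a user table can be supplied via the CDS
input), copy-number and structural events, and regime-dependent total
burden — counts are drawn independently of regime, so the real-world
undermutation of negatively selected genes appears only through the
shrinking analysed population in `sensitivity_scan()`, not as a per-gene
count deficit. Passing tests on this generator therefore demonstrate the
estimators' statistical behavior under the stated model, not robustness
to every covariate structure of real tumor data.

## Numerical choices

* Undefined ratios (zero denominators) are `NA`, R's native missing
  marker, and propagate explicitly; no sentinel numbers.
* Rounding happens only at presentation (5 decimals in reports), never in
  computation.
* Ties at exactly k·SD fall inward (1 SD is still passenger; 2 SD is not
  yet candidate).
* Fraction-level starred metrics (rS\*, rM\*, rN\*) are exactly unbiased
  under neutrality because observed fractions are unbiased and the
  expectation is a per-transcript constant. Ratio-level starred metrics
  (rSM\*, …, rNSM\*) carry a finite-count Jensen (convexity) bias of order
  1/n, appreciable at ~150 mutations per transcript. The
  calibration tests therefore assert unbiasedness on the fraction-level
  starred metrics; ratio-level metrics are used for ranking and
  thresholding, where the common small bias is immaterial.
* Cohort-average profiles are activity-weighted by default (each signature
  weighted by the mutations it explains); sample-weighted averaging is an
  option, since either convention is defensible when attribution tables
  do not state one.

## Known limitations

* With 30% of a cohort planted under selection, the full-population SDs
  that define the passenger cluster are partly driven by the selected
  classes themselves. The oncogene displacement (missense enrichment) is
  the smallest of the three class displacements, so OG recall is bounded
  by the 2 SD candidacy rule rather than by the rMSN > 3 threshold: most
  planted OGs pass the class threshold, but only about half deviate far
  enough from the inflated cluster to become candidates at all. Robust
  (e.g. passenger-only or trimmed) SD estimation would relax this, at the
  cost of departing from the plain full-population definition used here.
* Genes with few mutations are invisible regardless of selection strength;
  the minimum-mutation threshold trades this visibility against noise.
* The silent-hotspot guard is heuristic; hotspot-driven silent excess that
  is spread over many positions (below the top-k share) is not caught.
* Germline tables carry substitutions only (N/M/S categories); indel-based
  germline metrics are not defined.

## Problem sizes used in the test suite

Unit tests run on cohorts of 25–500 transcripts. The calibration and
recovery tests use the package's reference operating point — 3000
transcripts, 100–300 mutations each (the neutral calibration fixes 150) —
and the comparative and hotspot tests use 500–1000 transcripts, sizes at
which the tested contrasts are well resolved.
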