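---
title: "Methods: comparative-CT copy-number genotyping, growth association, and ferritin transcript annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qpcrcnv)
```

## The problem

Gene copy-number variants (CNVs) can be genotyped cheaply in non-model
species with real-time quantitative PCR: a target amplicon inside the
variable gene is compared against a control amplicon assumed to sit in a
single-copy region (two copies per diploid genome). This package
implements that pipeline for the ferritin heavy-chain gene *Fth1* of the
freshwater pearl mussel *Hyriopsis cumingii* — where copy number ranges
from 2 to 12 across wild and cultured stocks and correlates with shell
growth — together with annotation of the transcript features that make
ferritin biologically interesting: the iron-responsive element (IRE)
stem-loop in the 5' UTR, the ORF/UTR architecture, and the exon–intron
structure of the gene.

## The copy-number model

Let $Ct_T$ and $Ct_C$ be the mean threshold cycles of target and control
assays for one individual (means of triplicate wells from the same DNA
preparation). Under perfect per-cycle doubling, the diploid copy number
is

$$\hat{k} = 2 \cdot 2^{-(Ct_T - Ct_C)}.$$

When per-assay amplification efficiencies $E_T, E_C$ (fractional gain per
cycle) are known from standard curves, the corrected form is

$$\hat{k} = 2 \cdot (1+E_C)^{Ct_C} \, (1+E_T)^{-Ct_T},$$

which reduces to the base-2 formula at $E_T = E_C = 1$. Efficiencies come
from a genomic-DNA dilution series: OLS of Ct on $\log_{10}$ quantity
gives a slope $m$, and $E = (10^{-1/m} - 1) \cdot 100\%$; a slope of
$-3.3219$ cycles per ten-fold dilution is 100%.

### Integer calling and the no-call zone

$\hat{k}$ is real-valued. With fractional part $f = \hat{k} -
\lfloor\hat{k}\rfloor$, the caller returns $\lfloor\hat{k}\rfloor$ when
$f \le 0.3$, $\lfloor\hat{k}\rfloor + 1$ when $f \ge 0.7$, and refuses to
call otherwise. The two cutoffs were stated by the method's source
without an application rule; we adopted the fractional-part reading with
inclusive boundaries because it yields a symmetric no-call window of
width 0.4 around every half-integer and reproduces integer calls exactly
on clean data. Estimates below 0.7 — too small to round up to a single
copy — are no-called as "below one copy"; calls of 1 (hemizygous-like
estimates in $[0.7, 1.3]$) are allowed, following the caller's contract,
although the cohorts this emulates never produced one.

Replicate aggregation happens *before* estimation (the mean Ct is what
enters the formula); per-group replicate SDs above 0.5 cycles are flagged
for QC but never dropped, since no outlier rule was published.

## Association testing

Growth traits (shell length mm, shell width mm, body weight g) are
compared between two copy-number classes with a two-sided two-sample
t-test. Both the Student (pooled-variance, mirroring SPSS defaults) and
Welch variants are provided; Welch is the default because class variances
need not be equal. `t_from_summary()` runs the same tests from published
$(n, \text{mean}, \text{SE})$ summaries, reconstructing SDs as
$SE\sqrt{n}$ for the pooled variant. No multiple-testing correction is
applied across the three traits (each is reported at $\alpha = 0.05$).

A deliberate non-reproduction: applying either test to the published
cultured-cohort summaries (3 copies: $n=40$, shell length
$133.37 \pm 1.29$; 4 copies: $n=49$, $136.57 \pm 1.30$) gives
$p \approx 0.084$ (Welch) / $0.088$ (Student), not $p < 0.05$ as reported
from the raw data. Summary statistics do not determine the raw-data test
(pairing structure, rounding, or a different test configuration could
explain the gap); the package reports the computed value and is not tuned
toward significance.

## Transcript annotation

* **ORF/UTRs** — longest ATG-initiated, in-frame-stop-terminated frame on
  the forward strand (the cDNA orientation is known), ties resolved to
  the 5'-most start; the partition $UTR_5 + ORF + UTR_3$ always sums to
  the transcript length. A 525-nt ORF (including the stop codon) encodes
  174 residues.
* **Poly(A) signals** — exhaustive overlapping scan for ATTAAA/AATAAA.
* **Protein statistics** — average-isotopic mass as residue-mass sum plus
  one water; pI by bisection (60 iterations on pH 0–14) on the
  Henderson–Hasselbalch net charge with the EMBOSS pKa set (N-term 8.6,
  C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1),
  reported to 2 decimals.
* **IRE** — a deterministic consensus matcher, not thermodynamic folding:
  anchor on the apical loop CAGUGA, verify five upper-stem pairs
  (Watson–Crick plus G·U wobble by default), one unpaired bulged C
  immediately 5' of the upper stem, then at least `lower_stem_min`
  (default 3) contiguous lower-stem pairs. Folding servers are
  non-deterministic dependencies; the consensus matcher is reproducible
  and captures every feature the consensus literature agrees on.
  "Bulged cysteine" in the source literature is read as bulged cytosine.
* **Lower-stem counting** — the mussel element is described as having a
  "six nucleotide bottom stem". On the printed 27-mer this cannot mean
  six *pairs*: after the 6-nt loop, 2×5 upper-stem arms and the bulge,
  only 5 nt remain per lower arm, and the terminal C·C does not pair, so
  the element supports exactly 4 contiguous lower-stem pairs (with two
  G·U wobbles). Six *nucleotides* — three pairs — is consistent with the
  default minimum of 3. The acceptance suite keeps the six-pair reading
  as a deliberately failing expectation rather than weakening it.
* **Exon–intron mapping** — ordered greedy exact anchoring of the cDNA
  against the genomic sequence: extend the longest exact match, and at
  each mismatch boundary take the largest exon extension whose donor is
  GT with the nearest downstream AG acceptor at which the genomic
  sequence resumes the cDNA (confirmed with a 12-nt seed; introns ≥ 4
  nt). Exact matching suffices because both sequences derive from the
  same individual; a mismatch-tolerant spliced aligner is out of scope,
  and exons shorter than the seed are unsupported. Concatenated exons
  are verified byte-for-byte against the cDNA. Coordinates are 1-based
  inclusive throughout.

## The synthetic world

The generators state a world matching the study's structure; their
defaults are not tuned against test outcomes.

* **Populations** — categorical diploid copy-number distributions:
  JH-like (cultured), copies 2–6 with 3:40% and 4:49% dominant; PY-like
  (wild), copies 2–12 with 7–10 at 23.3/16.7/20.0/15.0%. The published
  figures give only the principal classes; the 11%/25% remainders are
  split across minor classes as documented in the constructors, chosen
  once as a plausible unimodal tail.
* **Ct tables** — the control assay is centred at 26 cycles (a typical
  genomic-DNA qPCR Ct at ~50 ng input) with a between-sample SD of 0.3
  cycles shared by both assays (extraction/pipetting variation; it
  cancels from ΔCt), and the target assay is offset by the exact inverse
  of the copy-number equation; independent Gaussian replicate noise
  (default SD 0.1 cycles, a documented assumption — replicate dispersion
  was not published) is added per well, triplicates by default.
* **Dilution series** — Ct at $\log_{10}$ quantity $q$ is
  $18 - q\,\ln 10/\ln a$ for amplification factor $a$, plus optional
  noise; noiseless series recover $(a-1)\cdot100\%$ efficiency to 1e-6.
* **Phenotypes** — independent normal draws per trait with class means
  and SDs reconstructed from the published cohort summaries
  ($SD = SE\sqrt{n}$); traits are uncorrelated by construction, which
  real shell traits are not. (The published width SE of 1.35 mm implies
  an implausibly large SD of 8.5 mm; it is used as printed.)
* **Gene models / cDNAs** — random exons joined by GT...AG introns, with
  each post-intron exon forced to start with a non-G base so that greedy
  anchoring provably stops at the true donor; designed cDNAs scrub ATG
  from the UTRs and reject the rare draw whose chance reading frame
  outgrows the designed ORF.

What a green test does **not** establish: performance on real
fluorescence data (baselining, melting-curve artefacts, PCR inhibition),
correlated traits, or non-Gaussian Ct noise.

### Recovery metric

With triplicate means at replicate SD 0.1, ΔCt has SD ≈ 0.082 cycles, so
the raw estimate for $k$ copies is $k\,2^{-\varepsilon}$ with
$\varepsilon \sim N(0, 0.082)$. Because the call window $\pm 0.3$ shrinks
*relative to spacing* as $\log_2\frac{k+1}{k}$, the probability of
landing in the no-call zone grows from ~1% at 2 copies to ~35–40% at 6 —
by design: the zone absorbs exactly the estimates the method cannot
distinguish. End-to-end recovery is therefore scored as concordance
among called samples (~98% for copies 2–6 under the stated world);
all-sample recovery cannot mathematically reach 95% at 5–6 copies under
any implementation of the published cutoffs.

## Numerical choices

* Efficiency identity and the 97% acceptance check are exact to 1e-6;
  the copy-number formula is checked against direct evaluation to 1e-12
  relative error.
* $R^2$ is computed from residual/total sums of squares directly so that
  noiseless series do not trigger spurious perfect-fit warnings.
* Seeds: every generator takes an explicit `seed` and is bit-reproducible
  under it; functions never set a seed unless one is passed.
* Degenerate inputs: positive-or-zero standard-curve slopes, < 3 dilution
  levels, zero-variance t-test groups, all-no-call frequency tables and
  non-reconstructable cDNAs all raise errors rather than guessing.

## Known limitations

* The control locus is *assumed* present at exactly two copies per
  diploid genome in every individual (3' UTR anchoring); a deletion
  spanning it would bias every call in that individual.
* The splice mapper requires exact exon matches and canonical GT/AG
  introns; it will not map across sequencing errors or non-canonical
  sites (it reports, rather than repairs, the furthest coordinate
  reached).
* The IRE matcher validates the consensus geometry only; it does not
  compute folding free energies and will accept consensus-conforming
  elements that might not fold in context.
* Whether the original genotype calls used the efficiency correction or
  only verified near-100% efficiencies is unknown; both paths are
  exposed via `calling_policy()`, defaulting to the printed base-2 form.
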