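---
title: "Measuring STR instability from short reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring STR instability from short reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strharvest)
```

This vignette is the package's own account of its models and the design
choices behind them: what each estimator assumes, which knobs matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where the honest limitations lie. It states
no empirical result that the test suite does not itself compute.

## 1. The measurement problem

A short tandem repeat (STR) allele of `a` units of a 2–6 bp motif appears
in a 151 bp read in one of three geometries:

* **spanning** — the read contains the whole tract plus flanking sequence
  on both sides, so `a` can be read off exactly;
* **in-repeat (IRR)** — the read lies wholly inside the tract, which only
  happens when the allele is longer than the read and whose *count* is
  therefore informative about length;
* **partial** — the read overlaps one boundary and measures nothing by
  itself.

Everything in this package is built from these three read classes: allele
lengths and germline genotypes from spanning reads, long-allele length
estimates from IRR counts, very-long-allele evidence from fragments whose
both mates are IRRs, somatic mosaicism from the minority of spanning reads
that disagree with the germline genotype, and germline mutation rates from
allele disagreements between haplotypes that share a locus
identical-by-descent (IBD).

## 2. Motif classes and repeat purity

Two motifs describe the same tandem repeat when one is a rotation of the
other or of its reverse complement, so motifs are keyed by a canonical
representative: the lexicographically smallest of all rotations of both
strands (`CAG`, `AGC`, `GCA`, `CTG`, `TGC`, `GCT` → `AGC`). Reads are
compared against canonical classes, which removes any need for a strand
flag.

A read's *purity* for a motif is the best fraction of positions matching a
perfect tiling over all rotations of both strands. The definition counts
substitutions only: a read whose best explanation would need an internal
indel scores low rather than being realigned. This keeps the operation
O(len × |motif|), makes the score an exact function of the substitution
count (`1 − e/len` when `e` substitutions are planted), and avoids the
rabbit hole of gapped alignment inside low-complexity sequence. `N` bases
count as mismatches. Rotation ties are broken by rotation order of the
canonical form, so results are deterministic.

A read is an IRR when purity ≥ τ. **τ defaults to 0.95** — a 151 bp read
may carry ~7 substitutions and still qualify. The value is a configurable
knob, not an empirical constant: it is chosen to admit reads that are
"almost entirely" repeat (sequencing errors and occasional interruptions)
while excluding random sequence, whose purity against a trinucleotide
class concentrates far below 0.9 (the test suite checks specificity on
random reads).

## 3. Harvesting reads

**Locus assignment.** An IRR has no usable alignment of its own (aligners
pile pure-repeat reads onto some representative locus), but its mate
usually anchors in unique flank. An IRR is assigned to the unique catalog
locus of the same motif class whose tract lies within **500 bp** (default
`window_bp`) of the mate's aligned interval. Zero candidates, two or more
candidates, or an unmapped mate leave it unassigned with a counted reason,
so pipeline accounting always sums to the input.

**IRR pairs.** A fragment whose both mates are IRRs of one motif class
must fit entirely inside a tract, implying an allele roughly as long as
the fragment — around 100+ units for a trinucleotide repeat at a 450 bp
insert. Neither mate anchors anywhere, so the pair inherits the unique
locus at which the same sample has assigned single IRRs, else it is
`ambiguous`.

**Spanning calls.** A spanning call requires an exact match of
**`min_anchor_bp` = 10** to the end of the left flank immediately before
the tract and to the start of the right flank immediately after it, tried
in both read orientations. Ten exact bases make a spurious anchor match
inside or near a trinucleotide tract vanishingly unlikely while tolerating
the 151 bp read budget; raising the anchor costs spanning yield roughly
linearly. When a flank is periodic enough to match its own anchor twice,
the occurrence closest to the tract is used. The segment between anchors
is counted in complete motif units against its best rotation; units
differing by substitution are recorded as interruptions
(`unit_index`, observed bases) up to a cap of **3 interrupted units**,
beyond which the call is rejected as unexplainable by substitution. Indels
inside the tract are deliberately *not* "interruptions": they change the
measured length, which makes the read a different length observation.

**Genotypes.** Per sample and locus, the germline genotype is the one or
two best-supported unit lengths; the second allele needs
`max(min_support, minor_frac × top)` reads (defaults 2 and 0.2). The
asymmetric rule reflects the data: a real heterozygous allele at 30×
coverage has far more than 20% of the top allele's reads, while PCR
stutter and somatic ladders sit at a few percent.

## 4. The stutter filter

PCR slippage during bridge amplification creates a *polyclonal* flow-cell
cluster: molecules with and without one extra (or missing) repeat unit
coexist. The instrument reports the majority base per cycle, so the read
carries the wrong length — but base qualities collapse at precisely the
cycles where the two molecular species disagree. Downstream of the shorter
species' repeat end, the species read (i) the right flank directly versus
(ii) one more repeat unit and then the flank; the positions where these
two hypotheses differ are the *signature positions*. When the flank itself
begins with repeat-like sequence the first informative position moves
downstream, and in the degenerate extreme the signature set is empty and
the read is simply not assessable.

The geometry is orientation-sensitive: sequencing proceeds in read
orientation from the fragment end, so for a reverse-strand read the
relevant junction empties into the reverse complement of the *left* flank.
The filter therefore evaluates the junction 3′ in read orientation, using
whichever flank follows the tract in that orientation. Whether a 5′-side
or mate-based signature would add power is left open; the single-junction
rule is documented as such.

A length-discordant read (δ = called − nearest germline allele, with
|δ| = 1; larger jumps are logged unclassified) is an **artifact** when its
signature-position quality mean is ≤ **q_low = 25** or at least
**q_drop = 10** below the mean over all other positions. The two rules are
complementary: the absolute floor catches reads that are degraded outright
(Q25 ≈ 0.3% error per base, far below a healthy Q37 cycle), while the
relative drop catches degraded signatures inside reads whose overall
quality is already mediocre. Both are exposed as parameters because the
instrument-scale calibration data behind any particular operating point is
not available at desk scale; the packaged defaults reach sensitivity ≥ 0.9
at FPR ≤ 0.01
on the generator's labelled reads (computed in the acceptance suite, not
assumed). Reads whose junction falls within 10 bp of the read end are
not assessable and are excluded from somatic estimation rather than
trusted.

## 5. Somatic phenotypes

**Expansion fraction.** For allele `a` and direction ±1, the estimate is
`n(a±1) / (n(a) + n(a±1))` over retained spanning reads — the average
fraction of cells in which one copy of `a` has changed by one unit. A
sample contributes only when attribution is unambiguous: it carries `a`,
no germline allele equals the target `a±1`, and the other allele is at
least **3 units** away (`min_gap`), except for the exact a/a homozygote,
where the fraction reads per allele copy. The 95% CI is the Wilson score
interval, which behaves sensibly at the tiny numerators (0–3 shifted reads
in 20–50) this estimator lives at. Pooling across individuals or age bins
sums counts before dividing — the ratio of sums, not the mean of ratios —
which is unbiased under varying coverage.

**Age trends** are weighted least squares of the per-individual metric on
age (weights default to attributable read counts). The single-step model
implies fraction ≈ rate × age, i.e. linearity, which the generator also
uses; on real data the linear slope is a first-order summary, not a claim
about the generative process.

**Long alleles.** An allele of L bp offers `L − R + 1` start positions for
a read to land wholly inside it, so `E[IRR] = c (L − R + 1)` at haploid
read-start density `c`, inverted to `L̂ = (R − 1) + IRR/c`. Zero IRRs
censor at L < R. Under mosaicism the estimate is the cell-averaged
expanded-allele length. When `c` is not supplied it is estimated as
(total mapped bases / (2 × genome size)) / R. The fragment-based score
divides the IRR-pair count by the fragment-start density, giving the
estimated number of eligible fragment-start positions —
`E[pairs] = c_frag × E_F[max(0, L − F + 1)]` over the fragment-length
distribution — which is monotone in L and can be inverted numerically
when the distribution is known.

**Calibration.** Because inherited length dominates any raw length metric,
individuals are compared within inherited-allele groups (labels are an
input column; the generator emits the inherited allele as the label, a
stand-in for haplotype-imputation groups): a within-group z-score plus an
inverse-normal transform of within-group ranks with offset `(r − 0.5)/n`,
ties averaged. Groups under **10** samples or with zero variance are
dropped with a reason. How the calibrated length metric and the
fragment-count metric would best be combined into a single optimized
phenotype is intentionally left as a user-facing weight: both metrics and
the calibration are exposed, no combination is hard-coded.

## 6. Germline rates from IBD sharing

Haplotypes sharing a tract IBD inherited one ancestral allele; each
discordance among them is a germline mutation on some branch. The
estimator needs three ingredients:

* **Meioses.** A tract of t cM implies about `100/t` meioses under the
  exponential tract-length model, clamped below at 2 (the closest possible
  relationship through a common ancestor). This is deliberately the
  simplest defensible inverse; externally supplied per-member meioses
  override it and are preferred whenever the upstream IBD caller provides
  them.
* **Ancestral allele.** The strict modal allele state among members. Ties
  are resolved toward the globally more frequent state when population
  frequencies are available — the frequency of an allele across the whole
  cohort is what "more-distantly shared haplotypes" converge to, and
  without this fallback every discordant *pair* would be unpolarizable and
  all pairwise mutation evidence discarded. A frequency tie still leaves
  the cluster unpolarized and counted as such. The cost is a small
  misattribution rate when two tied alleles have comparable frequencies;
  with mutation rates ≤ 10⁻³ and a dominant common allele the
  mis-polarization fraction is far below the Poisson noise on event
  counts.
* **Exposure.** Every member contributes its branch meioses to the
  ancestral allele's exposure whether or not it mutated, so total exposure
  is conserved by construction. Rates are `events/exposure` with exact
  Poisson CIs; a zero-event cell reports rate 0 with upper bound
  3.689/exposure.

Interrupted alleles are distinct states keyed by
(length, interruption signature), so an interrupted 18-unit allele accrues
rates separately from the pure 18 — which is what makes
interrupted-versus-pure fold comparisons possible. The fold CI conditions
on the total event count: events in group a are binomial given the
exposure ratio, the exact Clopper–Pearson interval for that proportion
maps monotonically to the ratio. Members more than one unit from the
ancestor are reported at their observed step but excluded from the ±1 rate
bins; no multi-step path inference is attempted. Allele states seen on
fewer than 25 haplotypes are pooled for reporting (configurable), since
their individual rates would be all CI and no estimate.

## 7. What the generator emulates — and what it does not

The generator is a stated world, not a tuning dial. Its defaults describe
a biobank-style experiment at one polymorphic CAG locus: 151 bp paired
reads; haploid depth 16 (read-start density c = depth/R); fragments
N(450, 100²) truncated at the read length; substitution errors at 10⁻³
per base; baseline quality Q37; stutter probability 0.02 per
tract-overlapping read with degraded signature qualities N(12, 4²) clipped
to [2, 37]; common alleles 12–25 units with a realistic spectrum; ages
uniform 40–70; germline expansion rate 10^(−4 + 0.05(a − 10)) per meiosis
with a 3:1 expansion:contraction asymmetry; somatic rate
2 × 10⁻⁴ × 10^(0.05(a − 25)) per year, i.e. ~1% expanded cells by age 50
for a 25-unit allele. The exponential length dependence and the 3:1
asymmetry mirror the qualitative behaviour of unstable trinucleotide
repeats; the absolute values are configuration choices documented here
once and not revisited.

Mechanistic choices worth knowing:

* **Single-step mosaicism**: cells carry `a` or `a+1` only, with fraction
  `f = rate × age`. Multi-step somatic ladders are out of scope, so a
  green test says nothing about +2/+3 behaviour.
* **Stutter is physical, not label-painted.** A stuttered read is
  re-extracted from a molecule one unit longer or shorter — left-anchored
  for forward reads, 3′-end-anchored for reverse reads, as bridge
  amplification dictates — and *every position where the two molecular
  species disagree* gets a degraded quality. The filter's hypothesis
  construction is computed independently from catalog flank and motif, so
  generator and filter share the mechanism but not a code path, and
  degraded qualities are drawn stochastically rather than copied from the
  filter's expectation.
* **Alignment is idealized**: reads map at their true coordinates, with
  in-tract positions piled at the tract start (as an aligner piles
  pure-repeat reads) and right-of-tract positions shifted by the length
  difference. Mapping error, soft-clipping, duplicates, GC bias, indel
  sequencing errors and instrument-specific quality profiles are absent.
  Green tests therefore establish the *estimators'* correctness given
  honest geometry, not robustness to alignment pathology.
* **IBD clusters** mutate stepwise per meiosis at the configured rates,
  with tract lengths exponential with mean 100/m cM and true per-branch
  meioses emitted alongside.

Determinism is a contract: every stochastic operation takes an explicit
seed, the locus sequence has its own seed (so the reference is stable
across run seeds), and identical configuration plus seed reproduces SAM
output byte-for-byte.

## 8. Numerical and interface choices

* Coordinates are 0-based half-open everywhere internally and in the
  catalog TSV (BED convention); SAM's 1-based positions are converted at
  the boundary.
* Nearest-germline-allele ties for δ (a read exactly between two alleles)
  resolve toward the lower allele — deterministic and conservative for
  expansion estimates.
* Operations that decline to answer (insufficient coverage, ineligible
  allele configuration, zero-variance group) return a typed
  `excluded(reason)` marker rather than NA, and the pipeline logs reason
  counts so that input reads are fully accounted for.
* The implementation is single-threaded R; `--threads` is accepted for
  interface compatibility and ignored, which makes thread-count
  independence trivially true.
* `sample_id` and `locus_id` are joined internally with a control
  character (`\r`) that is rejected in normal TSV input, avoiding
  separator collisions.

## 9. Known limitations

Beyond the generator's idealizations above: compound and adjacent repeats
are not disambiguated; soft-clipped reads are not realigned, so alleles
just short of spanning range are underobserved at fixed anchor length;
the IRR length estimator assumes uniform coverage and known `c`; pairwise
IBD polarization leans on the population-frequency fallback and will
misattribute direction when two alleles of comparable frequency meet in a
pair; and parent-of-origin or parental-age effects on germline rates need
family designs that IBD sharing cannot substitute for.
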