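# strharvest

Quantifying short-tandem-repeat (STR) instability — germline and somatic —
from short-read whole-genome sequencing.

Tandem repeats such as the CAG tracts in *TCF4* or *GLS* mutate orders of
magnitude faster than single nucleotides: alleles gain or lose repeat units
between generations (germline instability) and within the blood of a single
person over their lifetime (somatic mosaicism). Neither process is directly
visible in a standard variant callset, but both leave quantifiable traces in
the raw read alignments. `strharvest` implements that read-level machinery
for anyone with paired-end alignments, a repeat catalog and (optionally)
identity-by-descent (IBD) sharing information:

- **In-repeat reads (IRRs).** A 151 bp read consisting entirely (purity ≥ τ,
  default 0.95) of tandem copies of a 2–6 bp motif signals an allele longer
  than the read. IRRs are assigned to a catalog locus through their mate's
  alignment (window 500 bp); a fragment whose *both* mates are IRRs (an
  *IRR pair*) implies an allele roughly as long as the fragment — ~100+
  units for a trinucleotide repeat. Motifs are canonicalized over rotation
  and strand, so CAG, AGC and CTG are one class (`AGC`).
- **Spanning reads.** Reads containing the full tract plus ≥ 10 bp of exact
  flank on both sides measure allele length in units, with intra-repeat
  interruptions (e.g. the stabilizing `CAT` in unit 9 of an 18-unit allele)
  recorded per unit. Per-sample germline genotypes are the one or two
  best-supported lengths.
- **PCR-stutter filtering.** Polymerase slippage during bridge amplification
  creates polyclonal clusters whose reads carry a spurious ±1-unit length
  change — but with *depressed base qualities* exactly where the two
  molecular species in the cluster disagree (downstream of the shorter
  species' repeat junction). A length-discordant read is discarded as an
  artifact when its signature-position quality mean falls below Q25 or more
  than 10 below the rest of the read.
- **Somatic phenotypes.** The expansion fraction of allele *a* is
  n(a+1)/(n(a)+n(a+1)) over retained reads (Wilson 95% CI) — the average
  fraction of blood cells in which the allele has gained one unit — with
  pooling by allele and age bin, weighted age-trend regression, IRR-count
  length estimates for unsizeable alleles (E[IRR] = c·(L−R+1), inverted to
  L̂ = (R−1)+IRR/c), a fragment-count score for highly expanded alleles, and
  inverse-normal calibration within inherited-allele groups.
- **Germline rates from IBD.** Haplotypes sharing a tract IBD carry the same
  allele unless a meiosis on some branch mutated it. With the ancestral
  allele imputed by consensus (population frequency breaks pairwise ties)
  and meioses estimated from tract length (m̂ = max(2, 100/cM)) or supplied,
  per-generation expansion/contraction rates are events/allele-meioses with
  exact Poisson CIs; interrupted alleles are separate states, enabling
  interrupted-vs-pure fold comparisons with conditional-binomial CIs.
- **Synthetic data.** A seeded generator emits SAM read alignments plus full
  truth tables (mixtures, per-read class and stutter labels, IBD events), so
  every stage above is testable end to end without restricted biobank data.

## Worked example

```r
library(strharvest)

cfg <- sim_config()                                  # 151 bp reads, 16x haploid
pop <- simulate_population(cfg, 50, seed = 1)
sim <- simulate_reads(pop, cfg, seed = 2)            # 12,990 reads
h   <- harvest_reads(sim$reads, sim$locus$catalog)   # 865 spanning calls

head(h$genotypes, 3)
#>   sample_id locus_id allele1 allele2 support1 support2
#> 1    S00001   locus1      17      17        8        8
#> 2    S00002   locus1      12      17        8        2
#> 3    S00003   locus1      17      18        6       14

fl <- filter_stutter(h$spanning, h$genotypes, sim$reads, sim$locus$catalog)
table(fl$assessments$verdict)
#>       artifact     concordant not-applicable       retained
#>             15            846              3              1

fr <- somatic_fraction_table(fl$retained, h$genotypes, pop)

ib  <- simulate_ibd(cfg, 5000, cluster_size = 2, m = 10, seed = 3)
est <- estimate_rates(ib$members, min_haplotypes = 0)
est$rates[est$rates$allele_units == 25, ]
#>   allele_state direction events exposure      rate      ci_low     ci_high
#>             25         1      2     5210 0.0003839 0.000046489 0.00138670
#>             25        -1      2     5210 0.0003839 0.000046489 0.00138670
```

Reading the output: 15 of the 19 length-discordant spanning reads carried
the polyclonal-cluster quality signature and were discarded as PCR stutter;
the 25-unit allele accrued 2 expansion and 2 contraction events over 5,210
allele-meioses, i.e. a per-generation rate of 3.8 × 10⁻⁴ in each direction
(exact Poisson 95% CI 4.6 × 10⁻⁵ – 1.4 × 10⁻³).

A command-line front end wraps the same functions:

```sh
exec/strharvest simulate --out-dir sim --seed 5 --n-samples 25
exec/strharvest harvest  --reads sim/reads.sam --catalog sim/catalog.tsv \
                         --out-dir harvest
```

Every run writes a `manifest.json` (inputs, checksums, seed, row counts);
reruns with the same seed are byte-identical.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch — simulated
cohort → harvest → stutter filter → somatic fractions and age trend, plus
IBD-based germline rate estimation — under a caller-supplied seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The quantitative acceptance checks (spanning exactness, IRR-count oracle,
stutter-filter operating point, Wilson-CI calibration, germline rate
recovery, direction asymmetry, null safety, determinism) live in
`tests/testthat/test-acceptance.R` and run with the test suite.
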