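---
title: "BSAscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BSAscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BSAscan)
```

# The problem and the model

Bulked-segregant analysis locates a trait locus in a diploid biparental
cross by sequencing pooled DNA from phenotype-selected progeny. The
analysis rests on one idea: at markers linked to the selected locus, the
allele frequency in the pool is distorted away from its neutral
segregation expectation, and the distortion decays with genetic distance.

BSAscan works at the level of a multi-sample VCF. For each biallelic site
the parent's genotype polarizes the alleles — the tracked allele is the
one the homozygous parent does *not* carry (when the parent is homozygous
for the VCF ALT allele, ref and alt depths swap roles). The per-bulk
SNP-index is then simply the fraction of reads carrying the non-parental
allele, and the two-bulk statistic is the difference of the two indices,
bulk1 minus bulk2 in the configured order.

Two sources of noise separate the observed index from the linkage signal:

1. **finite bulk composition** — a pool of $n$ individuals carries only
   $2n$ chromosomes, and each individual's genotype at an unlinked locus
   follows the selfed-generation ratios
   $(p_{\mathrm{hom}}, p_{\mathrm{het}}, p_{\mathrm{hom}})
   = \left(\tfrac{1-h_k}{2},\, h_k,\, \tfrac{1-h_k}{2}\right)$ with
   $h_k = 0.5^{\,k-1}$ for generation $F_k$;
2. **read sampling** — at depth $d$, the observed index given the pool
   frequency $p$ is $\mathrm{Binomial}(d, p)/d$.

The null hypothesis ("no linkage to the selected locus") is simulated
exactly as this two-stage process, with no distributional assumption on
the index itself. Selection is deliberately absent from the null: at an
unlinked locus, selection on the causal locus does not distort
segregation. Per-depth empirical quantiles of the simulated statistic
give two-sided confidence bounds, so each variant is judged against the
bounds for *its own* depth — the natural way to handle the strong
depth heterogeneity of real resequencing data.

A variant is called at level $L$ iff its statistic lies **strictly
outside** $[q_{(1-L)/2},\, q_{1-(1-L)/2}]$; a value exactly on a bound is
not flagged. Two-sided bounds are used in both modes (a configurable
choice in principle; one-sided testing in one-bulk mode would only be
appropriate if low-index sites were a priori uninteresting, which is not
true for e.g. polarization errors worth inspecting).

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n` (per bulk) | — | individuals | experiment fact; the dominant term in the null variance |
| `generation` (k) | 2 | selfed generation | F2 progeny; 6 for typical RIL populations. One-bulk runs are F2 by construction |
| `reps` | 10 000 | replicates/depth | quantile error at 99% ≈ a few 10⁻³ on the index scale; cheap |
| `levels` | 0.95, 0.99 | — | the two conventional bands drawn on BSA plots |
| `depthCap` | 400 | reads | deeper variants reuse the cap's bounds — conservative, since width shrinks with depth |
| `minMQ` | 40 | Phred | standard mpileup-era mapping-quality floor |
| `minDepth`, `maxDepth` | 8, 250 | reads | below 8 the index is too grainy; above 250 suggests collapsed repeats |
| `strandBiasPhredMax` | 40 | Phred | Fisher exact on (ADF, ADR) × (ref, alt); only evaluated where strand counts exist |
| `minIndexEitherBulk` | 0.3 | index | two-bulk spurious-SNP rule: a real segregating site should exceed 0.3 in at least one bulk |
| `windowBp`, `stepBp` | 2 Mb, 100 kb | bp | smooth at typical marker densities while resolving ~Mb peaks; presentation-layer only |
| `minVariants` | 3 | variants | windows with fewer members are masked rather than averaged |

Filter rules are all evaluated for every variant (no short-circuiting),
so the per-reason rejection counts in the run log are additive and
order-independent diagnostics.

# Numerical choices

* Quantiles use R's default interpolating definition (type 7). Because
  the interpolated bound almost never coincides with an atom of the
  discrete statistic (multiples of $1/d$), the strict-inequality
  flagging convention is effectively immaterial at realistic depths; the
  realised false-positive rate sits slightly *below* nominal at low
  depth, i.e. the test errs conservative.
* CI tables are built only for the depths (or two-bulk depth pairs)
  actually observed, capped at `depthCap`, in sorted order under one
  seed — identical configuration therefore reproduces bit-identical
  tables, and every output TSV is byte-reproducible.
* With multiple levels the empirical bounds are clamped so higher
  confidence always encloses lower confidence, removing rare
  Monte-Carlo crossings at small `reps`.
* The strand-bias statistic is defined as 0 whenever a margin of the
  2×2 table is empty (the test carries no information), and Fisher
  p-values are floored at the smallest positive double before the
  Phred transform.
* Degenerate inputs fail loudly rather than silently: SNP-index at
  depth 0 is an error (such sites must be filtered), multi-allelic
  records must be removed before the index table is built, unsorted
  variant tables are rejected by the window scan, and a run in which no
  variant survives filtering aborts with the per-reason counts.
* Šidák correction ($\alpha' = 1-(1-\alpha)^{1/m}$) is used rather than
  Bonferroni so the adjusted quantity stays a probability. The
  effective test count is $m = \max(\text{chromosomes},\,
  \mathrm{round}(\text{total cM}/50))$ — loci ≥ ~50 cM apart segregate
  near-independently — and is isolated in `effectiveTests()` so an
  alternative rule can be swapped in. All three genome facts
  (chromosome count, genome size, total cM) are required; the
  correction is refused when any is unknown.

# What the synthetic generator emulates

`bsaScenario()` + `writeScenarioVcf()` simulate the *experiment*, not
the sequencer: a genome of named chromosomes; a planted causal locus;
finite bulks whose individuals are fixed at the causal locus (one-bulk:
homozygous non-parental; two-bulk: the two bulks fixed in opposite
directions); marker genotypes on the carrier chromosome drawn as two
gametes each non-parental with probability $1-r$ (or $r$ in the low
bulk), with $r$ from the Haldane map $r = \tfrac12(1-e^{-2d/100})$ at
`cmPerMb` × physical distance; exact $F_k$ segregation on other
chromosomes; per-site depths fixed or negative-binomially overdispersed;
uniform per-read miscall errors; and a parent emitted homozygous
reference at full depth. The realised (finite-bulk) frequency of every
marker is written to a truth table, so tests can separate bulk-sampling
noise from read-sampling noise.

The two-gamete draw is exact for F2 individuals. For advanced selfed
generations it approximates the RIL linkage map (which would require
tracking recombination through every selfing round); unlinked loci use
the exact $F_k$ genotype classes. The defaults — two 10 Mb chromosomes
at 4 cM/Mb, causal locus at chr1:5 Mb, 20 F2 individuals, depth 100,
2 000 markers, no read errors — are a desk-scale miniature of a typical
rice MutMap experiment in which the carrier chromosome spans 40 cM, so
both strong linkage near the peak and visible decay toward the
chromosome ends are observable.

What it does **not** emulate, and what passing tests therefore cannot
show about real data: alignment and variant-calling artifacts (the
filters for mapping quality and strand bias are exercised only through
hand-built fixtures), repeat-induced depth pathologies, segregation
distortion unrelated to the phenotype, partial-penetrance selection,
heterozygous parents, and outcrossing species. The generator's
`errorRate` is a uniform miscall probability, not a base-quality model.

# Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on generated data:
null simulations at $10^5$ replicates, exact-enumeration cross-checks at
bulk sizes ≤ 2 and depths ≤ 3, coverage checks on 20 000 null variants
against independently seeded tables, and end-to-end runs on 300–2 000
marker scenarios. These sizes were chosen to keep each statistical check
well inside its Monte-Carlo tolerance (3 standard errors for means,
total-variation distance < 0.01 against enumeration) while remaining
desk-scale.

# Known limitations

* One-bulk mode assumes the bulk is selected for the homozygous
  non-parental class, as in mutant mapping; dominant traits where the
  bulk mixes genotype classes need the two-bulk design.
* The null ignores residual heterozygosity of the *parent* line; the
  parent is assumed a homozygous inbred (heterozygous parent sites are
  filtered by default).
* Multi-allelic sites are excluded rather than decomposed — the
  SNP-index is a two-allele contrast and decomposition would change
  depths ambiguously.
* Two-bulk CI tables are keyed by the exact per-bulk depth pair, never
  by the mean depth, so tables grow with the number of distinct observed
  pairs; extremely heterogeneous depth profiles pay a simulation-time
  cost (bounded by `depthCap`).
* The sliding-window summary is an unweighted mean over member variants
  anchored at position 1 of each chromosome; no kernel or local
  regression smoothing is offered.
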