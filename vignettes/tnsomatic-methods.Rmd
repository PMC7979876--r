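---
title: "Models and methods behind tnsomatic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnsomatic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnsomatic)
```

tnsomatic analyses matched tumour/normal genome sequencing in the setting
where somatic events must be separated from a much larger background of
germline variation and platform noise — typically a tumour/normal pair
sequenced on both a short-read and an error-prone long-read platform. This
vignette describes the statistical models the package implements, the
parameters that matter, the behaviour of the synthetic-data generators the
test suite relies on, and the numerical choices made where the methods
leave room for interpretation.

## The tumour/normal mixture model

Everything in the package rests on one mixture model. A tumour sample is a
mixture of tumour cells (fraction $\alpha$, the *purity*) and normal cells
(fraction $1-\alpha$). For a genomic segment with integer tumour copy
number $p$ and germline copy number $g$, the expected sequencing
representation of the segment relative to the normal sample is
$(\alpha p + g(1-\alpha))/g$, so the expected log ratio of
yield-normalised window counts is

$$ m(p) = \log_2\frac{\alpha p + g(1-\alpha)}{g}, $$

with $g = 2$ on autosomes and $g = 1$ on the sex chromosomes of a male
genome (`theoreticalMean()`). The mean is zero at $p = g$ for any purity
and strictly increasing in $p$ whenever $\alpha > 0$; at $\alpha = 1$ and
$p = 0$ it is $-\infty$ (a homozygous loss in a pure tumour has no reads).
The same mixture underlies the expected VAF of somatic SNVs and the
cis/trans bounds below.

## Somatic SNVs by subtraction

The SNV pipeline (`runSnvPipeline()`) assumes tumour and germline samples
were called *separately* — not jointly — so the somatic set must be
obtained by subtraction, and the noise characteristics of long reads make
aggressive annotation-based filtering essential. The stages are:

1. **Restriction to SNVs.** Indel and MNP records are dropped with a
   logged count; the pipeline's thresholds are calibrated for
   single-nucleotide substitutions.
2. **Initial filter**: `QUAL > 1 & NUMALT < 2 & SAF > 1 & SAR > 1`, applied
   to both samples. All comparisons throughout are strict, mirroring how
   such filter strings are conventionally written. `NUMALT` is a
   site-level count: multi-allelic sites are expanded to per-alt records on
   reading, but each expanded record keeps the site's allele count so this
   filter still acts on the site.
3. **Germline subtraction** on the key (CHROM, POS, ALT). REF is
   deliberately not part of the key — at a given position the reference
   base is fixed anyway, and keying on ALT alone avoids losing matches
   when representations differ.
4. **Strand-bias exclusion.** A recurrent error signature of nanopore
   sequencing is an alternate allele seen almost exclusively on one
   strand. The filter removes a call when the *per-strand alternate
   fraction* — $f_{fwd} = SAF/(SAF+SRF)$ versus
   $f_{rev} = SAR/(SAR+SRR)$ — is more than 4× higher on one strand than
   the other. Per-strand fractions, rather than the raw $SAF:SAR$ ratio,
   are used so that genuinely uneven strand *coverage* is not penalised
   twice; a strand with zero depth contributes a fraction of zero, making
   the call removable only if the other strand's fraction is positive. A
   ratio of exactly 4 is retained ("more than" is strict).
5. **Final filter**: `AO > 10 & RO > 10 & QA > 100 & QR > 100 & AO < 100 &
   RO < 100 & SAP < 30 & MQM > 55`. The lower bounds remove weakly
   supported calls, the upper depth bounds remove repeat-driven pile-ups,
   the strand-balance cap (phred-scaled) catches residual imbalance, and
   the mapping-quality floor removes ambiguous placements.
6. Optionally a **second subtraction** against a germline call set from
   another platform, which removes germline variants the same-platform
   germline calling missed.

All filters are idempotent and commute (each is a pointwise predicate), and
the pipeline can only ever remove calls — properties the test suite checks
on arbitrary generated input. `compareCallsets()` reports the
shared/private overlap between two call sets on the same (CHROM, POS, ALT)
key.

## Somatic SVs: subtraction, filtering, benchmarking

Germline SV subtraction (`subtractGermlineSvs()`) removes a tumour call
when a germline call of the same type has both breakpoints within
$L/100$ bases, $L$ being the germline SV's length. The scaling reflects
that breakpoint estimates of large imprecisely-assembled events wander
further than those of small ones. Two choices the rule itself does not fix:

* **Translocations** have no length, so the $L/100$ rule cannot apply; they
  subtract within a fixed window (default 1000 bp, the same scale as the
  cross-method matching tolerance).
* A **floor of 10 bp** keeps tiny germline SVs able to subtract their
  re-called twins, since $L/100$ would otherwise fall below ordinary
  breakpoint jitter.

`filterSomaticSvs()` then keeps precise calls longer than 10 kb whose
second breakpoint is not on the decoy contig (`hs37d5`); since an
inter-chromosomal call joins two chromosomes, translocations satisfy the
length criterion by construction. Imprecise calls with allele fraction
above 0.2 are returned separately for manual review rather than silently
dropped — in practice nearly all of them are artifacts, but the high-AF
subset is worth eyeballing.

`matchAcrossMethods()` clusters calls from several methods into unique
variants: same type, both breakpoints within a tolerance (default
1000 bp). Clusters are connected components of the pairwise relation, so
the result is independent of method order and matches a transitive-closure
oracle exactly (tested). `evaluateMethods()` scores each method per SV type
with

$$ \mathrm{FNR} = \frac{\text{true variants not detected}}
{\text{total true variants}}, \qquad
\mathrm{FDR} = \frac{\text{false calls detected}}
{\text{total calls from the method}}, $$

treating truth labels as an input (in real studies they come from manual
review of read evidence; `labelVariants()` assigns them from a truth table
and appends true variants no method detected). Zero denominators yield
`NA`, never zero. Rates are reported raw and rounded half-up to two
decimals only in the presentation layer (`formatBenchmarkTable()`), the
convention such tables are printed with.

## Windowed copy number

### Log ratio and masking

With $T(w)$ and $N(w)$ the tumour/normal read counts in window $w$
(100 kb windows of MAPQ ≥ 20 reads in the intended application),

$$ R(w) = \log_2 \frac{T(w)}{N(w)} - \text{offset}, \qquad
\text{while } N(w) > \overline{N} - 2\,\mathrm{sd}(N), $$

and `NA` otherwise. The mask removes windows the normal sample barely
covers — centromeres, assembly gaps, accumulated mapping deserts — where
the ratio is dominated by noise in the denominator. The offset absorbs the
difference in total sequencing yield between the samples; `"auto"` uses
$\log_2(\sum T / \sum N)$. Two degenerate cases are defined explicitly: a
zero tumour count in an unmasked window becomes `NA` with a logged count
(log of zero), and when $\mathrm{sd}(N) = 0$ no window is masked (a strict
threshold at the mean would otherwise mask everything).

### Circular binary segmentation

`segmentCBS()` implements CBS directly. Each chromosome's non-missing
ratios are treated as a circle; the scan considers every arc
$x_{(i+1)..j}$ versus its complement and maximises the standardised
mean-difference statistic
$|\bar{x}_{arc} - \bar{x}_{rest}| / \sqrt{1/k + 1/(n-k)}$, with both parts
at least `minWidth` (default 5) points. Significance is assessed by
permutation: the maximal statistic is recomputed for random permutations
of the segment and the split is accepted when
$(1 + \#\{exceedances\})/(1 + n_{perm}) \le \alpha$ (defaults
$n_{perm} = 1000$, $\alpha = 0.01$). Accepted splits recurse into the
resulting sub-segments. Finally, *sd-undo* removes change points whose
adjacent segment means differ by less than `undoSD` (default 3) times a
robust point-level noise estimate, $\mathrm{mad}(\Delta x)/\sqrt{2}$.

Numerical and performance choices:

* The $O(n^2)$ scan and the permutation loop are compiled (Rcpp); the
  permutation loop stops early as soon as enough exceedances have
  accumulated to rule out significance at $\alpha$, which makes testing a
  homogeneous chromosome cheap without changing the accept/reject
  decision.
* Permutations are drawn in R from a seeded, caller-isolated RNG stream
  (`CbsParams(seed = )`), so segmentation is deterministic and never
  perturbs the caller's random state.
* Ties in the scan resolve to the first split in scan order; the scan is
  verified against an exhaustive oracle on all short sequences.
* A segment whose values are constant to machine precision is never
  tested for splitting.

### Recentring, purity, classification

When the tumour genome's average ploidy differs from 2, yield
normalisation shifts copy-neutral windows away from $R = 0$, so segment
means must be recentred before the mixture formula can be inverted.
`recentreSegments()` estimates the ploidy-2 baseline as the
window-weighted mean of long segments (> 500 windows) lying within
`zeroBand` (default 0.25) of the *window-weighted median* of all long
segment means. The median anchor matters: most of the genome is neutral,
so the median sits on the neutral level even when the yield offset has
moved it close to the band edge — a plain "within 0.25 of zero" rule can
capture triploid segments once the offset exceeds a tenth or so, which
measurably biases the purity estimate. Sex chromosomes are excluded from
the baseline, since germline-haploid chromosomes cannot represent
ploidy 2.

`estimatePurity()` clusters the non-neutral autosomal segment means along
the real line (a gap larger than `gapThreshold`, default 0.1, starts a new
cluster), assigns provisional ploidies — most negative cluster $p = 1$,
positive clusters ascending $p = 3$ then $p = 4$, with a warning when the
cluster count is not the expected one — and inverts the autosomal formula
per cluster, $\alpha_p = (2^{m+1} - 2)/(p - 2)$, averaging the per-cluster
estimates. The default `zeroBand` of 0.25 separates ploidy 2 from 3 only
at purities above roughly 0.35; the noiseless inversion property is
therefore exercised with a narrower band in the tests, and users analysing
low-purity samples should narrow it too. `classifySegments()` assigns each
segment the ploidy in 0–6 whose theoretical mean (with the correct
germline ploidy per chromosome) is nearest its recentred mean, breaking
ties toward the lower ploidy and leaving segments further than
`maxDistance` (default 0.5) from every theoretical mean unclassified.

## The cis/trans expected-VAF model

For a somatic SNV inside a heterogeneous somatic deletion's footprint, with
tumour purity $\pi$ (percent) and the deletion carried by $x$ percent of
all cells, counting allele copies gives the expected read fraction of the
SNV as at most

$$ \mathrm{cis}: \frac{\pi - x}{200 - x}, \qquad
\mathrm{trans}: \frac{\pi}{200 - x} $$

(`expectedVafCis()`, `expectedVafTrans()`, returned as percentages). In cis
the SNV sits on the haplotype that is lost, so only tumour cells that have
not acquired the deletion carry it; in trans every tumour cell carries it
on the retained haplotype. Both bounds coincide at $x = 0$ at $\pi/2$; cis
decreases and trans increases in $x$. At $\pi = 60$ the cis bound peaks at
30% and the trans bound reaches $60/140 \approx 43\%$ at $x = 60$ — so an
observed VAF above 30% is only achievable in trans, which
`classifyConfiguration()` operationalises (observations at or below the
boundary are reported inconclusive; `deletionAfToCellFraction()` maps an
observed deletion allele fraction to the cell fraction under the same
mixture). The formulas are implemented for general purity with the
published 60% as the worked instance.

`haplotagReads()` is a deliberate simplification of read-based phasing
tools: each read votes once per covered phased heterozygous site for the
haplotype whose allele it shows, is assigned by strict majority, and
per-site REF/ALT counts are tabulated within each haplotype group. There
is no recombination or error model; with per-site error rate $e$ and $k$
informative sites the assignment accuracy follows the binomial
majority-vote bound $P(\mathrm{Bin}(k, 1-e) > k/2)$, which the tests check
at $e = 0.1$, $k = 5$.

## What the synthetic data emulates

The generators produce data with exactly the statistical structure the
analyses assume, which is what makes the recovery tests meaningful — and
delimits what they show.

* `simulateSmallVariants()`: germline heterozygous SNVs present in both
  samples with $AO \sim \mathrm{Bin}(d, 1/2)$; somatic SNVs at expected
  VAF $c/2$ for cell fraction $c$; depths negative-binomial around 60;
  $QA = AO \times$ (per-call mean base quality around Q13); MQM normal
  around 60; SAP computed as the phred-scaled two-tail binomial
  probability of the observed strand split — the annotation-producing
  caller defines SAP differently in detail, but the pipeline only
  thresholds it, so any monotone strand-imbalance score with the same
  scale behaves identically. Planted strand artifacts put every alternate
  observation on one strand. With `clean = TRUE` (default) somatic and
  germline annotation draws are truncated into the filter-passing ranges,
  so truth labels are exactly recoverable; with `clean = FALSE` borderline
  calls can legitimately fail filters.
* `simulateSvSets()`: a germline SV inventory present in both samples
  (tumour-side re-calls jittered by at most $L/200$, half the subtraction
  tolerance), a tumour-only somatic inventory whose per-type counts
  default to a curated single-genome large-SV survey (49 DEL, 6 DUP,
  10 INV, 4 TRA), tumour-set noise exercising every filter branch (decoy
  translocations, imprecise calls either side of the AF cutoff,
  sub-threshold lengths), and per-method call sets with configured
  per-type miss probabilities and false calls placed in a coordinate range
  disjoint from the truth.
* `simulateWindowCounts()`: negative-binomial counts (dispersion 0.02 by
  default — variance about five times Poisson at depth 60; 0 gives
  Poisson, `noise = "none"` gives deterministic expected counts) over a
  whole-genome layout whose per-chromosome window counts mirror real
  chromosome lengths at 100 kb (about 30,900 windows), with the tumour at
  purity 0.63 gaining chromosome 3 to four copies, 7 and 18 to three,
  losing one copy of 17 and all of the germline-haploid Y. One percent of
  windows get near-zero normal counts to exercise the mask.
* `simulatePhasedReads()`: two haplotypes over 14 heterozygous sites,
  reads covering contiguous runs of 5 sites with 10% per-site allele
  error.

Same seed, same output, byte for byte; the generators restore the caller's
RNG state.

What passing these tests does *not* show: real windowed coverage has
GC- and mappability-driven autocorrelation the independent
negative-binomial draws lack, real germline call sets disagree between
platforms far more than the generator's shared-inventory model, subclonal
copy number produces non-integer mixtures the classifier deliberately does
not model, and truth labels for SVs come from manual review, not from a
clean inventory. The package's correctness on the generated data bounds
its behaviour on real data from the favourable side.

## Problem sizes and determinism

The stochastic recovery checks run the full copy-number pipeline on the
~30,900-window genome described above (a few tens of seconds, dominated by
the permutation tests), recover purity within ±0.03 of the simulated 0.63,
and classify every whole-chromosome aberration correctly; the SV benchmark
checks use several hundred deletions so that binomial error on FNR
estimates is a few percent. All stochastic steps take explicit seeds, and
`scripts/acceptance.R --seed N --out f.json` re-runs the headline
computations end to end.

## Known limitations

* The SNV pipeline assumes FreeBayes-style annotations; call sets without
  per-strand observation counts cannot use the strand-bias filter.
* Purity estimation requires at least one non-neutral autosomal cluster
  and assumes the provisional ploidy assignment {1, 3, 4}; genomes whose
  aberrations are all at other ploidies need the cluster assignment
  overridden, and whole-genome duplication (where the *median* level is
  not ploidy 2) defeats the recentring anchor.
* Classification treats ploidies above 6 as unclassifiable and does not
  model subclonal (non-integer) states.
* The haplotagger has no phase-set segmentation: it assumes one phase
  block spanning the supplied sites.
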