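# tnsomatic

Tumour–normal subtraction analysis of somatic variants for matched cancer
genome sequencing, built for the setting where a tumour/normal pair has been
sequenced on both a short-read and a long-read platform and somatic events
must be pulled out of call sets dominated by germline variation and
platform-specific artifacts.

The package implements four connected analyses:

* **Somatic SNV calling by subtraction.** Tumour and germline small-variant
  call sets carrying FreeBayes-style annotations (AO, RO, SAF, SAR, QA, QR,
  MQM, SAP, NUMALT, ...) are filtered
  (`QUAL > 1 & NUMALT < 2 & SAF > 1 & SAR > 1`), the germline calls are
  subtracted on matching (CHROM, POS, ALT), calls whose per-strand
  alternate-allele fraction differs by more than 4× between strands are
  removed, and a final count/quality filter
  (`AO > 10 & RO > 10 & QA > 100 & QR > 100 & AO < 100 & RO < 100 &
  SAP < 30 & MQM > 55`) yields the somatic set, with per-stage counts and
  call-set overlap reporting.
* **Somatic SV derivation and benchmarking.** Germline SVs are subtracted
  from the tumour SV set when type matches and both breakpoints agree within
   (germline length)/100 bases; the survivors are filtered to precise calls
  over 10 kb away from the decoy contig (imprecise calls with AF > 0.2 are
  side-tracked for review). Call sets from multiple methods are clustered
  into unique variants, and labelled variants are scored per SV type with
  `FNR = missed true / total true` and `FDR = false calls / total calls`.
* **Windowed copy number with purity and ploidy.** Per-window log ratios
  `R(w) = log2(T(w)/N(w)) − offset` (windows with
  `N(w) ≤ mean(N) − 2·sd(N)` masked) are segmented by circular binary
  segmentation (permutation-tested splits, `alpha = 0.01`, `min.width = 5`,
  sd-undo at 3 SDs), segment means are recentred on the ploidy-2 baseline,
  tumour purity α is estimated by inverting the mixture model
  `m(p) = log2((α·p + 2(1−α))/2)` over the ploidy-1/3/4 segment-mean
  clusters, and each segment is classified to the nearest theoretical mean
  for ploidy 0–6 (germline ploidy 1 on sex chromosomes).
* **Cis/trans phasing of a somatic SNV against a heterogeneous deletion.**
  With tumour purity π% and a deletion carried by x% of cells, the expected
  SNV read fraction is at most `(π − x)/(200 − x)` in cis and `π/(200 − x)`
  in trans; an observed VAF above the cis maximum π/2 supports the trans
  configuration. A majority-vote haplotagger assigns long reads to phased
  haplotypes and tabulates per-site REF/ALT counts per haplotype.

Seeded generators (`simulateSmallVariants`, `simulateSvSets`,
`simulateWindowCounts`, `simulatePhasedReads`) produce every input the
pipelines consume, with truth tables, so all stages run and are tested
without any external data.

## Worked example

Simulate a chromosome-17-style tumour/germline pair (1000 germline
heterozygous SNVs shared by both samples, 20 clonal somatic SNVs at purity
0.6-ish VAF, plus strand-artifact and multi-allelic decoys) and run the
subtraction pipeline:

```r
library(tnsomatic)

sim <- simulateSmallVariants(simConfig(seed = 7))
res <- runSnvPipeline(sim$tumour, sim$germline)
res$report
#>                 stage    n
#> 1        input_tumour 1031
#> 2            snv_only 1031
#> 3      initial_filter 1020
#> 4 germline_subtracted   20
#> 5  strand_bias_filter   20
#> 6        final_filter   20
```

The initial filter removes the five strand-artifact calls (all alternate
observations on one strand fail `SAR > 1`) and the six records from
multi-allelic sites (`NUMALT < 2`); germline subtraction removes all 1000
planted germline variants; the 20 survivors are exactly the planted somatic
SNVs (`sim$truth` confirms).

The cis/trans model at the published purity of 60%:

```r
expectedVafCis(60, 0)    # cis maximum, deletion cell fraction 0
#> [1] 30
expectedVafTrans(60, 60) # trans bound at full deletion cell fraction
#> [1] 42.85714
classifyConfiguration(PhasingScenario(60, 40, observedVafPct = 44))
#> $configuration
#> [1] "supports_trans"
#> $margin
#> [1] 14
```

An observed somatic VAF of 44% exceeds the cis ceiling of 30%, so the SNV
must lie on the non-deleted haplotype (trans).

Copy number, purity and ploidy from simulated whole-genome window counts
(tumour gains chromosome 3 to four copies, 7 and 18 to three, loses one
copy of 17 and all of Y, at purity 0.63):

```r
sim <- simulateWindowCounts(simConfig(seed = 1))
res <- runCnaPipeline(sim$counts, CbsParams(seed = 1))
purity(res$model)
#> [1] 0.6181245
subset(segTable(res$segments), chrom %in% c("c3", "c7", "c17", "Y"))
#>    chrom first_window last_window n_windows   seg_mean ploidy_call
#> 3     c3         4921        6900      1953  0.6952444           4
#> 7     c7        12331       13920      1570  0.3993406           3
#> 17   c17        24991       25800       800 -0.5268123           1
#> 24     Y        30341       30927       370 -1.6968400           0
```

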