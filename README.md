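# ampsim

Simulation and truth-based assessment of PCR artifacts in 16S rRNA
amplicon sequencing data.

## The problem

Amplicon surveys observe a microbial community through a PCR, and the
PCR leaves fingerprints: polymerase misincorporation, template-switch
chimeras, preferential amplification of some templates (bias), and
run-to-run stochastic drift — all growing with the number of
amplification rounds. With a mock community of known reference
sequences these artifacts can be measured exactly, because every read
can be traced to the reference (or pair of references) it came from.
`ampsim` is for researchers and pipeline developers who want to
quantify how polymerase choice and cycle number distort amplicon data,
and to test curation steps (denoising, chimera screening, OTU
clustering, diversity statistics) against a known truth.

The package couples:

* a **count-space PCR simulator** — per cycle, every molecule
  duplicates with its template's efficiency *p*; new copies acquire
  Poisson(rate × length) substitutions and indels that descendants
  inherit; with probability *c* a copy is instead a single-breakpoint
  chimera joining the template's prefix to the aligned suffix of an
  abundance-weighted partner; template ratios under bias compound as
  (1+p₁)ᶜʸᶜ/(1+p₂)ᶜʸᶜ; reads are drawn multinomially with residual
  sequencing substitutions;
* the **truth machinery** used with mock communities — the exhaustive
  library of bimeras between reference pairs; the margin rule that
  calls a sequence chimeric when it is ≥ 3 bases closer to a chimera
  than to any single reference; the chimera-excluded error rate
  (subs + ins + dels per base against each sequence's best reference);
  the dominant:rare intra-genome variant ratio;
* **curation and detection** — 2-nt abundance preclustering
  (denoising), and a deterministic UCHIME-style de novo detector whose
  sensitivity/specificity can be evaluated against truth labels;
* **community statistics** — abundance-greedy 3% OTU clustering,
  rarefaction, richness/Shannon/Good's coverage, Bray-Curtis distances
  (Σ|x−y| / Σ(x+y)), PCoA, a from-scratch sequential-SS PERMANOVA
  (cross-checked against `vegan::adonis2`), a three-stage attribution
  analysis separating pure amplification bias from residual errors and
  imperfect chimera removal, and intercycle/replicate-drift distance
  summaries.

## A worked example

Simulate the packaged 8-organism mock community (nine synthetic 250-nt
references; one organism carries two variants of its amplicon at a 6:1
copy ratio differing by a single base) through 30 cycles with two
polymerase presets, then measure artifacts against the truth:

```r
library(ampsim)
cm <- example_community()
cl <- truth_classifier(cm, margin = 3)

for (pol in c("KAPA", "Platinum")) {
  rs <- sample_reads(
    simulate_pcr(cm, polymerase_profile(pol), cycles = 30,
                 initial_molecules = 1000, seed = 7),
    depth = 5000, seq_sub_rate = 2e-4, seed = 8)
  tab <- precluster(dereplicate(rs), max_diffs = 2)
  er <- error_rate(tab, classifier = cl)
  cr <- truth_chimera_rate(tab, classifier = cl)
  cat(sprintf("%-9s error rate %.4f%%  chimera rate %.2f%%\n", pol,
              100 * er$error_rate, 100 * cr$chimera_rate))
}
#> KAPA      error rate 0.0002%  chimera rate 1.18%
#> Platinum  error rate 0.0192%  chimera rate 9.44%
```

The high-fidelity preset leaves a denoised error rate two orders of
magnitude lower and an order of magnitude fewer chimeric reads than the
error-prone, chimera-prone preset — the numeric rates are preset
calibrations, but the orderings are the point. Downstream, the truth
screen plus 3% clustering recovers exactly the community's 8 OTUs, and
the variant ratio estimates the 6:1 template mixture:

```r
rs  <- sample_reads(simulate_pcr(cm, polymerase_profile("Platinum"), 30,
                                 1000, seed = 7), 5000, 2e-4, seed = 8)
tab <- precluster(dereplicate(rs), 2)
lab <- classify_table(tab, cl)
ot  <- cluster_otus(tab[!lab$is_chimeric[match(tab$sequence,
                                               lab$sequence)], ], 0.03)
print(ot)
#> OTU table: 1 samples x 8 OTUs; totals 4528-4528
print(alpha_diversity(ot))
#>          sample sobs  shannon goods_coverage
#> 1 Platinum_30_0    8 2.026306              1
variant_ratio(dereplicate(rs), "org3_v1", "org3_v2", classifier = cl)
#> [1] 7.75   # single sample at depth 5000; only ~20 rare templates seed
#>            # the reaction, so per-run estimates scatter around 6
```

`run_experiment_grid()` scales this to a full polymerase × cycles ×
replicate design with one master seed, and `attribution_pipeline()`,
`intercycle_distance()`, `replicate_drift()`, `permanova()` summarize
the community-level consequences.

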