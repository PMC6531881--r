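---
title: "Simulating and assessing PCR artifacts in amplicon sequencing"
author: "ampsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and assessing PCR artifacts in amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampsim)
```

## The problem

Community profiling by 16S rRNA gene amplicon sequencing observes a
community only through a PCR. The polymerase misincorporates bases, the
reaction forms template-switch chimeras, templates amplify with unequal
efficiencies, and independent reactions drift apart stochastically. All
four artifacts grow with the number of amplification rounds, and their
community-level footprint (inflated richness and diversity, shifted
ordinations) depends on how aggressively the downstream curation
pipeline denoises and screens chimeras.

With a mock community of known reference sequences, each artifact can be
measured exactly: every read can be aligned back to the reference it
came from, every possible two-parent chimera can be enumerated, and the
difference between the expected and observed community can be
attributed. `ampsim` packages this truth-based assessment machinery
together with a simulator of the amplification process itself, so that
the whole pipeline — simulation, curation, truth classification,
detection, and community statistics — can be exercised and tested
end to end without any sequencing data.

## The simulation model

`simulate_pcr()` runs a per-cycle branching process in *count space*:
the pool is a multiset of unique (sequence, provenance) molecules with
counts, not individual agents. Each cycle, for every molecule entry:

* the number of new copies is binomial in the entry's count with its
  per-template efficiency (a probability in (0, 1]; per-reference
  efficiencies encode amplification bias);
* each new copy acquires `Poisson(sub_rate * length)` substitutions and
  `Poisson(indel_rate * length)` single-base indels at uniform
  positions. Copies of an erroneous molecule inherit its errors —
  mutation history is genealogical, which is what makes early-cycle
  errors abundant and gives abundance-based denoising something to do;
* with probability `chimera_prob` the new copy is instead a
  template-switch chimera: the template's prefix up to a uniform
  interior breakpoint joined to the suffix of a partner molecule drawn
  abundance-proportionally from the start-of-cycle pool. The suffix is
  taken at the *aligned* coordinate of the partner's reference (the
  package precomputes a coordinate map from the global alignment of
  every ordered reference pair), so an error-free template switch
  between two references reproduces a member of the exhaustive bimera
  library exactly. Partner molecules with indels are mapped
  proportionally, a deliberate approximation that avoids a fresh
  alignment per switch event; at the default indel rates
  (`sub_rate / 10`, i.e. about 1e-6 per base) such events are a small
  minority of switches. A switch onto a partner of the *same* reference
  lineage is emitted as a plain duplication, because the join of two
  faithful copies of one reference *is* that reference — tagging it
  chimeric would make the truth tags unsound.

When the total count would exceed `pool_cap` (default 1e6) the pool is
downsampled multinomially back to the cap. This preserves expected
proportions while bounding memory; the distortion it introduces is the
same kind of multinomial noise as the final sequencing step, applied
earlier. `sample_reads()` finishes the virtual experiment: `depth` reads
multinomial in molecule counts, plus per-read
`Poisson(seq_sub_rate * length)` substitutions for residual sequencing
error. Substitution-only sequencing noise reflects assembled paired-end
contigs, whose dominant residual artifact is substitutions; indels enter
through the polymerase model. Every read carries its molecule's truth
provenance (source reference, or chimera parents and breakpoint, and
accumulated error count).

All randomness flows from integer seeds; `run_experiment_grid()` derives
a distinct stream per (polymerase, cycles, replicate) run from one
master seed, so a whole experiment is reproducible from a single
integer. Optional per-replicate lognormal jitter of the efficiencies
(`efficiency_sd`) models tube-to-tube drift.

### Polymerase presets

The five presets (`Accuprime`, `KAPA`, `Phusion`, `Platinum`, `Q5`) are
calibration choices, not measured constants. What they encode is the
documented relative structure of such enzymes: two fidelity classes
roughly tenfold apart (substitution rates 1.0-1.2e-4 for Accuprime and
Platinum versus 1.0-1.2e-5 for KAPA, Q5 and Phusion, all distinct so the
ordering is strict, with KAPA lowest), `indel_rate = sub_rate / 10`, and
template-switch probabilities between 0.001 (KAPA) and 0.008 (Platinum).
No claim is made that these reproduce any particular instrument's
absolute error or chimera percentages; the package's tests assert
orderings and trends, not preset-specific values.

## One alignment, one distance

Every distance in the package comes from a single global aligner
(match +1, mismatch -1, gap open -2, gap extend -1, end-to-end,
deterministic tie-breaking that prefers substitutions over indels):

* `align()` reports substitutions, inserted and deleted bases; their sum
  is the *distance* between two sequences;
* *dissimilarity* is (mismatches + indel columns) / alignment columns,
  used by `reference_otu_map()` and `cluster_otus()`. All indel columns
  are counted, including terminal ones; for same-length amplicons under
  an end-to-end aligner the distinction from internal-only counting is
  immaterial, and counting all columns makes the pruning bound below
  provably lossless;
* the 2-nt preclustering rule and the chimera classifier both count
  alignment operations.

Two lossless accelerations keep the exhaustive machinery fast. A banded
unit-cost Levenshtein bound underlies every thresholded comparison (any
alignment's operation count is at least the unit edit distance). The
chimera classifier additionally indexes the bimera library by 4-mer
profiles and scans candidates in order of the q-gram lower bound
`distance >= L1(profiles) / (2k)`, stopping when the bound exceeds the
best distance found; tests assert exact agreement with the unpruned
scan.

## Ground truth machinery

`build_chimera_library()` enumerates every single-breakpoint bimera of
every ordered reference pair at every interior column of their global
alignment, deduplicates, and drops candidates identical to a reference.
`classify_sequence()` calls a query chimeric when it is at least
`margin` (default 3) bases closer to some library bimera than to any
single reference; non-chimeric queries get substitution/indel counts
against their best reference (ties to the lexicographically smallest
id). `error_rate()` excludes chimeric sequences and reports
count-weighted errors per base; the measured rate deliberately conflates
polymerase and sequencer errors, as does the quantity it estimates.
Multimeras (three or more parents) are outside the library by design —
the truth screen considers chimeras between pairs — so later-generation
nested switches are classified by whatever bimera or reference they most
resemble.

The margin rule has a consequence worth knowing: an error-free bimera
whose breakpoint sits within `margin` bases of its parents' nearest
divergent site is *not* called chimeric, because it is nearly identical
to a parent. Such borderline molecules also sit within a couple of
operations of a reference, so they fold back into their parent's OTU
rather than inflating richness.

## Curation and detection

`precluster()` implements greedy 2-nt abundance denoising with a fully
specified visit order (decreasing abundance, ties lexicographic; merge
into the first retained sequence within `max_diffs` operations; single
pass, no transitive re-merge). The full specification makes the
operation deterministic and order-invariant, which the suite asserts by
permuting inputs. The exact tie-breaking of widely used implementations
is not documented; this one is a package decision.

`detect_chimeras()` is a UCHIME-style stand-in, not a clone: real
detectors are treated as black boxes with imperfect sensitivity, and the
package needs a deterministic detector whose sensitivity and specificity
*can be measured* against truth labels. Queries are processed in
decreasing abundance; candidate parents must be previously accepted
sequences at least `min_parent_fold` (default 2) times as abundant; the
best single-breakpoint two-parent model is scored by query positions
explained by one parent but not the other on each side of the
breakpoint, minus positions explained by neither; flagging requires
score >= 2 and at least 2 fewer differences than the best single parent.
When many parents qualify, the 20 with the closest 4-mer profiles are
examined, mirroring k-mer candidate selection in real detectors.
`evaluate_detector()` computes sensitivity and specificity against truth
labels, unweighted or abundance-weighted.

## Community-level analyses

OTU clustering is abundance-greedy radius clustering at 3%
dissimilarity against founding representatives. Optimizing assignment
algorithms are deliberately out of scope: the community-level claims the
package tests concern trends across PCR conditions, and greedy radius
clustering is fully specifiable and order-independent. Shannon diversity
uses natural logarithms. Good's coverage is 1 - singletons/reads.
Rarefaction subsamples without replacement to a common depth (default:
the smallest sample total), dropping and reporting samples below depth.
Bray-Curtis distances come from `vegan::vegdist`; PCoA is classical
scaling with negative eigenvalues reported and a fixed sign convention.

`permanova()` is a from-scratch sequential (Type I) partition of the
Gower-centered distance matrix with free label permutation and the
`(1 + exceedances) / (1 + permutations)` p-value estimator, so p is
never 0. Factor order matters under sequential sums of squares and is
the caller's choice. The implementation is cross-checked against
`vegan::adonis2` in the test suite (R-squared and pseudo-F agree to
1e-10) and its type-I error is verified to be calibrated at the 5% level
over 200 null simulations.

`attribution_pipeline()` reproduces the three-stage artifact attribution
design: (1) chimera-tagged reads dropped and remaining reads mapped to
the OTUs their source references would form with no errors (pure
bias/drift); (2) observed sequences dereplicated, preclustered,
truth-screened and clustered (residual errors, perfect chimera removal);
(3) the same but with the de novo detector (the realistic pipeline).
Stage 1 requires truth tags; stage 2 applies the margin classifier to
dereplicated sequences, since sequences — not reads — are the unit the
screen operates on after dereplication. `intercycle_distance()` and
`replicate_drift()` summarize amplification bias (mean Bray-Curtis to a
25-cycle baseline) and stochastic drift (mean pairwise Bray-Curtis among
replicates).

## The packaged community

`example_community()` loads a fully synthetic 8-organism community: nine
250-nt references with operon copy numbers between 4 and 10 mixed at
equal genomic abundance (template proportions proportional to copy
number), one organism carrying two intra-genome variants of its amplicon
at a 6:1 copy ratio that differ by a single T→G substitution. This
mirrors the *structure* of commercial 8-member mock standards — in
particular the variant pair enables the dominant:rare ratio analysis,
expected near 6 under unbiased amplification — without reproducing any
vendor sequence. All members are more than 10% divergent except the
variant pair, so the community forms exactly 8 OTUs at 3% dissimilarity.

## What the simulator does and does not emulate

It emulates: per-cycle misincorporation with genealogical inheritance,
single-breakpoint template switching with abundance-proportional partner
choice, per-template efficiency bias compounding as (1+p)^cycles,
replicate drift, multinomial sampling, and residual sequencing
substitutions. It does not emulate: primer annealing thermodynamics,
quality scores, paired-end assembly, GC- or length-dependent efficiency
(deliberately — per-template efficiencies are free parameters instead),
or multi-breakpoint chimera formation. Passing tests therefore
demonstrate the internal consistency and calibration of the assessment
machinery on data matching these assumptions, not the behavior of any
particular polymerase or sequencer on real communities.

## Problem sizes and numerical choices

The test suite runs simulations at deliberately desk-friendly sizes
(4-member communities of 120-150 nt, depths of 500-5000, pool caps of
5e4-1e6, ten seeds per trend) chosen so the full suite exercises every
claim — including a complete 5-polymerase x 4-cycle-count x 4-replicate
grid at depth 5000 — in minutes on one CPU. Error-free doubling,
conservation, determinism and truth-tag soundness are asserted exactly;
stochastic recoveries (variant ratio, multinomial proportions,
efficiency compounding) are asserted within three standard errors;
estimator recovery within 20% relative error; trend claims as orderings
of means over ten seeds. Degenerate inputs (empty libraries for
one-base-apart reference pairs, all-chimeric samples, sub-depth samples,
single-level factors) return flagged results or errors as documented
rather than silent values.
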