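---
title: "Filtering spurious taxa from 16S rRNA amplicon count tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering spurious taxa from 16S rRNA amplicon count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spuria)
```

## The problem

16S rRNA gene amplicon profiling reports operational taxonomic units (OTUs)
or amplicon sequence variants (ASVs) that are not real members of the
sequenced community: cross-contamination between co-multiplexed samples
(e.g. index hopping), reagent DNA, PCR and sequencing errors that escape
denoising, and low-abundance "satellite" variants of true taxa. Benchmarks
against communities of known composition — in vitro mock standards and
gnotobiotic animals colonized with defined strains — show that such spurious
taxa can constitute half or more of all reported taxa, while carrying only
about 1% of the reads. They barely perturb composition but severely distort
diversity readouts: richness inflates with sequencing depth, varies between
sequencing runs of the same sample, and presence/absence-based
beta-diversity metrics absorb the noise.

The conventional mitigation, removing *singletons* (taxa represented by one
read across all samples), treats a one-read taxon in a 100-read sample the
same as in a 100,000-read sample and leaves most contaminants (which
typically have more than one read) untouched. A *relative-abundance*
cutoff — keep a taxon only if it exceeds a small proportion in at least one
sample — is depth-aware, and reference-community benchmarks locate an
effective consensus value at 0.25%: nearly all first-occurring spurious
taxa sit below it.

`spuria` implements that benchmarking workflow end to end, plus the
diversity statistics used to measure its consequences, and a synthetic-data
generator with ground-truth labels so every claim is testable without
access to raw sequencing data.

## Filtering rules

For a count table $n_{ij}$ (taxon $i$, sample $j$) with per-sample
proportions $p_{ij} = n_{ij} / \sum_i n_{ij}$:

* **Singleton removal** deletes taxa with $\sum_j n_{ij} = 1$. It is a
  raw-count concept; non-integer tables are rejected.
* **Relative-abundance filtering** at cutoff $t$ keeps taxon $i$ iff
  $\max_j p_{ij} > t$, with proportions computed on the *unfiltered* table
  and retained counts left untouched (no re-normalization). The default is
  $t = 0.0025$.

The boundary is **strict**: a taxon exactly at the cutoff is removed. This
choice keeps three formulations of the same idea mutually consistent —
"occurring above 0.25%", the effective-richness definition below, and the
reads-based phrasing "remove taxa occurring below 2.5 counts per 1000
reads" (a tie at 2.5 counts is removed in all three). Whether existing
pipeline implementations treat the boundary as `>` or `>=` is generally
undocumented; since ties have probability near zero on real data, the
choice matters only for internal consistency.

Two normalizations are provided because both are in common use:
`normalize_min_sum()` (deterministic scaling to the minimum sample sum,
which preserves proportions exactly) and `rarefy()` (random subsampling
without replacement to a fixed depth, seeded and RNG-state-preserving).

## Reference matching

Observed representative sequences are classified against the reference
community by semi-global alignment: the query is aligned end-to-end
against the best-fitting region of the reference (reference end gaps
free), scoring match +1, mismatch −1, affine gaps open 5 / extend 2 — the
classic `blastn` gap costs. With these costs, $k$ scattered substitutions
in a length-$L$ query score identity exactly $(L-k)/L$; a cheaper linear
gap penalty would let one-base shifts occasionally "rescue" a mismatch and
blur the decision boundary, which matters because the positive-hit rule is
a sharp threshold:

* **identity** = matching columns / all alignment columns (gap columns
  count as mismatches, `N` never matches);
* **coverage** = query bases aligned to reference bases / query length
  (insertions and overhang reduce it);
* **positive hit** iff identity ≥ 0.97 and coverage ≥ 0.90; best reference
  chosen by identity, then coverage, then lexicographic id (fully
  deterministic).

An e-value criterion is deliberately omitted: e-values depend on database
size and add nothing for a closed reference set of a few sequences. For
ASV-style analyses, `classify_by_hamming()` implements the exact-sequence
rule instead: matched iff the minimum Hamming distance to an equal-length
reference is ≤ 1. For generator output, `classify_by_label()` consumes the
ground-truth labels directly, so downstream benchmarking can be tested
independently of alignment.

`collapse_redundant()` provides greedy centroid clustering at 97% identity
(longest-first, deterministic tie-breaks) to de-duplicate spurious
sequences pooled across sequencing runs before prevalence analysis.

## Benchmark statistics

`benchmark_sample()` applies a filter and reports, per sample: the fraction
of retained (nonzero) taxa that are spurious; the fraction of reference
members detected by at least one retained matched taxon (*positive hits* —
counting members, not matched taxa, so satellites cannot push it above
100%); the cumulative relative abundance of retained spurious taxa; and
the relative abundance of the first (most abundant) spurious taxon in the
unfiltered sample. Per-sample denominators count only taxa present in that
sample, and dataset-level numbers are reported as mean ± SD over replicate
samples. `threshold_sweep()` traces both fractions over a cutoff grid
(default 0–0.5% in 0.05% steps, 11 points); both curves are non-increasing
in the threshold because the filters are nested.

## Alpha diversity and reproducibility

* **Richness**: taxa with nonzero count. Depth-dependent.
* **Effective microbial richness (EMR)**: taxa with $p_{ij} >$ cutoff
  (default 0.25%). Scale-invariant, hence unaffected by depth or scaling
  normalization; equivalently the count of taxa above 2.5 counts after
  rescaling to 1000 reads.
* **Shannon effective count**: $\exp(-\sum p \ln p)$, natural log
  (the Rhea convention; the base is a convention choice and only rescales
  the entropy, not the effective number's interpretation as "k for k
  equally abundant taxa").
* **IQR of richness** per subject across time points uses type-7
  (linear-interpolation) quantiles — the R default, chosen for
  cross-platform reproducibility.
* **Coefficients of variation** use the $n-1$ standard deviation.
  Within-run CV is computed over technical replicates inside a run;
  across-run CV over the per-run replicate means of the same sample, i.e.
  the run-to-run irreproducibility that stringent filtering is supposed to
  reduce (pooled replicates would conflate the two levels).

## Phylogenetic beta diversity

For each branch $b$ with length $L_b$, let $p_b^A$ be the fraction of
sample $A$'s reads descending from $b$. Then

* unweighted UniFrac
  $= \sum_b L_b\,[\text{present in exactly one sample}] \big/
     \sum_b L_b\,[\text{present in at least one}]$,
* generalized UniFrac
  $= \sum_b L_b (p_b^A + p_b^B)^\alpha \frac{|p_b^A - p_b^B|}{p_b^A + p_b^B}
     \big/ \sum_b L_b (p_b^A + p_b^B)^\alpha$
  over branches with $p_b^A + p_b^B > 0$, with $\alpha = 0.5$ by default
  and $\alpha = 1$ equal to weighted-normalized UniFrac.

Branches above the common ancestor of all observed taxa have equal
descendant proportions (both 1) in the two samples and cancel, so rooting
detail is immaterial; missing Newick branch lengths are read as 0 and
contribute nothing. The implementation shares an edge-by-tip incidence
matrix across pairs (`distance_matrix()`); tests verify it exhaustively
against a naive branch-enumeration oracle on all 13 rooted binary shapes
with 2–6 leaves and against `phyloseq::UniFrac`. Proportions for UniFrac
are computed after whichever filter the analysis specifies — the filter's
effect on beta diversity is precisely the object of study, so it is an
explicit input, not a hidden default.

## Prevalence and exclusivity of spurious taxa

Given an occurrence map (relative abundances of spurious clusters across
samples of several categories), prevalence in a category is the percentage
of its samples above the 0.25% positivity threshold. Samples with no hit
to any spurious cluster are excluded from denominators by default, since a
zero there cannot be distinguished from a primer-region mismatch; a flag
disables this. Exclusivity of a cluster for its top category is tested
against the runner-up category with a pooled two-proportion z-test
(two-sided, no continuity correction — the intended regime is dozens to
thousands of samples per category), Benjamini–Hochberg adjusted across
clusters. The variant of z-test (top vs runner-up rather than vs all
others pooled) is a design choice: it is the most conservative pairwise
contrast that still answers "is this taxon specific to one habitat".
`run_redundancy()` counts, per spurious cluster, the sequencing runs it
appears in; run-exclusive clusters indicate sporadic cross-contamination
rather than generalist artifacts.

## The synthetic generator

`synthetic_design()` / `simulate_study()` emulate the benchmark study
designs with known ground truth. Default parameters are fixed once, as the
conditions the benchmarks assume:

| parameter | default | rationale |
|---|---|---|
| true community | 8 members; even, log (10-fold dilutions) or geometric profile | size and profiles of commercial DNA standards |
| sequencing depth | Normal(25 000, 7 000), truncated at 1 000, rounded | scale of the benchmark datasets |
| sequence length | 250 nt | typical merged V3–V4/V4 read |
| contaminants | pool of 25 per run; each enters a sample with prob. 0.8; individual abundance log-uniform 0.01–0.15%; rescaled to a cumulative target of 1% per sample (cap at the individual ceiling) | spurious taxa are individually rare but collectively ~1% of reads |
| run structure | pool overlap prob. 0.1 between runs | most contaminants are run-exclusive |
| satellites | Poisson(0.5) per true taxon, 1–3 substitutions, abundance 0.005–0.1% | sequencing-error variants that still match their parent at ≥97% identity |
| singletons | Poisson(1) artifacts per sample, count exactly 1 | the population that singleton filtering removes |
| subjects | lognormal(sd 0.75) perturbation of the profile per replicate group (multi-group designs only) | inter-individual variation of fecal communities |

The individual contaminant ceiling of 0.15% leaves a ≈4σ multinomial
margin below the 0.25% cutoff at the default depth, so the generator's
contract "the cutoff removes every contaminant" holds for realized counts,
not just for the underlying probabilities. Raising
`contaminant_max_abundance` to 0.0044 reproduces the outlier regime in
which a single contaminant crosses the cutoff.

All randomness derives from one master seed through fixed per-component
offsets (reference, per-run pools, satellites, tree, one stream per
sample), so output is bit-reproducible and adding samples or runs never
perturbs earlier draws. Functions that consume randomness save and restore
the caller's RNG state.

`simulate_depth_series()` models re-sequencing one library at increasing
cluster densities by *incremental* multinomial draws — the deeper sample
contains the shallower sample's reads. This makes richness monotone in
depth pathwise, as it is physically; independent draws per depth would
only be monotone in expectation.

**What the generator does not emulate:** chimeras, PCR-cycle and primer
bias, length variation and indel errors (mutations are substitution-only,
keeping identity and Hamming modes consistent), taxonomic structure in
contaminant sequences (they are uniform-random, hence trivially divergent
from references), and overdispersion beyond multinomial sampling.
Passing tests therefore demonstrate the correctness and internal
consistency of the statistics and of the filtering mechanism — not that
0.25% is optimal for any particular real dataset, where contaminant
abundance distributions may differ.

## Numerical choices and degenerate inputs

* Proportions are validated to sum to 1 within 1e-9; all-zero samples are
  an error wherever proportions are needed (richness alone tolerates
  them).
* Counts are stored as doubles; integer-ness is asserted only where the
  operation requires it (singleton removal, rarefaction), with tolerance
  1e-9.
* Tie-breaking is total-ordered everywhere (best reference: identity,
  coverage, id; clustering order: length, then id), so all outputs are
  deterministic.
* EMR's strict `>` together with exact rational arithmetic of counts means
  the 1000-read reformulation agrees exactly, including ties.
* The exhaustive UniFrac oracle test uses all rooted binary tree shapes
  with up to 6 leaves; shapes (not labeled trees) are the exhaustive
  object because UniFrac depends on the shape/length structure, and labels
  enter only through presence sets, which are enumerated completely.

## Problem sizes used in the test suite

The suite simulates its data at the study scale described above: 1000
random tables for the EMR equivalence; depth series 5k–500k; six
reference-community datasets for the sweep; 13 tree shapes × all
presence-set pairs plus 100 random 6-leaf instances for UniFrac; 100 × 11
substitution-count cases for the matching boundary; 100 multi-run studies
(6 groups × 3 replicates × 7 runs) for the reproducibility direction; 100
replicates of the exclusivity simulation at 50 samples per category.

## Known limitations

* The alignment is exact dynamic programming over full sequences; for
  thousands of observed taxa against large references a k-mer prefilter
  (as in production clustering tools) would be needed.
* `collapse_redundant()` is greedy and order-dependent by design (as are
  the field's standard tools); cluster counts near the threshold can
  differ from optimal clustering.
* The exclusivity test compares top vs runner-up only; an all-pairs option
  is a natural extension and the per-category counts are exposed so users
  can run any contrast.
* Trees are taken as given (or simulated); no alignment/tree inference is
  performed.
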