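---
title: "Methods: comparative genomics of diploid oat assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of diploid oat assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`avenacomp` implements the analysis chain used to anchor and interpret
chromosome-scale assemblies of the diploid oats (*Avena*, A and C genomes)
and to deconvolve the subgenomes of hexaploid oat (AACCDD): assembly
summary statistics, perfect-identity placement of 64-bp tag-level haplotype
markers, linkage-group assignment and collinearity-based chromosome-arm
merging, subgenome calling with intergenomic-translocation detection,
majority-rule synteny orthology, synonymous-divergence (Ks) estimation with
molecular-clock dating, SNP filtering with LD pruning and bootstrapped
neighbor-joining phylogenies, and tandem-repeat landscape profiling. A
synthetic-data generator produces all inputs together with ground-truth
tables, so the whole chain is testable offline.

# The synthetic truth set

`simulate_truth_set()` builds an `A` genome from i.i.d. background sequence
at 44% GC (the GC content typical of assembled oat and other cereal
genomes), then derives `D` and `C` genomes by per-site substitution at
configurable divergences (defaults: A→D 0.01, A→C 0.10 per site). The
ordering encodes the biology the downstream callers rely on: A and D are
the recently diverged pair, C is the distant genome. With 64-bp tags this
gives a perfect-match rate on the A reference of about
$0.99^{64} \approx 0.52$ for D-derived tags and essentially zero for
C-derived tags — the asymmetry that drives both homoeolog pairing and the
roughly two-fold difference in total placements between references.

Each chromosome carries planted satellite arrays: a genome-specific 159-bp
centromeric monomer (the unit length characteristic of grass centromeric
repeats) in a single pericentromeric array, and a 665-bp telomeric
sub-repeat near both ends. Arrays are exact tandem copies; each derived
genome gets its own monomer so that cross-genome repeat similarity is not
assumed. Gene intervals are non-overlapping and identical in coordinates
across the three genomes (mutation is substitution-only), which gives a
known one-to-one synteny map.

The genetic map is a cumulative recombination density along the
chromosome, uniform except for a 10-fold suppression inside the third of
the chromosome centred on the centromere. Published comparisons show
pericentromeric suppression spanning roughly five- to 200-fold; 10-fold is
a mid-range choice and any strictly positive suppression preserves the
monotone cM–bp relationship the merge planner needs.

Default sizes are desk-scale — three chromosomes of 2 Mb, 60 markers per
linkage group, 2000 codon-aligned gene pairs of 400 codons, 24 accessions
with 2000 sites — and every size is overridable. The generator emulates
the statistical structure the analyses assume (divergence asymmetry,
map compression, satellite dominance, clade structure), not read-level
noise: there is no sequencing-error or assembly-gap model, no indels, no
recombination within the genotype panel, and no repeat families beyond the
planted satellites. Tests passing on these bundles therefore demonstrate
correctness of the algorithms under their stated assumptions, not
robustness to raw-data artefacts.

# Marker anchoring and arm merging

`place_markers()` retains a tag only when it matches the reference exactly
and exactly once genome-wide over both strands; everything else is
rejected as `no_hit` or `multi_hit`. Discarding multi-hit tags entirely
(rather than keeping a best hit) mirrors the perfect-unique-identity
filter used against repeat-rich genomes. Internally placements are 0-based
starts; gene annotations are 1-based closed (GFF3) and bedGraph output is
0-based half-open.

`assign_linkage_groups()` tallies placements per scaffold by linkage
group; the plurality LG wins, exact ties break toward the
lexicographically smallest LG id and are flagged. Percentages are rounded
half-up to one decimal, matching table conventions. The summary reports
the total mismatch rate both as the mean of per-row percentages and as the
pooled count ratio, because the two differ slightly and either may be
wanted.

`infer_merge_plan()` requires at least two scaffolds claiming one LG, each
with three or more placements; scaffolds are ordered by the midpoint of
their cM spans and oriented by the sign of the Spearman correlation
between cM and physical position (fewer than three placements defaults to
`+` with a `low_evidence` flag). Overlapping cM spans beyond 1 cM raise a
conflict instead of a silent merge. `apply_merge()` joins arms head-to-tail
with 1000-N spacers — the gap convention of proximity-guided scaffolding —
reverse-complementing negative-orientation arms.

# Subgenome deconvolution

`call_subgenomes()` works from two placement contingency matrices (LG by
chromosome, one per reference). An LG is C-derived when its C-reference
count exceeds its A-reference count at least `c_ratio`-fold (default 2,
motivated by the observed roughly two-fold placement asymmetry). Remaining
LGs are grouped by their primary A chromosome; a group of two is a
homoeolog pair. Within a pair the A label goes to the LG with the higher
perfect-match *rate* on the A reference, computed over the markers not
placed on the C reference. A raw perfect-match *count* ordering is
equivalent for clean LGs but fails for a translocated LG — when a segment
of an A-derived LG moves to the C genome, the markers of that segment
leave the A tally, and the intact D homoeolog can overtake it. The rate
normalization restores the intended discriminator (A-derived tags place at
~100%, D-derived at ~50%). An optional prior-label file overrides the
data-driven ordering where historical designations exist.

LGs with substantial placements on both references (secondary count at
least half the primary, `slash_ratio = 0.5`) receive slash labels with the
larger segment first (e.g. `A/C`, `C/D`). No numeric threshold for
"substantial" is established in the literature; both ratios are exposed as
parameters.

`detect_translocations()` orders each LG's placed markers by cM, removes
isolated runs shorter than `min_segment_markers` (default 5) as strays,
and emits a call at every remaining switch of placement chromosome, with
the open cM interval between the flanking markers as the breakpoint
interval. Switches between references are intergenomic, within a reference
intragenomic.

# Synteny orthology

`call_orthologs()` computes, per query chromosome, the fraction of its
syntenic bp attributable to each partner chromosome; a partner above 50%
is the ortholog, otherwise the chromosome is `split`. The denominator is
the sum of block footprints on the query side with overlapping blocks
merged first, so double-covered query sequence is not counted twice.
Blocks are read either from a per-block TSV or from a DAGchainer-style
file (header line per block, one row per gene pair).

# Ks and the molecular clock

`ks_ng86()` implements the Nei–Gojobori (1986) counting method:
synonymous sites per codon are the fractions of the three possible changes
per position that preserve the amino acid (changes to stop codons count as
nonsynonymous, keeping the three-change denominator); multi-difference
codons average synonymous/nonsynonymous differences over all minimal
substitution pathways, excluding pathways through stop codons (falling
back to all pathways only if every one is blocked); and the proportion
`pS = Sd/S` is Jukes–Cantor corrected,
$K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$, undefined (flagged
saturated) at $p_S \ge 3/4$. NG86 with JC correction stands in for a
maximum-likelihood codon model: it is deterministic, assumption-light, and
its counting can be verified exhaustively against a brute-force pathway
enumerator, which the test suite does for all short inputs. Estimates from
the two families agree closely at the low divergences relevant here
(Ks ≈ 0.1–0.3); no claim of ML equivalence is made at high divergence.

The distribution peak is estimated by a fixed-width histogram
(`bin_width = 0.005`), reporting the centre of the fullest bin with ties
to the smallest centre — deterministic and seed-free, unlike a bandwidth-
dependent kernel mode. The clock is the strict relation $K_s = 2rT$:
`calibrate_rate()` divides a calibration Ks by twice the node age,
`divergence_time()` inverts it. The generic eukaryotic synonymous rate
8.1e-9 per site per year is shipped as a named constant
(`EUKARYOTIC_SYNONYMOUS_RATE`), externally sourced from the standard
literature value.

The pair generator draws each pair's target Ks from a truncated normal
(default peak 0.0875, dispersion 0.01) and applies exactly
`round(pS * S)` synonymous substitutions at third positions of fourfold-
degenerate codon families whose first two positions are always
nonsynonymous (Val, Ala, Gly, Thr, Pro, the TCN serines), so each codon
contributes exactly one synonymous site and the realized NG86 value is
known in closed form. The dispersion models a dated orthologous-divergence
peak, not the full mixture of ancient duplications that a whole-paranome
Ks distribution would show.

# SNP filtering, LD pruning and trees

`filter_sites()` applies, in order and with first-rule attribution:
unplaced chromosome, any missing call (a 0%-missing policy), heterozygous
fraction strictly above 5% (in a highly inbred, cleistogamous panel excess
heterozygosity flags spurious read mapping; the strict reading of
"> 5%" keeps a site at exactly 5%), and minor allele frequency below 0.1
(the conventional reading of an MAF threshold of 0.1; heterozygotes count
half a dose). `ld_prune()` is the greedy left-to-right windowed scheme:
a site is dropped when its squared dosage correlation with any retained
site within 500 kb upstream exceeds 0.1; monomorphic sites are dropped
with their own reason. After pruning, no retained pair within a window
exceeds the threshold — asserted directly in the tests.

`build_tree()` computes pairwise p-distances on allele dosage, runs
neighbor joining (the `ape` implementation; on an exactly additive matrix
NJ reproduces the generating metric, which the tests check to 1e-9
against a brute-force oracle), roots on the designated outgroup, and
attaches bootstrap support by resampling site indices — accession order
therefore cannot affect supports. NJ on p-distances replaces an ML tree
engine; the acceptance surface is topology and support recovery, not
likelihoods.

One interaction deserves emphasis: the simulated panel has no
recombination, so linkage never decays with distance and sites sharing a
clade pattern are perfectly correlated across a whole chromosome. Windowed
r²-pruning on such data keeps roughly one site per pattern per window —
far more aggressive than on real panels, where LD decay leaves hundreds of
weakly correlated sites per window. The pipeline therefore reports the
pruned matrix as its own artifact but builds the tree from the filtered
matrix; on real, recombining data the conventional filter → prune → tree
order is the intended usage (`build_tree()` accepts either).

# Repeat landscape

`find_tandem_monomers()` uses the most-common-repeat heuristic for
centromere discovery: in repeat-dominated plant genomes the most abundant
tandem monomer is the putative centromeric satellite. Candidate periods
are seeded from the spacing of repeated 13-mers; for each period *p*,
positions matching the position *p* bases downstream score +1 and
mismatches score −(1−d)/d (d = `max_divergence`, default 0.2), and
maximal positive-scoring segments — extracted by a Kadane-style scan over
the run-length encoding — are arrays if they reach `min_copies` (default
5) and stay within the divergence budget. Random background (25% chance
matches) scores negative throughout, and a segment must accumulate at
least one full period of net match, which suppresses spurious seeds.
Monomers are reduced to their primitive unit and canonicalized as the
lexicographically minimal rotation over both strands; ranking is by total
array bp.

`density_track()` counts monomer occurrences (both strands, Hamming
budget `max_mismatch_fraction`, default 0.1) greedily and without overlap,
assigning each occurrence to the window of its start — so each satellite
base is counted once and tracks are additive. The centromere call is the
count-weighted centroid of the contiguous non-empty window run around the
global maximum; arms are measured from that midpoint and classified by the
Levan-style arm-ratio cutoffs (metacentric < 1.7, submetacentric ≤ 3.0,
sub-telocentric ≤ 7.0, telocentric beyond), all configurable since the
morphology classes are conventional rather than derived. Telomere clusters
within 5% of a chromosome end are `terminal`, otherwise `interstitial`;
the 5% cutoff quantifies a qualitative "distal" description and is
exposed as `terminal_fraction`.

`scan_ssrs()` reports maximal perfect tandem runs of primitive 2–4 bp
units at conventional minimum copy numbers (di ≥ 6, tri ≥ 5, tetra ≥ 5),
with motifs canonicalized like monomers.

# Pipeline and determinism

`run_pipeline()` executes simulate → stats → anchoring → subgenome →
synteny → Ks clock → SNP tree → repeats, writing every artifact under one
directory with an md5 manifest. A single global seed fans out to per-stage
seeds by stable hashing of stage names, so adding a stage never perturbs
the random stream of another; two runs with the same configuration produce
identical checksums. The demo configuration plants its A/C translocation
at 60 cM — the midpoint of the genetic map — because map compression over
the pericentromeric third makes low-cM segments physically small, and at
desk scale a 40-cM breakpoint can leave fewer markers than the segment
minimum on one side.

Problem sizes used by the test suite and the acceptance script: bundles of
three 2-Mb (tests also use 300-kb) chromosomes, 2000 Ks pairs per
replicate with 20 replicates per peak value, 24-accession panels with 2000
sites and 200 bootstrap replicates. These sizes keep each property check
well-determined while the whole chain remains runnable in minutes.

# Known limitations

* Marker placement is exact-match only; there is no approximate alignment
  engine, by design.
* NG86 is a counting estimator; transition/transversion bias and codon
  frequencies are not modelled.
* The subgenome caller's A/D disambiguation is data-driven and assumes the
  divergence asymmetry; where historical subgenome designations exist they
  can and should be supplied as prior labels.
* Tandem-array detection assumes arrays are locally homogeneous; highly
  diverged higher-order repeat structures would be reported as fragmented
  arrays.
* The genotype generator has no recombination, no missing-at-random
  structure beyond Bernoulli contamination, and star-shaped clades; it
  validates bookkeeping and recovery, not population-genetic realism.
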