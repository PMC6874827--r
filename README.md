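# avenacomp

Comparative genomics of diploid oat (*Avena*) assemblies, as a tested,
offline-runnable R pipeline.

Chromosome-scale assemblies of the A- and C-genome diploid oats are the
stepping stones for understanding hexaploid oat (AACCDD). The analyses that
turn raw assemblies into that understanding are scattered across one-off
scripts in most projects; `avenacomp` implements the whole chain as a
package, with a synthetic-data generator that produces every input together
with ground-truth tables, so each stage is testable without downloads:

* **Assembly statistics** — N50/L50 by the cumulative half-total rule, base
  composition, and gap accounting under the ≥ 20-N contig-break convention.
* **Marker anchoring** — placement of 64-bp tag-level haplotype markers at
  perfect unique identity, plurality assignment of scaffolds to linkage
  groups, and collinearity-based head-to-tail merging of chromosome arms
  with 1000-N joins.
* **Subgenome deconvolution** — contingency of hexaploid linkage groups
  against both diploid references, A/C/D labelling with homoeolog pairing,
  slash labels for translocated groups, and run-based detection of
  intergenomic translocation breakpoints.
* **Synteny orthology** — majority-rule (> 50% syntenic bp) orthologous
  chromosome calls from synteny-block files (per-block TSV or
  DAGchainer-style), plus block-size correlation.
* **Ks molecular clock** — Nei–Gojobori (1986) synonymous divergence with
  Jukes–Cantor correction, histogram peak estimation, and strict-clock
  calibration/dating via Ks = 2rT.
* **SNP phylogenies** — 0%-missing / ≤ 5%-het / ≥ 0.1-MAF site filters,
  sliding-window LD pruning (r² > 0.1 within 500 kb), and bootstrapped,
  outgroup-rooted neighbor-joining trees in Newick.
* **Repeat landscape** — discovery of the dominant tandem monomer (the
  most-common-repeat centromere heuristic), windowed density tracks
  (bedGraph), centromere calls with Levan-style morphology classes, and a
  microsatellite scanner.

## Worked example

The clock arithmetic at the heart of the dating analysis:

```r
library(avenacomp)

rate <- calibrate_rate(0.3, 44.3e6)        # deep-node Ks 0.3 at 44.3 Ma
signif(rate, 3)
#> [1] 3.39e-09

divergence_time(0.0875, rate) / 1e6        # A/C split, lineage rate
#> [1] 12.9056
divergence_time(0.0875, EUKARYOTIC_SYNONYMOUS_RATE) / 1e6
#> [1] 5.401235
```

A Ks peak of 0.0875 therefore dates the split of the A- and C-genome
diploids to ~5.4–12.9 Ma depending on the rate used. One NG86 estimate:

```r
ks_ng86("GTTGTT", "GTCGTT")
#> NG86: S = 2.00, N = 4.00, Sd = 1.00, pS = 0.5000, Ks = 0.8240
```

The full simulated chain, from genomes to trees and repeat tracks:

```r
res <- run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
res$results$subgenome$assignment
#>      lg label a_count c_count primary_chr_A primary_chr_C homoeolog_partner
#> 1 Mrg01   C/A      25      35            A1            C1             Mrg06
#> 2 Mrg02     A      60       0            A2          <NA>             Mrg03
#> 3 Mrg03     D      36       0            A2          <NA>             Mrg02
#> 4 Mrg04     C       0      60          <NA>            C3              <NA>
#> ...
```

Each linkage group is labelled by its subgenome of origin; `Mrg01` carries
the planted A/C intergenomic translocation (slash label, larger segment
first), and `detect_translocations()` reports its breakpoint interval. The
run writes FASTA/GFF3/TSV/VCF/Newick/bedGraph artifacts plus an md5
manifest under `demo_run/`; two runs with the same seed are byte-identical.

A thin command-line front end over the same functions ships as
`inst/exec/compass.R` (subcommands `simulate`, `stats`, `map-markers`,
`assign-lg`, `merge-arms`, `ks`, `clock`, `tree`, `repeat-profile`, `run`,
and friends).

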