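# ambimux

Genotype-aware simulation of ambient contamination in multiplexed
single-nucleus multiome experiments, and a variant-consistency metric
for auditing demultiplexed singlets.

## The problem

Pooling nuclei from several donors in one droplet experiment
(multiplexing) cuts cost and batch effects, and genotype-based
demultiplexers reassign each barcode to its donor from the alleles its
reads carry. Ambient RNA/DNA — cell-free molecules carrying alleles
from *every* pooled donor — contaminates droplets, degrades
demultiplexing, and is particularly severe in single-nucleus assays.
Two gaps follow: existing read simulators cannot generate multiplexed
joint snRNA/snATAC data with controlled, per-droplet ambient fractions
sampled from donor genotypes; and there is no post-hoc way to estimate
how much foreign material the singlets a method reports actually
contain.

`ambimux` provides both, for method developers and pipeline builders
who need ground-truth benchmarks, and for analysts who want a
per-droplet contamination estimate on real data.

## What it computes

**Simulation.** Per droplet: a type (singlet / heterotypic doublet /
empty), donor identity(ies), an ambient fraction
f ~ Beta(μ<sub>a</sub>c, (1−μ<sub>a</sub>)c), and negative-binomial
depths. Per molecule: ambient status ~ Bernoulli(f); a locus sampled
uniformly over informative regions (native) or, with weight β from
informative regions and otherwise genome-wide (ambient); at every
covered SNP an allele from the source donor's diploid genotype
(alt with probability dosage/2), then a uniform substitution error
channel at rate ε. Output: 10x-layout FASTQs, coordinate-sorted BAMs
with `CB`/`UB` tags placed at the true loci, and complete per-droplet /
per-molecule truth.

**Variant consistency.** Given droplet × variant ref/alt count matrices
R, A, donor genotypes G ∈ {0,1,2}<sup>K×V</sup> and per-droplet donor
assignments, every observed allele of an assigned singlet is classified
against the assigned donor's allele set:

| consistent with assigned donor | carried by another donor | category |
|---|---|---|
| yes | no  | C1 |
| yes | yes | C2 |
| no  | yes | **I1** — must be foreign material: a lower bound on ambient contamination |
| no  | no  | I2 — sequencing/genotyping error |

Counts accumulate into F ∈ N<sup>D×4</sup>; the per-droplet I1 count
tracks the droplet's true number of ambient molecules (validated by
simulation; squared correlations ≈ 0.93 RNA / 0.95 ATAC at the scaled
depths the package tests itself at, rising toward 0.96–0.97 at
real-experiment depths).

**Benchmark metrics.** Droplet-type accuracy, singleton-donor accuracy,
optimal cluster-to-donor label harmonization (Hungarian assignment),
between-method droplet-type correlation, and multi-method
intersection/UpSet-style membership counts.

## Worked example

Everything below is self-contained — the reference (2 Mb genome, 5,000
SNPs, 4 donors, gene bodies, peaks, barcode whitelist) is generated on
the fly.

```r
library(ambimux)

ref     <- makeToyReference("toyref", seed = 1)
panel   <- loadGenotypes(ref$vcf)
panel
#> VariantPanel: 5000 biallelic SNPs x 4 donors
#>   donors: donor1, donor2, donor3, donor4
#>   variants with R2 annotation: 5000

cfg <- experimentConfig(nDroplets = 500, nDonors = 4, doubletRate = 0.1,
                        ambientLevel = 0.2, rnaDepthMean = 2000,
                        atacDepthMean = 3200, seed = 1)
droplets <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
droplets
#> DropletSet: 500 droplets
#> doublet singlet
#>      52     448
#>   mean ambient fraction 0.198; mean depths RNA 2041 / ATAC 3228

sim  <- simulateReads(droplets, panel, ref$regions$rna, ref$regions$atac,
                      ref$genome, seed = 2)
pile <- pileupFromReads(sim, "rna")
res  <- consistencyCounts(pile, panel, truthCalls(sim))
res
#> ConsistencyResult: 448 assigned droplets (read counts)
#>   column totals:
#>     C1     C2     I1     I2
#>   6699 186120   7045      0
#>   excluded droplets:
#> doublet
#>      52

round(head(consistencyRates(res), 3), 4)
#>                      C1     C2     I1 I2
#> TAGATAAAGTCGTTTG 0.0242 0.9366 0.0393  0
#> GTTGCAATGTACCAGT 0.0272 0.9012 0.0716  0
#> GTTCATGTCAAATTTC 0.0230 0.8946 0.0824  0

round(ambientCorrelation(res, sim, "rna"), 3)
#> [1] 0.805
```

Reading the output: at a 20% mean ambient level, droplets show I1 rates
of roughly 4–8% — the read-count share that *provably* came from another
donor (the lower bound; much contamination is invisible because shared
alleles land in C2). Per-droplet I1 counts correlate with the true
ambient molecule counts (R² = 0.805 at this single contamination level;
pooling a 0–50% sweep raises it to ≈ 0.93, see below). I2 is zero here
because every simulated SNP discriminates donors, so even sequencing
errors always match somebody's genotype on this panel.

To write actual sequencing files and run the BAM-based pileup instead:

```r
out  <- writeSimOutputs(sim, "simout", ref$genome)
pile <- pileupCounts(out$rnaBam, panel, barcodes(sim), modality = "rna")
```

A command-line wrapper over the same functions ships in
`inst/cli/ambimux` with subcommands `fixtures`, `simulate`, `pileup`,
`consistency`, `evaluate`.

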