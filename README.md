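# prophager

Estimating whether an integrated prophage is **active** (lytic) or
**dormant** (lysogenic) from short-read coverage.

## The problem

Temperate phages integrate into their host's chromosome and, while
lysogenic, replicate passively in a 1:1 ratio with the host genome. Upon
induction the phage genome replicates independently, so sequencing reads
recruit to the prophage interval far in excess of the flanking host
region. Prophage *prediction* tools (VIBRANT, PHASTER, ...) locate
integrated prophages on assembled scaffolds but say nothing about their
stage of infection. `prophager` takes those coordinates plus reads (or a
ready SAM/BAM alignment) and decides, per prophage, whether the coverage
evidence supports active replication.

## The method

For each host scaffold:

1. **Read filtering.** Aligned reads are kept when their alignment percent
   identity

   identity = (l − g − m) / l × 100

   (alignment columns *l*, gap columns *g*, mismatches *m*, derived from
   the CIGAR string and NM tag) reaches the threshold (default 97%).
   Unmapped, secondary and supplementary records are discarded.
2. **Depth extraction.** Per-nucleotide depth is computed over the whole
   scaffold, zero-coverage positions included; 150 bp at each scaffold end
   is masked to suppress partial-scaffold edge artifacts.
3. **Host segmentation.** All positions outside every prophage interval
   form one cohesive host region, shared identically by every co-resident
   prophage; prophage and host regions must each be ≥ 1 kb.
4. **Decision.** Each prophage is scored by the coverage ratio
   x̄_prophage / x̄_host and by Cohen's *d*,

   d = |x̄_host − x̄_prophage| / √((S²_host + S²_prophage) / 2).

   A prophage is called **active** when ratio ≥ 2.0 (1.75 in sensitive
   mode) *and* d ≥ 0.70, provided its mean coverage ≥ 1.0 and coverage
   breadth ≥ 0.50; prophages failing the presence gates are **not
   present**, prophages failing only the ratio/effect gates are
   **dormant**, and conflicting evidence yields **ambiguous**. All cutoffs
   are closed bounds and user-tunable.

A seeded synthetic-data module (`sim_scenario()`, `sim_genome()`,
`sim_reads()`, `subsample_fastq()`) generates host scaffolds with
implanted prophages and reads at a controlled prophage:host depth ratio,
giving ground truth for every pipeline stage.

## Worked example

Simulate an active prophage (true ratio 4, host 20×) and analyze it:

```r
library(prophager)
sc <- sim_scenario(seed = 7, ratio = 4)       # 10 kb prophage in 50 kb scaffold
g  <- sim_genome(sc, "demo")
r  <- sim_reads(sc, g, "demo")
res <- estimate_activity(g$coords, alignment = r$sam)
res
#> Prophage activity estimate: 1 prophage(s) on 1 scaffold(s)
#>   active 1 | ambiguous 0 | dormant 0 | not present 0
#>   thresholds: ratio >= 2.00, Cohen's d >= 0.70
```

The results table (`write_activity_table(res, "activity.tsv")`) holds one
row per prophage; here the prophage's mean coverage is 80.19× against a
host mean of 20.02×, giving a coverage ratio of 4.0054 with Cohen's
d = 7.2683 and breadth 0.9996 — an unambiguous **active** call, and the
true simulated ratio recovered within 0.2%.

The same run from the shell:

```sh
prophager -c demo/prophage_coordinates.tsv -s demo/reads.sam -o activity.tsv
```

or from FASTQ, letting the package drive the aligner:

```sh
prophager -c demo/prophage_coordinates.tsv -f demo/scaffolds.fasta \
          -u demo/reads.fastq -o activity.tsv
```

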