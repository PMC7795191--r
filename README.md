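# loopstack

Comparative chromatin-architecture analysis for two-condition Hi-C / HiChIP
studies — e.g. an embryonic stem cell (ESC) population against its neural
crest cell (NCC) derivative. `loopstack` takes the loop lists, binding
peaks, expression tables and contact matrices that upstream tools emit and
answers the downstream questions: where are the topologically associating
domains (TADs) and how much did their borders move, which loops changed
between conditions and is the change statistically supported, which genomic
features pile up at domain borders and around co-regulated gene pairs, and
how predictive the chromatin context is of expression level.

## What the package computes

**Uniform binned genome.** Every chromosome is tiled into fixed-width bins
(1 kb by default). Scored features (loop anchor strength, ChIP signal,
FPKM) are summed into the bins they overlap; positional annotations
(promoters, exons, CpG islands, ...) contribute their overlap in bp, capped
at the bin width so features shared between genes never count twice.
Interaction **anchor strength** of a bin is the sum of the scores of all
loops with an anchor overlapping it, counted once per overlapping anchor.

**Directionality-index TAD calling.** At 40 kb resolution, each bin's
upstream (A) and downstream (B) contact sums within a 2 Mb window form the
signed statistic

    DI = (B − A)/|B − A| · ( (A − E)²/E + (B − E)²/E ),   E = (A + B)/2

Deterministic run-segmentation of the DI sign calls domains; borders of the
two conditions are compared by nearest-neighbor distance, giving the
percent of borders changed and the mean/min/max shift.

**Hierarchical paired-t differential testing.** Loop scores are accumulated
on a fine grid (100 kb genome-wide, 1 kb at loci), fine-bin pairs are
grouped into coarse cells (1 Mb / 10 kb), and each cell is tested with a
paired t-test on its fine-pair vectors — 100 paired values per full cell —
with optional Bonferroni correction. Differential loops are rendered per
favored condition with one statistic per midpoint (largest delta), and the
top-N cells form an interaction network whose per-node degree and
clustering coefficients are computed from the adjacency matrix.

**Aligned pile-ups.** Midpoint- and border-aligned loci × offset-bin
matrices with explicit masks: cells past a TAD's own midpoint, or off a
chromosome end, never enter a summary. DiffTADs are oriented by the
strand-directional span of their regulated genes before alignment.
Same-size TAD stacks report Pearson correlations between interaction
strength and other attributes; z-score profiles give two-tailed
significance of positional enrichment; a resampling scanner tests motif
enrichment in 10 kb bins around borders.

**Expression prediction.** Two-window sliding concentrations (inner/outer)
of any attribute set feed either a 7-layer ReLU network or a deterministic
multinomial-logistic classifier predicting FPKM or interaction-score
classes.

**qPCR quantification.** The 3C / ChIP / RT formulas
(`percent input = 100·2^(ref CT − sample CT)·100`, etc.), replicate
aggregation (technical within biological), fold changes and Fisher's-LSD
significance.

A synthetic-data module (`sim_config()` / `simulate_genome()`) plants TADs,
condition-specific loops, border-enriched peaks and TAD-coupled
co-regulated expression with known truth, so the whole pipeline is testable
end-to-end.

## Worked example

```r
library(loopstack)

cfg <- sim_config(n_chroms = 1, chrom_length = 12e6,
                  tad_size_range = c(360e3, 840e3), intra_tad_enrichment = 5,
                  read_depth = 1e6, seed = 7, n_loops = 10000, n_genes = 500)
sim  <- simulate_genome(cfg)
mats <- simulate_contact_matrix(cfg, sim$truth)

tads <- lapply(names(mats), function(cond)
  call_tads(directionality_index(mats[[cond]]$chr1), condition = cond))
names(tads) <- names(mats)

compare_tads(tads$ESC, tads$NCC)
#> <border_shift> 22 borders; 27.27% changed (>= 40000 bp), mean 80000 bp [40000, 160000]

rank_diffgenes(sim$data$loops$hic_NCC, sim$data$expression, "up",
               q_max = 0.01, top_n = 20, min_spacing = 1e6)[1:3,
  c("chrom1", "start1", "start2", "sum_log2fc", "midpoint", "rank")]
#>   chrom1  start1  start2 sum_log2fc midpoint  rank
#> 1 chr1    208000  360000       7.34   286500     1
#> 2 chr1   6727000 6753000       6.96  6742500     2
#> 3 chr1   5358000 5483000       5.46  5423000     3
```

The border comparison says that between the two simulated cell states 27%
of domain borders moved by at least one 40 kb bin (mean 80 kb); the
DiffGene table ranks high-confidence loops by the summed log2 fold change
of the upregulated genes in their two anchors, one interaction per 1 Mb.

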