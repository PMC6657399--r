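# Shared study configuration for the numbered analysis scripts.
# Run every script from the repository root: Rscript analysis/01_simulate.R

library(poolsweep)

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 20190718L

# One 10-Mb contig at 1 SNP / 500 bp and 25x pooled depth per group,
# with a single 300-kb sweep: the selected group keeps 10% of background
# heterozygosity and is displaced 0.3 in allele frequency.
CONTIGS <- data.frame(contig = "chr1", length = 1e7)
SWEEPS <- data.frame(contig = "chr1", start = 4e6 + 1, end = 4.3e6,
                     het_reduction = 0.1, divergence_shift = 0.3)
SIM_CONFIG <- sim_config(CONTIGS, sweeps = SWEEPS, seed = STUDY_SEED)

# Synthetic gene models around and away from the sweep (labels only;
# positions are invented for the simulated contig).
GENES <- data.frame(
  contig = "chr1",
  start = c(3.95e6, 4.05e6, 4.12e6, 4.21e6, 4.28e6, 6.00e6, 8.50e6),
  end = c(4.01e6, 4.09e6, 4.18e6, 4.26e6, 4.35e6, 6.08e6, 8.60e6),
  gene_name = c("geneA", "geneB", "geneC", "geneD", "geneE",
                "bystander1", "bystander2"),
  stringsAsFactors = FALSE
)
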