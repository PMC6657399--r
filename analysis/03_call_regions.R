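# Extract dual Z > 5 outlier windows, merge them into candidate sweep
# regions, annotate with the synthetic gene set and compare against the
# planted truth.

source("analysis/00_config.R")

sim <- simulate_sites(SIM_CONFIG)
res <- run_pipeline(sim$sites, CONTIGS, genes = GENES,
                    out_dir = RESULTS_DIR)

cat(sprintf("%d outlier window(s) -> %d candidate region(s)\n",
            res$manifest$counts$windows_outlier,
            res$manifest$counts$regions))
for (i in seq_len(nrow(res$regions))) {
  r <- res$regions[i, ]
  cat(sprintf("  %s:%d-%d  maxZ(FST)=%.2f  maxZ(HPratio)=%.2f  genes: %s\n",
              r$contig, r$start, r$end, r$max_z_fst, r$max_z_hp_ratio,
              paste(r$genes[[1]], collapse = ", ")))
}
ov <- res$regions$start <= SWEEPS$end & res$regions$end >= SWEEPS$start
cat(sprintf("regions overlapping the planted sweep: %d of %d\n",
            sum(ov), nrow(res$regions)))
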