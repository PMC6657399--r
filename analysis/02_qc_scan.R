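# QC-filter the simulated SNPs and run the 50-kb/10-kb sliding-window
# scan of pooled heterozygosity and FST.

source("analysis/00_config.R")

sim <- simulate_sites(SIM_CONFIG)  # deterministic: same seed as 01
sites <- drop_uncovered(sim$sites)

qc <- run_qc(sites, qc_config())
cat(sprintf("QC: %d sites in; %d fail quality, %d fail spacing, %d fail depth; %d retained (%.1f%%)\n",
            qc$report$n_input, qc$report$n_fail_quality,
            qc$report$n_fail_spacing, qc$report$n_fail_depth,
            qc$report$n_retained,
            100 * qc$report$n_retained / qc$report$n_input))
write_qc_report(qc$report, file.path(RESULTS_DIR, "qc_report.txt"))

windows <- scan_windows(qc$sites, CONTIGS, scan_config())
cat(sprintf("scan: %d windows, %d retained (>= 10 sites), %d discarded\n",
            nrow(windows), sum(!windows$discarded), sum(windows$discarded)))
in_sweep <- windows$start >= SWEEPS$start & windows$end <= SWEEPS$end
cat(sprintf("background window HP (selected group): %.3f; inside sweep: %.3f\n",
            mean(windows$hpA[!in_sweep], na.rm = TRUE),
            mean(windows$hpA[in_sweep], na.rm = TRUE)))
cat(sprintf("max Z(FST) = %.2f, max Z(HP ratio) = %.2f\n",
            max(windows$z_fst, na.rm = TRUE),
            max(windows$z_hp_ratio, na.rm = TRUE)))
write_window_track(windows, file.path(RESULTS_DIR, "windows.tsv"),
                   bedgraph_dir = RESULTS_DIR)
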