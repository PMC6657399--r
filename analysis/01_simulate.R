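# Simulate the study data: two-group pooled allele counts with one
# planted sweep, plus a qPCR Ct table with a known 1.5-dCt group effect.

source("analysis/00_config.R")

sim <- simulate_sites(SIM_CONFIG)
cat(sprintf("simulated %d SNPs on %d contig(s); mean depth A = %.2fx, B = %.2fx\n",
            nrow(sim$sites), nrow(CONTIGS),
            mean(sim$sites$countA_major + sim$sites$countA_minor),
            mean(sim$sites$countB_major + sim$sites$countB_minor)))
cat(sprintf("planted sweep: %s:%d-%d (het_reduction %.2f, divergence %.2f)\n",
            SWEEPS$contig, SWEEPS$start, SWEEPS$end,
            SWEEPS$het_reduction, SWEEPS$divergence_shift))

write_sync_counts(sim$sites, file.path(RESULTS_DIR, "sim_sites.sync"))
write_truth_bed(sim$truth, file.path(RESULTS_DIR, "sweep_truth.bed"))

qpcr <- simulate_qpcr(n_stages = 6, group_effect_dct = 1.5,
                      stage_slope = 0.02, noise_sd = 0.15,
                      seed = STUDY_SEED)
write_ct_csv(qpcr, file.path(RESULTS_DIR, "qpcr_ct.csv"))
cat(sprintf("wrote %d qPCR samples (6 stages x 2 groups, triplicate Cts)\n",
            nrow(qpcr)))
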