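# Fixtures and independent oracles used across test files.

# Minimal VCF with per-sample GT:AD fields. `records` is a data.frame with
# chrom, pos, ref, alt, qual and one "refDepth,altDepth" string column per
# sample name.
write_test_vcf <- function(path, records, sample_names) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    gt <- vapply(sample_names,
                 function(s) paste0("0/1:", records[[s]][i]), "")
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], records$qual[i], "PASS", ".", "GT:AD", gt),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

# 12-site QC fixture, hand-traced: sites at pos 200 and 400 fail quality
# (qual 10 and 15); the clusters {300,303} and {600,603} fail spacing
# (gap 3 < 5); the site at pos 1000 fails depth in group A (depth 150
# against a post-spacing group-A mean of 400/6, upper bound 2*mean =
# 133.33); the five sites at 100, 500, 700, 800, 900 survive.
make_qc_fixture <- function() {
  pos <- c(100, 200, 300, 303, 400, 500, 600, 603, 700, 800, 900, 1000)
  qual <- c(50, 10, 50, 50, 15, 50, 50, 50, 50, 50, 50, 50)
  majA <- rep(40, 12); minA <- rep(10, 12)
  majA[12] <- 120; minA[12] <- 30  # depth 150 in group A
  site_counts(contig = rep("c1", 12), pos = pos, qual = qual,
              countA_major = majA, countA_minor = minA,
              countB_major = rep(40, 12), countB_minor = rep(10, 12))
}

# Independent window-scan oracle: recomputes every window from scratch by
# subsetting sites, with plain-loop formulas. Used to check the window
# engine produces identical sums.
naive_scan_oracle <- function(sites, contigs, config) {
  windows <- list()
  k <- 0
  for (ci in seq_len(nrow(contigs))) {
    L <- contigs$length[ci]
    start <- 1
    while (start + config$window_size - 1 <= L) {
      end <- start + config$window_size - 1
      d <- sites[sites$contig == contigs$contig[ci] &
                   sites$pos >= start & sites$pos <= end, , drop = FALSE]
      hp <- function(a, b) if (sum(a) + sum(b) == 0) NA_real_ else
        2 * sum(a) * sum(b) / (sum(a) + sum(b))^2
      num <- den <- numeric(nrow(d))
      for (i in seq_len(nrow(d))) {
        p1 <- d$countA_minor[i] / (d$countA_major[i] + d$countA_minor[i])
        p2 <- d$countB_minor[i] / (d$countB_major[i] + d$countB_minor[i])
        num[i] <- (p1 - p2)^2 - (p1 * (1 - p1) / (config$haploids_A - 1) +
                                   p2 * (1 - p2) / (config$haploids_B - 1))
        den[i] <- p1 * (1 - p2) + p2 * (1 - p1)
      }
      k <- k + 1
      windows[[k]] <- data.frame(
        contig = contigs$contig[ci], start = start, end = end,
        n_sites = nrow(d),
        hpA = hp(d$countA_major, d$countA_minor),
        hpB = hp(d$countB_major, d$countB_minor),
        fst = if (nrow(d) == 0 || sum(den) == 0) NA_real_ else
          sum(num) / sum(den)
      )
      start <- start + config$step
    }
  }
  do.call(rbind, windows)
}

# Small simulated genome shared by several tests (kept modest for speed).
small_sim <- function(seed = 7, sweeps = NULL, length = 2e6) {
  simulate_sites(sim_config(
    contigs = data.frame(contig = "chr1", length = length),
    sweeps = sweeps, seed = seed
  ))
}

swap_groups <- function(sites) {
  out <- sites
  out$countA_major <- sites$countB_major
  out$countA_minor <- sites$countB_minor
  out$countB_major <- sites$countA_major
  out$countB_minor <- sites$countA_minor
  out
}
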