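#' Configuration of the pooled allele-count simulator
#'
#' The simulator emulates a two-group pool-seq experiment: SNPs placed by
#' a Poisson process, a symmetric U-shaped background allele-frequency
#' spectrum, independent logit-scale drift between the groups, finite
#' pools of chromosomes, and Poisson read depth with binomial allele
#' sampling. Sweep intervals reduce the selected group's expected per-site
#' heterozygosity by `het_reduction` and displace its frequency away from
#' the control group by `divergence_shift`.
#'
#' @param contigs data.frame with columns `contig`, `length` (bp).
#' @param snp_rate expected SNPs per bp (default 1/500).
#' @param depth_A,depth_B mean read depth per group (default 25, matching
#'   a ~25x pooled sequencing design).
#' @param haploids_A,haploids_B chromosomes per pool group (defaults 800
#'   and 400: 40 and 20 pools of 10 diploid animals).
#' @param sfs_shape shape of the symmetric Beta background frequency
#'   spectrum (default 0.2; small values give the U-shape typical of
#'   site-frequency spectra).
#' @param drift_sd between-group frequency jitter on the logit scale
#'   (default 0.2).
#' @param sweeps data.frame of planted sweeps with columns contig, start,
#'   end, het_reduction (fraction of background heterozygosity retained in
#'   the selected group; 0 = complete sweep), divergence_shift (extra
#'   allele-frequency displacement between groups). NULL for none.
#' @param qual_mean,qual_sd site quality distribution (Normal truncated at
#'   0; defaults 60 and 15).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(contigs, snp_rate = 1 / 500,
                       depth_A = 25, depth_B = 25,
                       haploids_A = 800L, haploids_B = 400L,
                       sfs_shape = 0.2, drift_sd = 0.2,
                       sweeps = NULL,
                       qual_mean = 60, qual_sd = 15,
                       seed = 1L) {
  stopifnot(depth_A > 0, depth_B > 0, snp_rate > 0,
            all(contigs$length >= 1), !anyDuplicated(contigs$contig))
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    stopifnot(all(sweeps$start < sweeps$end),
              all(sweeps$het_reduction >= 0 & sweeps$het_reduction <= 1))
    for (i in seq_len(nrow(sweeps))) {
      L <- contigs$length[match(sweeps$contig[i], contigs$contig)]
      if (is.na(L) || sweeps$start[i] < 1 || sweeps$end[i] > L) {
        stop("sweep interval outside contig bounds: row ", i)
      }
    }
    by_ctg <- split(sweeps, sweeps$contig)
    for (s in by_ctg) {
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("overlapping sweep intervals")
      }
    }
  }
  structure(list(
    contigs = contigs, snp_rate = snp_rate,
    depth_A = depth_A, depth_B = depth_B,
    haploids_A = as.integer(haploids_A),
    haploids_B = as.integer(haploids_B),
    sfs_shape = sfs_shape, drift_sd = drift_sd,
    sweeps = sweeps, qual_mean = qual_mean, qual_sd = qual_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# move p toward its nearer boundary so that p'(1-p') = r * p(1-p)
squeeze_het <- function(p, r) {
  q <- r * p * (1 - p)
  root <- sqrt(pmax(1 - 4 * q, 0))
  ifelse(p <= 0.5, (1 - root) / 2, (1 + root) / 2)
}

#' Simulate two-group pooled allele counts with planted sweeps
#'
#' Per contig: SNP count ~ Poisson(length x snp_rate) at distinct uniform
#' positions; ancestral frequency p ~ Beta(sfs_shape, sfs_shape); each
#' group's frequency is a logit-jittered copy of p. Inside sweep
#' intervals the selected group's frequency is squeezed toward the nearer
#' boundary so expected heterozygosity is scaled by `het_reduction`, then
#' displaced from the control frequency by `divergence_shift`. Reads are
#' drawn in two stages — pool frequency ~ Binomial(haploids, freq)/haploids,
#' then minor reads ~ Binomial(Poisson depth, pool frequency) — which
#' reproduces the count correlation of finite pools. Counts are oriented
#' so the pooled major allele comes first.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (site-count table) and `truth` (data.frame of
#'   planted sweep intervals, possibly empty).
#' @export
simulate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  res <- vector("list", nrow(config$contigs))
  for (ci in seq_len(nrow(config$contigs))) {
    ctg <- config$contigs$contig[ci]
    L <- config$contigs$length[ci]
    set.seed((config$seed + 7919L * ci) %% 2147483647L)
    n <- stats::rpois(1, L * config$snp_rate)
    if (n == 0) next
    n <- min(n, L)
    pos <- sort(sample.int(L, n))
    eps <- 1e-4
    p0 <- pmin(pmax(stats::rbeta(n, config$sfs_shape, config$sfs_shape),
                    eps), 1 - eps)
    jitter <- function(p) {
      stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, config$drift_sd))
    }
    pA <- jitter(p0)
    pB <- jitter(p0)
    sw <- config$sweeps
    if (!is.null(sw) && nrow(sw) > 0) {
      sw <- sw[sw$contig == ctg, , drop = FALSE]
      for (k in seq_len(nrow(sw))) {
        in_sw <- pos >= sw$start[k] & pos <= sw$end[k]
        if (!any(in_sw)) next
        p <- squeeze_het(pA[in_sw], sw$het_reduction[k])
        dir <- sign(p - pB[in_sw])
        dir[dir == 0] <- ifelse(p[dir == 0] <= 0.5, -1, 1)
        pA[in_sw] <- pmin(pmax(p + sw$divergence_shift[k] * dir, 0), 1)
      }
    }
    draw <- function(freq, haploids, depth) {
      pool <- stats::rbinom(n, haploids, freq) / haploids
      d <- stats::rpois(n, depth)
      alt <- stats::rbinom(n, d, pool)
      cbind(ref = d - alt, alt = alt)
    }
    cA <- draw(pA, config$haploids_A, config$depth_A)
    cB <- draw(pB, config$haploids_B, config$depth_B)
    qual <- pmax(stats::rnorm(n, config$qual_mean, config$qual_sd), 0)
    res[[ci]] <- site_counts(
      contig = rep(ctg, n), pos = pos, qual = qual,
      countA_major = cA[, "ref"], countA_minor = cA[, "alt"],
      countB_major = cB[, "ref"], countB_minor = cB[, "alt"]
    )
  }
  sites <- do.call(rbind, res)
  if (is.null(sites)) {
    sites <- site_counts(character(), integer(), numeric(),
                         numeric(), numeric(), numeric(), numeric())
  }
  sites <- orient_major_minor(sites)
  rownames(sites) <- NULL
  truth <- config$sweeps
  if (is.null(truth)) {
    truth <- data.frame(contig = character(), start = integer(),
                        end = integer(), het_reduction = numeric(),
                        divergence_shift = numeric())
  }
  list(sites = sites, truth = truth)
}

#' Write planted-sweep truth intervals as BED
#'
#' @param truth truth data.frame from [simulate_sites()].
#' @param path output BED path (0-based half-open).
#' @export
write_truth_bed <- function(truth, path) {
  lines <- paste(truth$contig,
                 format(truth$start - 1L, scientific = FALSE, trim = TRUE),
                 format(truth$end, scientific = FALSE, trim = TRUE),
                 sprintf("sweep_%02d", seq_len(nrow(truth))),
                 sep = "\t")
  writeLines(lines, path)
}

#' Simulate a qPCR Ct table with a known group effect
#'
#' One sample per group and fetal stage, each with triplicate Ct
#' replicates for the target and the reference gene. The target Ct is
#' `baseline + stage_slope * stage - group_effect_dct` for the selected
#' group (so `group_effect_dct` is the true log2 fold ratio
#' selected/control); the reference gene is flat across groups and
#' stages.
#'
#' @param n_stages number of fetal stages (>= 2).
#' @param stage_lengths_mm fetal lengths in mm; default
#'   `seq(30, 130, length.out = n_stages)`.
#' @param group_effect_dct true dCt reduction in the selected group
#'   (log2 fold ratio).
#' @param stage_slope change of target Ct per mm of fetal length
#'   (positive = expression falls with development).
#' @param noise_sd replicate noise SD in Ct units.
#' @param seed integer seed.
#' @param baseline,ref_baseline mean target / reference Ct.
#' @param n_replicates replicates per gene and sample (default 3).
#' @return qPCR sample table (see [read_ct_csv()] for the shape).
#' @export
simulate_qpcr <- function(n_stages = 6, stage_lengths_mm = NULL,
                          group_effect_dct = 1, stage_slope = 0.02,
                          noise_sd = 0.15, seed = 1L,
                          baseline = 24, ref_baseline = 17,
                          n_replicates = 3) {
  stopifnot(n_stages >= 2)
  if (is.null(stage_lengths_mm)) {
    stage_lengths_mm <- seq(30, 130, length.out = n_stages)
  }
  set.seed(as.integer(seed) %% 2147483647L)
  rows <- list()
  i <- 0
  for (s in stage_lengths_mm) {
    for (g in c("selected", "control")) {
      i <- i + 1
      mu <- baseline + stage_slope * s -
        if (g == "selected") group_effect_dct else 0
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_%0.0fmm", substr(g, 1, 3), s),
        group = g, stage_mm = s, stringsAsFactors = FALSE
      )
      rows[[i]]$target_cts <- list(mu + stats::rnorm(n_replicates, 0, noise_sd))
      rows[[i]]$reference_cts <-
        list(ref_baseline + stats::rnorm(n_replicates, 0, noise_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a qPCR sample table as a tidy Ct CSV
#'
#' Inverse of [read_ct_csv()].
#'
#' @param samples qPCR sample table.
#' @param path output CSV path.
#' @param target_gene,reference_gene gene labels to write.
#' @export
write_ct_csv <- function(samples, path, target_gene = "VRTN",
                         reference_gene = "ACTB") {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    rbind(
      data.frame(sample_id = samples$sample_id[i], group = samples$group[i],
                 stage_mm = samples$stage_mm[i], gene = target_gene,
                 ct = samples$target_cts[[i]]),
      data.frame(sample_id = samples$sample_id[i], group = samples$group[i],
                 stage_mm = samples$stage_mm[i], gene = reference_gene,
                 ct = samples$reference_cts[[i]])
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
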