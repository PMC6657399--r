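#' Configuration of the sliding-window sweep scan
#'
#' @param window_size window width in bp (default 50000).
#' @param step step between window starts in bp (default 10000; must not
#'   exceed `window_size`).
#' @param min_sites minimum informative SNPs per window; windows below
#'   this are flagged discarded and excluded from the Z-transformation
#'   (default 10).
#' @param z_cutoff Z-score threshold for outlier windows; a window is a
#'   candidate iff BOTH Z(FST) and Z(HP ratio) exceed it strictly
#'   (default 5).
#' @param hp_floor small positive constant substituted for a zero window
#'   HP before taking the log ratio, so complete sweeps give large finite
#'   values instead of infinities (default 1e-4).
#' @param fst_estimator `"hudson"` (default; per-site sampling correction
#'   using the haploid pool sizes) or `"wright_mean"` (no correction).
#' @param haploids_A,haploids_B number of chromosomes sampled per group,
#'   used by the Hudson correction and the simulator (defaults 800 and
#'   400: 40 and 20 pools of 10 diploid animals).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(window_size = 50000L, step = 10000L,
                        min_sites = 10L, z_cutoff = 5,
                        hp_floor = 1e-4,
                        fst_estimator = c("hudson", "wright_mean"),
                        haploids_A = 800L, haploids_B = 400L) {
  stopifnot(step <= window_size, step >= 1, min_sites >= 1,
            z_cutoff > 0, hp_floor > 0)
  structure(list(
    window_size = as.integer(window_size),
    step = as.integer(step),
    min_sites = as.integer(min_sites),
    z_cutoff = z_cutoff,
    hp_floor = hp_floor,
    fst_estimator = match.arg(fst_estimator),
    haploids_A = as.integer(haploids_A),
    haploids_B = as.integer(haploids_B)
  ), class = "scan_config")
}

#' Pooled heterozygosity of a window
#'
#' HP = 2ab / (a + b)^2 with a the sum of major-allele read counts and b
#' the sum of minor-allele read counts over the window's SNPs in one
#' group. Bounded in [0, 0.5], attaining 0.5 iff a = b; 0 when the group
#' carries only major alleles.
#'
#' @param major,minor vectors of per-site major/minor read counts for one
#'   group over the window's sites.
#' @return HP value, or NA if the window carries no reads.
#' @export
pooled_heterozygosity <- function(major, minor) {
  a <- sum(major)
  b <- sum(minor)
  if (a + b == 0) return(NA_real_)
  2 * a * b / (a + b)^2
}

#' Per-site FST numerator and denominator
#'
#' Default Hudson-type estimator: with minor-allele read fractions
#' p1, p2 and haploid sample sizes n1, n2,
#' numerator = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator = p1(1-p2) + p2(1-p1). Per-site numerators may be negative;
#' windows aggregate as ratio of sums. The `wright_mean` variant omits the
#' sampling-correction terms.
#'
#' @param sites site-count table (rows with nonzero depth in both groups).
#' @param estimator `"hudson"` or `"wright_mean"`.
#' @param haploids_A,haploids_B haploid sample sizes (must exceed 1 for
#'   the Hudson correction).
#' @return data.frame with columns `num`, `den`.
#' @export
snp_fst <- function(sites, estimator = "hudson",
                    haploids_A = 800L, haploids_B = 400L) {
  dA <- sites$countA_major + sites$countA_minor
  dB <- sites$countB_major + sites$countB_minor
  stopifnot(all(dA > 0), all(dB > 0))
  p1 <- sites$countA_minor / dA
  p2 <- sites$countB_minor / dB
  if (estimator == "hudson") {
    if (haploids_A <= 1 || haploids_B <= 1) {
      stop("haploid sample sizes must exceed 1 for the Hudson estimator")
    }
    # correction terms grouped so group swap is exactly symmetric
    num <- (p1 - p2)^2 - (p1 * (1 - p1) / (haploids_A - 1) +
                            p2 * (1 - p2) / (haploids_B - 1))
  } else if (estimator == "wright_mean") {
    num <- (p1 - p2)^2
  } else {
    stop("unknown FST estimator: ", estimator)
  }
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den)
}

#' Window FST as a ratio of sums
#'
#' @param num,den per-site numerator and denominator vectors
#'   (see [snp_fst()]) for the window's sites.
#' @return sum(num)/sum(den), or NA when the summed denominator is 0 (all
#'   sites monomorphic and identical across groups).
#' @export
window_fst <- function(num, den) {
  d <- sum(den)
  if (d == 0) return(NA_real_)
  sum(num) / d
}

#' Enumerate sliding windows over contigs
#'
#' Windows start at 1, 1+step, ... and are emitted only when they fit
#' entirely within the contig: a contig of length L yields
#' floor((L - window_size)/step) + 1 windows when L >= window_size, else
#' none.
#'
#' @param contigs data.frame with columns `contig`, `length`.
#' @param window_size,step window width and step in bp.
#' @return data.frame with columns contig, start, end (1-based inclusive).
#' @export
make_windows <- function(contigs, window_size = 50000L, step = 10000L) {
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    if (L < window_size) return(NULL)
    n <- (L - window_size) %/% step + 1
    start <- 1L + (seq_len(n) - 1L) * as.integer(step)
    data.frame(contig = contigs$contig[i], start = start,
               end = start + as.integer(window_size) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Z-transform a vector of window statistics
#'
#' Standardizes to sample mean 0 and sample (n-1) standard deviation 1,
#' genome-wide across retained windows.
#'
#' @param x numeric vector with at least 2 finite values and nonzero
#'   dispersion.
#' @return Z-scores.
#' @export
z_transform <- function(x) {
  if (sum(is.finite(x)) < 2) stop("z_transform: fewer than 2 finite values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("z_transform: zero dispersion")
  (x - mean(x)) / s
}

#' Sliding-window sweep scan
#'
#' For every window fitting a contig, computes group HP values, the log HP
#' ratio ln(hpB/hpA) (control over selected, so positive values mean
#' heterozygosity loss in the selected group), and FST as a ratio of
#' per-site sums. Windows with fewer than `min_sites` SNPs, or with an
#' undefined statistic, are flagged `discarded` and excluded from the
#' genome-wide Z-transformation of FST and ln HP ratio.
#'
#' @param sites QC-filtered site-count table sorted by (contig, pos).
#' @param contigs data.frame with columns `contig`, `length`.
#' @param config a [scan_config()].
#' @return data.frame with columns contig, start, end, n_sites, hpA, hpB,
#'   ln_hp_ratio, fst, z_fst, z_hp_ratio, discarded.
#' @export
scan_windows <- function(sites, contigs, config = scan_config()) {
  assert_sorted(sites)
  windows <- make_windows(contigs, config$window_size, config$step)
  if (nrow(windows) == 0) {
    windows[c("n_sites", "hpA", "hpB", "ln_hp_ratio", "fst",
              "z_fst", "z_hp_ratio")] <- numeric()
    windows$discarded <- logical()
    return(windows)
  }
  fst_parts <- if (nrow(sites) > 0) {
    snp_fst(sites, config$fst_estimator, config$haploids_A,
            config$haploids_B)
  } else data.frame(num = numeric(), den = numeric())

  res <- vector("list", nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    ctg <- contigs$contig[ci]
    w <- windows[windows$contig == ctg, , drop = FALSE]
    if (nrow(w) == 0) next
    idx <- which(sites$contig == ctg)
    pos <- sites$pos[idx]
    lo <- findInterval(w$start - 0.5, pos) + 1L
    hi <- findInterval(w$end + 0.5, pos)
    stat <- function(x, f) {
      x <- x[idx]
      vapply(seq_len(nrow(w)), function(i) {
        if (hi[i] < lo[i]) NA_real_ else f(x[lo[i]:hi[i]])
      }, 0.0)
    }
    w$n_sites <- pmax(hi - lo + 1L, 0L)
    aA <- stat(sites$countA_major, sum); bA <- stat(sites$countA_minor, sum)
    aB <- stat(sites$countB_major, sum); bB <- stat(sites$countB_minor, sum)
    hp <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b)^2, NA_real_)
    w$hpA <- hp(aA, bA)
    w$hpB <- hp(aB, bB)
    # difference of logs, so swapping groups negates the ratio exactly
    w$ln_hp_ratio <- log(pmax(w$hpB, config$hp_floor)) -
      log(pmax(w$hpA, config$hp_floor))
    num <- stat(fst_parts$num, sum)
    den <- stat(fst_parts$den, sum)
    w$fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    res[[ci]] <- w
  }
  out <- do.call(rbind, res)
  out$discarded <- out$n_sites < config$min_sites |
    !is.finite(out$fst) | !is.finite(out$ln_hp_ratio)
  out$z_fst <- NA_real_
  out$z_hp_ratio <- NA_real_
  keep <- !out$discarded
  if (sum(keep) >= 2) {
    out$z_fst[keep] <- z_transform(out$fst[keep])
    out$z_hp_ratio[keep] <- z_transform(out$ln_hp_ratio[keep])
  }
  rownames(out) <- NULL
  out
}

#' Extract dual Z-score outlier windows
#'
#' Returns windows where both Z(FST) and Z(HP ratio) strictly exceed the
#' cutoff — the intersection of the two single-statistic outlier sets.
#'
#' @param windows window table from [scan_windows()].
#' @param z_cutoff Z threshold (default 5; strict inequality).
#' @return the outlier rows.
#' @export
extract_outliers <- function(windows, z_cutoff = 5) {
  sel <- !windows$discarded &
    !is.na(windows$z_fst) & !is.na(windows$z_hp_ratio) &
    windows$z_fst > z_cutoff & windows$z_hp_ratio > z_cutoff
  windows[sel, , drop = FALSE]
}
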