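#' QC configuration for SNP retention filters
#'
#' Encodes the three retention rules applied before the sweep scan: site
#' quality (Phred error probability at most `max_error_rate`), inter-SNP
#' spacing (no same-contig neighbour closer than `min_spacing` bp), and
#' per-group depth within `[depth_low_factor, depth_high_factor]` times
#' the group's mean depth.
#'
#' @param max_error_rate maximum tolerated site error probability
#'   (default 0.01, i.e. Phred quality >= 20).
#' @param min_spacing minimum distance in bp to the nearest same-contig
#'   SNP (default 5; sites in closer clusters are removed symmetrically).
#' @param depth_low_factor,depth_high_factor inclusive depth bounds as
#'   fractions/multiples of the per-group mean depth (defaults 1/3 and 2).
#' @param missing_qual policy for sites with missing quality: `"drop"`
#'   (default) or `"keep"`.
#' @param spacing_mode `"symmetric"` (default: drop every member of a
#'   close cluster) or `"keep_first"` (keep the first member).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_error_rate = 0.01, min_spacing = 5,
                      depth_low_factor = 1 / 3, depth_high_factor = 2,
                      missing_qual = c("drop", "keep"),
                      spacing_mode = c("symmetric", "keep_first")) {
  stopifnot(max_error_rate > 0, max_error_rate < 1,
            min_spacing >= 0,
            depth_low_factor > 0, depth_low_factor < depth_high_factor)
  structure(list(
    max_error_rate = max_error_rate,
    min_spacing = min_spacing,
    depth_low_factor = depth_low_factor,
    depth_high_factor = depth_high_factor,
    missing_qual = match.arg(missing_qual),
    spacing_mode = match.arg(spacing_mode)
  ), class = "qc_config")
}

qc_pass_quality <- function(sites, max_error_rate, missing_qual = "drop") {
  err <- 10^(-sites$qual / 10)
  pass <- err <= max_error_rate
  pass[is.na(pass)] <- (missing_qual == "keep")
  pass
}

#' Filter sites on Phred-scaled site quality
#'
#' A site is retained iff its error probability `10^(-qual/10)` is at most
#' `max_error_rate`; at the default 0.01 this is quality >= 20. Sites with
#' missing quality are dropped (with a warning count in the
#' `n_missing_qual` attribute) unless `missing_qual = "keep"`.
#'
#' @inheritParams qc_config
#' @param sites site-count table.
#' @return the retained rows.
#' @export
filter_quality <- function(sites, max_error_rate = 0.01,
                           missing_qual = "drop") {
  pass <- qc_pass_quality(sites, max_error_rate, missing_qual)
  out <- sites[pass, , drop = FALSE]
  n_missing <- sum(is.na(sites$qual))
  if (n_missing > 0 && missing_qual == "drop") {
    warning(n_missing, " site(s) with missing quality dropped")
  }
  attr(out, "n_missing_qual") <- n_missing
  out
}

qc_pass_spacing <- function(sites, min_spacing, spacing_mode = "symmetric") {
  n <- nrow(sites)
  if (n == 0 || min_spacing == 0) return(rep(TRUE, n))
  same_next <- sites$contig[-n] == sites$contig[-1]
  gap_next <- sites$pos[-1] - sites$pos[-n]
  close_next <- same_next & gap_next < min_spacing    # i close to i+1
  if (spacing_mode == "keep_first") {
    return(c(TRUE, !close_next))
  }
  close_any <- c(close_next, FALSE) | c(FALSE, close_next)
  !close_any
}

#' Filter SNP clusters on inter-site spacing
#'
#' Every site with any same-contig neighbour closer than `min_spacing` bp
#' is removed (both members of a close pair; a distance exactly equal to
#' `min_spacing` passes). Input must be sorted by (contig, pos).
#'
#' @inheritParams filter_quality
#' @param min_spacing minimum spacing in bp.
#' @param spacing_mode see [qc_config()].
#' @return the retained rows.
#' @export
filter_spacing <- function(sites, min_spacing = 5,
                           spacing_mode = "symmetric") {
  assert_sorted(sites)
  sites[qc_pass_spacing(sites, min_spacing, spacing_mode), , drop = FALSE]
}

qc_pass_depth <- function(sites, depth_low_factor, depth_high_factor,
                          mean_depth = NULL) {
  dA <- sites$countA_major + sites$countA_minor
  dB <- sites$countB_major + sites$countB_minor
  if (is.null(mean_depth)) mean_depth <- c(A = mean(dA), B = mean(dB))
  okA <- dA >= depth_low_factor * mean_depth[["A"]] &
    dA <= depth_high_factor * mean_depth[["A"]]
  okB <- dB >= depth_low_factor * mean_depth[["B"]] &
    dB <= depth_high_factor * mean_depth[["B"]]
  list(pass = okA & okB, mean_depth = mean_depth)
}

#' Filter sites on total read depth per group
#'
#' The mean depth is computed per group over the input sites; a site is
#' retained iff its total depth in BOTH groups lies within
#' `[depth_low_factor * mean, depth_high_factor * mean]` (inclusive).
#'
#' @inheritParams filter_quality
#' @param depth_low_factor,depth_high_factor see [qc_config()].
#' @return the retained rows, with attribute `mean_depth` (named numeric,
#'   groups A and B).
#' @export
filter_depth <- function(sites, depth_low_factor = 1 / 3,
                         depth_high_factor = 2) {
  if (nrow(sites) == 0) stop("filter_depth: empty input, mean depth undefined")
  res <- qc_pass_depth(sites, depth_low_factor, depth_high_factor)
  out <- sites[res$pass, , drop = FALSE]
  attr(out, "mean_depth") <- res$mean_depth
  out
}

#' Run the full SNP QC cascade
#'
#' Applies quality, spacing and depth filters in that order; the depth
#' filter's group means are computed on the post-spacing set. The report
#' attributes each dropped site to the first filter it fails.
#'
#' @param sites site-count table sorted by (contig, pos).
#' @param config a [qc_config()].
#' @return list with `sites` (retained rows) and `report`: named list with
#'   n_input, n_fail_quality, n_fail_spacing, n_fail_depth, n_retained,
#'   mean_depth_A, mean_depth_B.
#' @export
run_qc <- function(sites, config = qc_config()) {
  assert_sorted(sites)
  n_input <- nrow(sites)

  pass_q <- qc_pass_quality(sites, config$max_error_rate, config$missing_qual)
  s1 <- sites[pass_q, , drop = FALSE]

  pass_s <- qc_pass_spacing(s1, config$min_spacing, config$spacing_mode)
  s2 <- s1[pass_s, , drop = FALSE]

  if (nrow(s2) == 0) {
    stop("run_qc: no sites left before depth filter, mean depth undefined")
  }
  res_d <- qc_pass_depth(s2, config$depth_low_factor, config$depth_high_factor)
  s3 <- s2[res_d$pass, , drop = FALSE]

  report <- list(
    n_input = n_input,
    n_fail_quality = sum(!pass_q),
    n_fail_spacing = sum(!pass_s),
    n_fail_depth = sum(!res_d$pass),
    n_retained = nrow(s3),
    mean_depth_A = unname(res_d$mean_depth[["A"]]),
    mean_depth_B = unname(res_d$mean_depth[["B"]])
  )
  stopifnot(report$n_retained ==
              n_input - report$n_fail_quality - report$n_fail_spacing -
              report$n_fail_depth)
  list(sites = s3, report = report)
}

#' Write a QC report as plain text and key-value pairs
#'
#' @param report the `report` element of [run_qc()] output.
#' @param path output path; a `.tsv` companion with the same stem carries
#'   the machine-readable key-value form.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(
    "SNP QC report",
    sprintf("  input sites:        %d", report$n_input),
    sprintf("  failed quality:     %d", report$n_fail_quality),
    sprintf("  failed spacing:     %d", report$n_fail_spacing),
    sprintf("  failed depth:       %d", report$n_fail_depth),
    sprintf("  retained:           %d", report$n_retained),
    sprintf("  mean depth A:       %.3f", report$mean_depth_A),
    sprintf("  mean depth B:       %.3f", report$mean_depth_B)
  )
  writeLines(lines, path)
  kv <- paste(names(report), unlist(report), sep = "\t")
  writeLines(kv, paste0(tools::file_path_sans_ext(path), ".tsv"))
  invisible(NULL)
}

assert_sorted <- function(sites) {
  if (nrow(sites) > 1) {
    o <- order(sites$contig, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      stop("sites must be sorted by (contig, pos)")
    }
  }
  invisible(TRUE)
}

#' Drop sites with zero total reads in either group
#'
#' Both HP and FST are undefined at such sites; they are removed before QC.
#'
#' @param sites site-count table.
#' @return rows with positive depth in both groups.
#' @export
drop_uncovered <- function(sites) {
  dA <- sites$countA_major + sites$countA_minor
  dB <- sites$countB_major + sites$countB_minor
  sites[dA > 0 & dB > 0, , drop = FALSE]
}
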