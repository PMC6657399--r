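#' Read qPCR Ct measurements from a tidy CSV
#'
#' Expects columns sample_id, group (`selected`/`control`), stage_mm
#' (fetal length in mm), gene, ct — one row per replicate measurement.
#'
#' @param path CSV path.
#' @param target_gene,reference_gene gene labels of the target and the
#'   normalisation reference (e.g. beta-actin).
#' @return qPCR sample table: one row per sample with list-columns
#'   `target_cts` and `reference_cts` holding replicate Ct vectors.
#' @export
read_ct_csv <- function(path, target_gene, reference_gene) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "stage_mm", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct CSV must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$sample_id)
  rows <- lapply(ids, function(id) {
    d <- df[df$sample_id == id, , drop = FALSE]
    data.frame(sample_id = id, group = d$group[1],
               stage_mm = d$stage_mm[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$target_cts <- lapply(ids, function(id)
    df$ct[df$sample_id == id & df$gene == target_gene])
  out$reference_cts <- lapply(ids, function(id)
    df$ct[df$sample_id == id & df$gene == reference_gene])
  if (any(lengths(out$target_cts) == 0) ||
      any(lengths(out$reference_cts) == 0)) {
    stop("every sample needs at least one replicate of both genes")
  }
  out
}

#' Per-sample delta-Ct
#'
#' dCt = mean(target replicate Cts) - mean(reference replicate Cts);
#' replicate aggregation is the arithmetic mean.
#'
#' @param samples qPCR sample table (see [read_ct_csv()]).
#' @return the table with a `delta_ct` column.
#' @export
delta_ct <- function(samples) {
  if (any(lengths(samples$target_cts) == 0) ||
      any(lengths(samples$reference_cts) == 0)) {
    stop("delta_ct: empty replicate list")
  }
  samples$delta_ct <-
    vapply(samples$target_cts, mean, 0.0) -
    vapply(samples$reference_cts, mean, 0.0)
  samples
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = dCt(sample) - dCt(calibrator); fold = 2^(-ddCt), so
#' log2(fold) = -ddCt exactly and the calibrator itself has fold 1.
#'
#' @param samples qPCR sample table with a `delta_ct` column (see
#'   [delta_ct()]; computed on the fly when absent).
#' @param calibrator_delta_ct dCt of the calibrator sample. Default:
#'   the control-group sample at the smallest fetal stage (ratios between
#'   groups are calibrator-invariant, so the choice only scales folds).
#' @return the table with `delta_delta_ct` and `fold` columns.
#' @export
fold_change <- function(samples, calibrator_delta_ct = NULL) {
  if (is.null(samples$delta_ct)) samples <- delta_ct(samples)
  if (is.null(calibrator_delta_ct)) {
    ctl <- samples[samples$group == "control", , drop = FALSE]
    if (nrow(ctl) == 0) stop("no control-group sample to use as calibrator")
    calibrator_delta_ct <- ctl$delta_ct[which.min(ctl$stage_mm)]
  }
  samples$delta_delta_ct <- samples$delta_ct - calibrator_delta_ct
  samples$fold <- 2^(-samples$delta_delta_ct)
  samples
}

#' Compare relative expression between groups across fetal stages
#'
#' Computes per-stage fold ratios selected/control against a common
#' calibrator, a two-sided Welch t-test on the per-sample dCt values, and
#' a Spearman rank correlation of fold versus fetal stage (negative when
#' expression falls as the fetus grows).
#'
#' @param samples qPCR sample table spanning both groups.
#' @param calibrator_delta_ct optional calibrator dCt passed to
#'   [fold_change()]; the reported ratios do not depend on it.
#' @return list with `samples` (dCt/ddCt/fold per sample), `per_stage`
#'   (stage_mm, fold_selected, fold_control, fold_ratio), `fold_ratio`
#'   (overall, 2^-(mean dCt difference)), `log2_fold_ratio`, `p_value` and
#'   `t_statistic` from the group test, and `stage_cor` (Spearman rho).
#'   Stages present in only one group are excluded with a warning.
#' @export
group_comparison <- function(samples, calibrator_delta_ct = NULL) {
  samples <- fold_change(delta_ct(samples), calibrator_delta_ct)
  stages <- sort(unique(samples$stage_mm))
  both <- vapply(stages, function(s) {
    g <- samples$group[samples$stage_mm == s]
    all(c("selected", "control") %in% g)
  }, TRUE)
  if (any(!both)) {
    warning("stage(s) present in only one group excluded: ",
            paste(stages[!both], collapse = ", "))
  }
  stages <- stages[both]
  per_stage <- do.call(rbind, lapply(stages, function(s) {
    d <- samples[samples$stage_mm == s, , drop = FALSE]
    fs <- mean(d$fold[d$group == "selected"])
    fc <- mean(d$fold[d$group == "control"])
    # ratio from dCt directly: the calibrator cancels algebraically,
    # so it is invariant to the calibrator choice by construction
    ratio <- 2^(mean(d$delta_ct[d$group == "control"]) -
                  mean(d$delta_ct[d$group == "selected"]))
    data.frame(stage_mm = s, fold_selected = fs, fold_control = fc,
               fold_ratio = ratio)
  }))
  use <- samples$stage_mm %in% stages
  dct_sel <- samples$delta_ct[use & samples$group == "selected"]
  dct_ctl <- samples$delta_ct[use & samples$group == "control"]
  tt <- stats::t.test(dct_sel, dct_ctl, alternative = "two.sided")
  rho <- suppressWarnings(
    stats::cor(samples$fold[use], samples$stage_mm[use], method = "spearman"))
  log2_ratio <- mean(dct_ctl) - mean(dct_sel)  # lower Ct = higher expression
  list(
    samples = samples,
    per_stage = per_stage,
    fold_ratio = 2^log2_ratio,
    log2_fold_ratio = log2_ratio,
    p_value = tt$p.value,
    t_statistic = unname(tt$statistic),
    stage_cor = rho
  )
}

#' Write per-sample fold changes and the per-stage summary
#'
#' @param comparison result of [group_comparison()].
#' @param path output CSV of per-sample dCt/ddCt/fold; a
#'   `_stages.csv` companion carries the per-stage summary.
#' @export
write_ddct_tables <- function(comparison, path) {
  s <- comparison$samples
  utils::write.csv(
    data.frame(sample_id = s$sample_id, group = s$group,
               stage_mm = s$stage_mm, delta_ct = s$delta_ct,
               delta_delta_ct = s$delta_delta_ct, fold = s$fold),
    path, row.names = FALSE)
  utils::write.csv(comparison$per_stage,
                   paste0(tools::file_path_sans_ext(path), "_stages.csv"),
                   row.names = FALSE)
  invisible(NULL)
}
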