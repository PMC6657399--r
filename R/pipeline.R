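#' Run the full sweep-detection pipeline
#'
#' Orchestrates ingest -> QC -> windowed scan -> dual-outlier extraction
#' -> region merging -> length filter -> gene annotation, and writes the
#' QC report, window track, region report, BED files and a machine-readable
#' run manifest. The run is deterministic: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param input either a site-count data.frame, a path to a sync-style
#'   count table, or a list `list(vcf = path, groups = named vector)` for
#'   VCF input.
#' @param contigs data.frame with columns `contig`, `length`.
#' @param genes optional gene intervals (data.frame as from
#'   [read_gene_intervals()], or a GFF3/BED path).
#' @param out_dir output directory (created if needed); NULL to skip all
#'   file output.
#' @param qc a [qc_config()].
#' @param scan a [scan_config()].
#' @param max_gap region merge gap in bp (default 0).
#' @param min_length minimum region length in bp (default 0).
#' @return list with `sites` (QC-retained), `windows`, `regions`
#'   (annotated when genes were given) and `manifest` (stage counts,
#'   configuration echo, input checksums, package version).
#' @export
run_pipeline <- function(input, contigs, genes = NULL, out_dir = NULL,
                         qc = qc_config(), scan = scan_config(),
                         max_gap = 0, min_length = 0) {
  checksums <- list()
  if (is.character(input)) {
    checksums$input <- unname(tools::md5sum(input))
    sites <- read_sync_counts(input)
  } else if (is.list(input) && !is.data.frame(input) && !is.null(input$vcf)) {
    checksums$input <- unname(tools::md5sum(input$vcf))
    sites <- read_vcf_counts(input$vcf, input$groups)
  } else if (is.data.frame(input)) {
    sites <- input
  } else {
    stop("pipeline stage 'ingest': unrecognised input")
  }
  n_ingested <- nrow(sites)

  sites <- drop_uncovered(sites)
  n_covered <- nrow(sites)

  qc_res <- tryCatch(run_qc(sites, qc),
                     error = function(e) stop("pipeline stage 'qc': ",
                                              conditionMessage(e)))
  windows <- tryCatch(scan_windows(qc_res$sites, contigs, scan),
                      error = function(e) stop("pipeline stage 'scan': ",
                                               conditionMessage(e)))
  outliers <- extract_outliers(windows, scan$z_cutoff)
  regions <- merge_windows(outliers, max_gap)
  regions <- filter_regions(regions, min_length)

  gene_df <- NULL
  if (!is.null(genes)) {
    gene_df <- if (is.character(genes)) read_gene_intervals(genes) else genes
    regions <- suppressWarnings(annotate_regions(regions, gene_df))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("poolsweep")),
    input_checksums = checksums,
    config = list(
      qc = unclass(qc),
      scan = unclass(scan),
      max_gap = max_gap, min_length = min_length
    ),
    counts = list(
      sites_ingested = n_ingested,
      sites_covered = n_covered,
      sites_retained = qc_res$report$n_retained,
      windows_total = nrow(windows),
      windows_retained = sum(!windows$discarded),
      windows_outlier = nrow(outliers),
      regions = nrow(regions)
    ),
    qc_report = qc_res$report
  )
  stopifnot(manifest$counts$sites_retained <= manifest$counts$sites_covered,
            manifest$counts$sites_covered <= manifest$counts$sites_ingested,
            manifest$counts$windows_outlier <= manifest$counts$windows_retained)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_qc_report(qc_res$report, file.path(out_dir, "qc_report.txt"))
    write_window_track(windows, file.path(out_dir, "windows.tsv"),
                       bedgraph_dir = out_dir)
    write_region_report(regions, file.path(out_dir, "regions.tsv"))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(sites = qc_res$sites, windows = windows, regions = regions,
       manifest = manifest)
}
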