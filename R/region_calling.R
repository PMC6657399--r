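#' Merge dual-outlier windows into candidate sweep regions
#'
#' Same-contig outlier windows whose intervals overlap or lie within
#' `max_gap` bp of each other are combined into one region (the sliding
#' windows overlap by construction at a step smaller than the window, so
#' any contiguous signal merges at the default `max_gap = 0`,
#' i.e. overlap-or-abut). Region bounds are the outer bounds of member
#' windows; per-region maxima are taken over members.
#'
#' @param outlier_windows window table (rows from [extract_outliers()]).
#' @param max_gap maximum gap in bp bridged when merging (default 0).
#' @return data.frame with columns region_id, contig, start, end,
#'   n_windows, max_z_fst, max_z_hp_ratio, sorted by (contig, start).
#' @export
merge_windows <- function(outlier_windows, max_gap = 0) {
  if (nrow(outlier_windows) == 0) {
    return(data.frame(region_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), max_z_fst = numeric(),
                      max_z_hp_ratio = numeric(), stringsAsFactors = FALSE))
  }
  w <- outlier_windows[order(outlier_windows$contig, outlier_windows$start), ,
                       drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = w$contig,
    ranges = IRanges::IRanges(start = w$start, end = w$end)
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    n_windows = lengths(revmap),
    max_z_fst = vapply(revmap, function(i) max(w$z_fst[i]), 0.0),
    max_z_hp_ratio = vapply(revmap, function(i) max(w$z_hp_ratio[i]), 0.0),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("region_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach overlapping genes to candidate regions
#'
#' A gene is attached iff its interval overlaps the region by at least
#' 1 bp (1-based inclusive coordinates on both sides). Gene names are
#' ordered by genomic position within each region.
#'
#' @param regions region table from [merge_windows()].
#' @param gene_intervals data.frame with columns contig, start, end,
#'   gene_name (see [read_gene_intervals()]).
#' @return the region table with a `genes` list-column of character
#'   vectors. Region contigs absent from the gene set trigger a warning.
#' @export
annotate_regions <- function(regions, gene_intervals) {
  if (nrow(regions) == 0) {
    regions$genes <- list()
    return(regions)
  }
  missing_ctg <- setdiff(regions$contig, gene_intervals$contig)
  if (length(missing_ctg) > 0) {
    warning("no gene intervals on contig(s): ",
            paste(missing_ctg, collapse = ", "))
  }
  rg <- GenomicRanges::GRanges(regions$contig,
                               IRanges::IRanges(regions$start, regions$end))
  if (nrow(gene_intervals) == 0) {
    regions$genes <- replicate(nrow(regions), character(), simplify = FALSE)
    return(regions)
  }
  gg <- GenomicRanges::GRanges(gene_intervals$contig,
                               IRanges::IRanges(gene_intervals$start,
                                                gene_intervals$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, gg))
  regions$genes <- lapply(seq_len(nrow(regions)), function(i) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    j <- j[order(gene_intervals$start[j])]
    gene_intervals$gene_name[j]
  })
  regions
}

#' Filter candidate regions on minimum length
#'
#' Retains regions whose 1-based inclusive length `end - start + 1` is at
#' least `min_length` bp. The default 0 keeps everything; a larger value
#' separates sustained sweep signals from short, possibly drift-fixed
#' segments.
#'
#' @param regions region table.
#' @param min_length minimum region length in bp (default 0).
#' @return the retained rows.
#' @export
filter_regions <- function(regions, min_length = 0) {
  regions[(regions$end - regions$start + 1) >= min_length, , drop = FALSE]
}
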