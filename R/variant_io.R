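#' Construct a table of per-site pooled allele counts
#'
#' The central data container of the package: one row per biallelic SNP,
#' with summed read counts for the genome-wide major and minor allele in
#' each of two pools of samples (group A = selected trait, group B =
#' control). Coordinates are 1-based inclusive throughout the package;
#' conversion to 0-based half-open happens only when writing BED.
#'
#' @param contig character vector of contig/chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param qual numeric Phred-scaled site qualities (NA allowed).
#' @param countA_major,countA_minor reads carrying the major / minor allele
#'   in group A.
#' @param countB_major,countB_minor same for group B.
#' @return data.frame with the seven columns above, sorted by
#'   (contig, pos).
#' @export
site_counts <- function(contig, pos, qual,
                        countA_major, countA_minor,
                        countB_major, countB_minor) {
  df <- data.frame(
    contig = as.character(contig),
    pos = as.integer(pos),
    qual = as.numeric(qual),
    countA_major = as.numeric(countA_major),
    countA_minor = as.numeric(countA_minor),
    countB_major = as.numeric(countB_major),
    countB_minor = as.numeric(countB_minor),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$pos >= 1), all(df[, 4:7] >= 0, na.rm = TRUE))
  df[order(df$contig, df$pos), , drop = FALSE]
}

#' Orient allele counts so the pooled major allele comes first
#'
#' Major/minor assignment is made once from the pooled (A+B) counts so that
#' the HP ratio in both groups refers to the same allele partition. Rows
#' where the "minor" total exceeds the "major" total have their two count
#' columns swapped in both groups simultaneously.
#'
#' @param sites a site-count table (see [site_counts()]).
#' @return the table with `countA_major + countB_major >=
#'   countA_minor + countB_minor` at every row.
#' @export
orient_major_minor <- function(sites) {
  tot_major <- sites$countA_major + sites$countB_major
  tot_minor <- sites$countA_minor + sites$countB_minor
  flip <- tot_minor > tot_major
  if (any(flip)) {
    tmpA <- sites$countA_major[flip]
    sites$countA_major[flip] <- sites$countA_minor[flip]
    sites$countA_minor[flip] <- tmpA
    tmpB <- sites$countB_major[flip]
    sites$countB_major[flip] <- sites$countB_minor[flip]
    sites$countB_minor[flip] <- tmpB
  }
  sites
}

#' Read pooled allele counts from a VCF with per-sample allele depths
#'
#' Each sample in the VCF is assigned to group A (selected) or B (control);
#' per-group counts are the sums of the per-sample AD allele depths.
#' Only biallelic SNP records are kept; multi-allelic and non-SNP records
#' are skipped and tallied in the `skip_log` attribute. Major/minor
#' orientation is decided on the pooled (A+B) counts, with ties resolved
#' toward the reference allele.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param group_assignment named character vector mapping every sample name
#'   in the VCF to `"A"` or `"B"`.
#' @return site-count data.frame (see [site_counts()]) with a `skip_log`
#'   attribute: named integer counts of skipped records.
#' @export
read_vcf_counts <- function(path, group_assignment) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(samples, names(group_assignment))
  if (length(missing) > 0) {
    stop("samples in VCF absent from group_assignment: ",
         paste(missing, collapse = ", "))
  }
  grp <- unname(group_assignment[samples])
  if (!all(grp %in% c("A", "B"))) {
    stop("group_assignment values must be 'A' or 'B'")
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  is_multi <- grepl(",", alt)
  keep <- is_snp & !is_multi
  skip_log <- c(multiallelic = sum(is_multi),
                non_snp = sum(!is_snp & !is_multi))

  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF has no per-sample AD (allele depth) field")
  }
  ad <- ad[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) {
    out <- site_counts(character(), integer(), numeric(),
                       numeric(), numeric(), numeric(), numeric())
    attr(out, "skip_log") <- skip_log
    return(out)
  }
  bad <- which(is.na(ad), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("missing AD value at record ", fix[bad[1, 1], "CHROM"], ":",
         fix[bad[1, 1], "POS"], " sample ", colnames(ad)[bad[1, 2]])
  }

  split_ad <- function(j) {  # ref/alt depth matrices, records x samples
    parts <- strsplit(ad, ",", fixed = TRUE)
    vapply(parts, function(p) as.numeric(p[j]), 0.0)
  }
  ref_d <- matrix(split_ad(1), nrow = nrow(ad))
  alt_d <- matrix(split_ad(2), nrow = nrow(ad))
  if (anyNA(ref_d) || anyNA(alt_d)) {
    stop("malformed AD field (expected 'refDepth,altDepth')")
  }

  a_cols <- grp == "A"
  refA <- rowSums(ref_d[, a_cols, drop = FALSE])
  altA <- rowSums(alt_d[, a_cols, drop = FALSE])
  refB <- rowSums(ref_d[, !a_cols, drop = FALSE])
  altB <- rowSums(alt_d[, !a_cols, drop = FALSE])

  # ref is major on ties
  ref_is_major <- (refA + refB) >= (altA + altB)
  out <- site_counts(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    countA_major = ifelse(ref_is_major, refA, altA),
    countA_minor = ifelse(ref_is_major, altA, refA),
    countB_major = ifelse(ref_is_major, refB, altB),
    countB_minor = ifelse(ref_is_major, altB, refB)
  )
  attr(out, "skip_log") <- skip_log
  out
}

#' Read pooled allele counts from a sync-style count table
#'
#' Tab-delimited format with columns contig, pos, ref, then one
#' colon-separated base-count field per group in the order A:T:C:G:N:del
#' (two groups expected, selected first). The two most frequent bases over
#' both groups define the biallelic pair; sites where any third base
#' exceeds `max_third_frac` of the total (default 0, i.e. any third-base
#' read) and monomorphic sites are skipped.
#'
#' @param path path to the sync file.
#' @param max_third_frac maximum tolerated fraction of reads on a third
#'   base before the site is skipped.
#' @return site-count data.frame with a `skip_log` attribute.
#' @export
read_sync_counts <- function(path, max_third_frac = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- site_counts(character(), integer(), numeric(),
                       numeric(), numeric(), numeric(), numeric())
    attr(out, "skip_log") <- c(monomorphic = 0L, multiallelic = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 5L)) {
    stop("malformed sync line ", which(nfield != 5L)[1],
         ": expected 5 tab-separated columns, got ", nfield[nfield != 5L][1])
  }
  m <- do.call(rbind, fields)
  base_order <- c("A", "T", "C", "G", "N", "del")
  parse_counts <- function(col) {
    p <- strsplit(col, ":", fixed = TRUE)
    if (any(lengths(p) != 6L)) {
      stop("malformed sync count field at line ", which(lengths(p) != 6L)[1])
    }
    matrix(as.numeric(unlist(p)), ncol = 6, byrow = TRUE,
           dimnames = list(NULL, base_order))
  }
  cA <- parse_counts(m[, 4])
  cB <- parse_counts(m[, 5])
  tot <- cA[, 1:4, drop = FALSE] + cB[, 1:4, drop = FALSE]  # ACGT only

  n <- nrow(m)
  keep <- logical(n)
  maj_i <- min_i <- integer(n)
  n_mono <- n_multi <- 0L
  ref_idx <- match(m[, 3], base_order[1:4])
  for (i in seq_len(n)) {
    ord <- order(tot[i, ], decreasing = TRUE)
    top2 <- ord[1:2]
    third <- sum(tot[i, ord[3:4]])
    total <- sum(tot[i, ])
    if (tot[i, top2[2]] == 0) {            # monomorphic
      n_mono <- n_mono + 1L
      next
    }
    if (total > 0 && third / total > max_third_frac) {
      n_multi <- n_multi + 1L
      next
    }
    # tie between the pair resolved toward the reference base
    if (tot[i, top2[1]] == tot[i, top2[2]] &&
        !is.na(ref_idx[i]) && top2[2] == ref_idx[i]) {
      top2 <- rev(top2)
    }
    keep[i] <- TRUE
    maj_i[i] <- top2[1]
    min_i[i] <- top2[2]
  }
  idx <- which(keep)
  out <- site_counts(
    contig = m[idx, 1],
    pos = as.integer(m[idx, 2]),
    qual = NA_real_,
    countA_major = cA[cbind(idx, maj_i[idx])],
    countA_minor = cA[cbind(idx, min_i[idx])],
    countB_major = cB[cbind(idx, maj_i[idx])],
    countB_minor = cB[cbind(idx, min_i[idx])]
  )
  attr(out, "skip_log") <- c(monomorphic = n_mono, multiallelic = n_multi)
  out
}

#' Write a site-count table as a sync-style file
#'
#' Inverse of [read_sync_counts()] up to base identity: the major allele is
#' written as A and the minor as C for every site (base identity is not part
#' of the count model).
#'
#' @param sites site-count table.
#' @param path output path.
#' @export
write_sync_counts <- function(sites, path) {
  fmt <- function(maj, min) sprintf("%d:0:%d:0:0:0", as.integer(maj), as.integer(min))
  lines <- paste(sites$contig, sites$pos, "A",
                 fmt(sites$countA_major, sites$countA_minor),
                 fmt(sites$countB_major, sites$countB_minor),
                 sep = "\t")
  writeLines(lines, path)
}

#' Read gene intervals from GFF3 or BED
#'
#' @param path path to a GFF3 (`.gff`, `.gff3`) or BED file; format picked
#'   by extension.
#' @param name_field GFF3 attribute holding the gene name (default
#'   `"Name"`, falling back to `"ID"` when absent).
#' @param feature_type GFF3 feature type to keep (default `"gene"`; ignored
#'   for BED).
#' @return data.frame with columns contig, start, end, gene_name
#'   (1-based inclusive coordinates).
#' @export
read_gene_intervals <- function(path, name_field = "Name",
                                feature_type = "gene") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(gr$type) && !is.null(feature_type)) {
      gr <- gr[as.character(gr$type) == feature_type]
    }
    nm <- S4Vectors::mcols(gr)[[name_field]]
    if (is.null(nm)) nm <- gr$ID
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- gr$name
  } else {
    stop("unrecognised gene-interval format: .", ext)
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_name = as.character(nm),
    stringsAsFactors = FALSE
  )
}

#' Write candidate sweep regions as BED
#'
#' Regions are written 0-based half-open; the name field carries the region
#' id and the score field the region's max Z(FST) clipped to [0, 1000].
#'
#' @param regions region table from [merge_windows()] (sorted by contig
#'   then start; unsorted input is an error).
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) > 1) {
    o <- order(regions$contig, regions$start)
    if (!identical(o, seq_len(nrow(regions)))) {
      stop("regions must be sorted by (contig, start)")
    }
  }
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(NULL))
  }
  ids <- if (!is.null(regions$region_id)) regions$region_id else
    sprintf("region_%03d", seq_len(nrow(regions)))
  score <- pmin(pmax(regions$max_z_fst, 0), 1000)
  lines <- paste(regions$contig,
                 format(regions$start - 1L, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 ids,
                 format(score, scientific = FALSE, trim = TRUE),
                 ".",
                 sep = "\t")
  writeLines(lines, path)
}

#' Read a regions BED written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return data.frame with contig, start, end (1-based inclusive),
#'   region_id, score.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), region_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(
    contig = m[, 1],
    start = as.integer(m[, 2]) + 1L,
    end = as.integer(m[, 3]),
    region_id = m[, 4],
    score = as.numeric(m[, 5]),
    stringsAsFactors = FALSE
  )
}

#' Write the tabular candidate-region report
#'
#' Tab-delimited with columns Chr, Start, End, Max.Z.FST, Max.Z.HP.ratio,
#' Candidate.genes (comma-joined gene names, "-" when none).
#'
#' @param regions annotated region table.
#' @param path output path.
#' @export
write_region_report <- function(regions, path) {
  genes <- if (!is.null(regions$genes)) {
    vapply(regions$genes, function(g) {
      if (length(g) == 0) "-" else paste(g, collapse = ", ")
    }, "")
  } else rep("-", nrow(regions))
  df <- data.frame(
    Chr = regions$contig,
    Start = regions$start,
    End = regions$end,
    Max.Z.FST = regions$max_z_fst,
    Max.Z.HP.ratio = regions$max_z_hp_ratio,
    Candidate.genes = genes,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the per-window scan track
#'
#' Tab-delimited track of every window's statistics, plus optional bedGraph
#' companions (one per statistic) for genome-browser loading.
#'
#' @param windows window table from [scan_windows()].
#' @param path output TSV path.
#' @param bedgraph_dir if non-NULL, directory to receive
#'   `z_fst.bedgraph` and `z_hp_ratio.bedgraph`.
#' @export
write_window_track <- function(windows, path, bedgraph_dir = NULL) {
  cols <- c("contig", "start", "end", "n_sites", "hpA", "hpB",
            "ln_hp_ratio", "fst", "z_fst", "z_hp_ratio")
  utils::write.table(windows[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedgraph_dir)) {
    ok <- !windows$discarded
    for (stat in c("z_fst", "z_hp_ratio")) {
      bg <- paste(windows$contig[ok],
                  format(windows$start[ok] - 1L, scientific = FALSE, trim = TRUE),
                  format(windows$end[ok], scientific = FALSE, trim = TRUE),
                  format(windows[[stat]][ok], scientific = FALSE, trim = TRUE),
                  sep = "\t")
      writeLines(bg, file.path(bedgraph_dir, paste0(stat, ".bedgraph")))
    }
  }
  invisible(NULL)
}
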