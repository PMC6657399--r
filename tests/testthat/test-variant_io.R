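test_that("VCF ingestion sums per-sample allele depths by group", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  records <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300), ref = c("A", "C", "G"),
    alt = c("G", "T,A", "GT"), qual = c(50, 60, 60),
    s1 = c("12,3", "5,5", "4,4"),
    s2 = c("10,5", "5,5", "4,4"),
    s3 = c("8,8", "5,5", "4,4"),
    stringsAsFactors = FALSE
  )
  write_test_vcf(vcf, records, c("s1", "s2", "s3"))
  sites <- read_vcf_counts(vcf, c(s1 = "A", s2 = "A", s3 = "B"))

  # only the biallelic SNP survives; multi-allelic and indel are logged
  expect_equal(nrow(sites), 1)
  expect_equal(attr(sites, "skip_log")[["multiallelic"]], 1)
  expect_equal(attr(sites, "skip_log")[["non_snp"]], 1)

  # hand-summed depths: A = (12,3)+(10,5), B = (8,8); ref is the majority
  expect_equal(sites$countA_major, 22)
  expect_equal(sites$countA_minor, 8)
  expect_equal(sites$countB_major, 8)
  expect_equal(sites$countB_minor, 8)
  expect_equal(sites$qual, 50)

  # conservation: group sums equal the sum of per-sample depths
  expect_equal(sum(sites[, 4:7]), 12 + 3 + 10 + 5 + 8 + 8)

  expect_error(read_vcf_counts(vcf, c(s1 = "A", s2 = "A")),
               "absent from group_assignment")
})

test_that("major/minor orientation flips when ALT is the pooled majority", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  records <- data.frame(
    chrom = "chr1", pos = 100, ref = "A", alt = "G", qual = 50,
    s1 = "2,20", s2 = "3,15", stringsAsFactors = FALSE
  )
  write_test_vcf(vcf, records, c("s1", "s2"))
  sites <- read_vcf_counts(vcf, c(s1 = "A", s2 = "B"))
  # ALT depths (20, 15) dominate REF (2, 3): labels swap relative to ref/alt
  expect_equal(sites$countA_major, 20)
  expect_equal(sites$countA_minor, 2)
  expect_equal(sites$countB_major, 15)
  expect_equal(sites$countB_minor, 3)
})

test_that("sync ingestion parses counts and skips degenerate sites", {
  sync <- withr::local_tempfile(fileext = ".sync")
  writeLines(c(
    "chr1\t100\tA\t10:0:5:0:0:0\t8:0:8:0:0:0",   # biallelic A/C
    "chr1\t200\tA\t10:0:0:0:0:0\t12:0:0:0:0:0",  # monomorphic
    "chr1\t300\tA\t10:5:5:0:0:0\t8:4:4:0:0:0"    # three segregating bases
  ), sync)
  sites <- read_sync_counts(sync)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$countA_major, 10)
  expect_equal(sites$countA_minor, 5)
  expect_equal(sites$countB_major, 8)
  expect_equal(sites$countB_minor, 8)
  expect_equal(attr(sites, "skip_log")[["monomorphic"]], 1)
  expect_equal(attr(sites, "skip_log")[["multiallelic"]], 1)

  writeLines("chr1\t100\tA\t1:0:0:0:0:0", sync)
  expect_error(read_sync_counts(sync), "line 1")
})

test_that("VCF and sync readers agree on equivalent inputs", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  records <- data.frame(
    chrom = "chr1", pos = c(100, 250), ref = c("A", "A"),
    alt = c("G", "C"), qual = c(50, 50),
    s1 = c("12,3", "7,9"), s2 = c("10,5", "6,8"), s3 = c("8,8", "20,2"),
    stringsAsFactors = FALSE
  )
  write_test_vcf(vcf, records, c("s1", "s2", "s3"))
  from_vcf <- read_vcf_counts(vcf, c(s1 = "A", s2 = "A", s3 = "B"))

  sync <- withr::local_tempfile(fileext = ".sync")
  # same counts: site 1 A-ref majority; site 2 minor allele C dominant in A
  writeLines(c(
    "chr1\t100\tA\t22:0:0:8:0:0\t8:0:0:8:0:0",
    "chr1\t250\tA\t13:0:17:0:0:0\t20:0:2:0:0:0"
  ), sync)
  from_sync <- read_sync_counts(sync)
  cols <- c("contig", "pos", "countA_major", "countA_minor",
            "countB_major", "countB_minor")
  expect_equal(from_vcf[, cols], from_sync[, cols],
               ignore_attr = TRUE)
})

test_that("region BED round-trips under the 1-based/BED convention", {
  regions <- data.frame(
    region_id = c("region_001", "region_002"),
    contig = c("chr7", "chr9"),
    start = c(82270000L, 1L), end = c(82640000L, 50000L),
    n_windows = c(10L, 2L),
    max_z_fst = c(41.194798, 6.5), max_z_hp_ratio = c(11.822053, 5.5),
    stringsAsFactors = FALSE
  )
  bed <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, bed)
  lines <- readLines(bed)
  # 1-based inclusive start becomes 0-based half-open
  expect_match(lines[1], "^chr7\t82269999\t82640000\t")
  back <- read_regions_bed(bed)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$contig, regions$contig)

  expect_error(write_regions_bed(regions[2:1, ], bed), "sorted")

  write_regions_bed(regions[0, ], bed)
  expect_equal(nrow(read_regions_bed(bed)), 0)
})

test_that("sync writer round-trips a site-count table", {
  sim <- small_sim(seed = 3, length = 2e5)
  sites <- drop_uncovered(sim$sites)
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync_counts(sites, path)
  back <- read_sync_counts(path)
  cols <- c("contig", "pos", "countA_major", "countA_minor",
            "countB_major", "countB_minor")
  # monomorphic sites (minor sum 0) are skipped on re-read by design
  poly <- sites$countA_minor + sites$countB_minor > 0
  expect_equal(back[, cols], sites[poly, cols], ignore_attr = TRUE)
})

test_that("gene intervals load from GFF3 and BED", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr7\t.\tgene\t82350000\t82380000\t.\t+\t.\tID=g1;Name=VRTN",
    "chr7\t.\tmRNA\t82350000\t82380000\t.\t+\t.\tID=t1;Parent=g1",
    "chr7\t.\tgene\t82400000\t82420000\t.\t-\t.\tID=g2;Name=NPC2"
  ), gff)
  genes <- read_gene_intervals(gff)
  expect_equal(genes$gene_name, c("VRTN", "NPC2"))
  expect_equal(genes$start, c(82350000L, 82400000L))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr7\t82349999\t82380000\tVRTN", bed)
  genes_bed <- read_gene_intervals(bed)
  expect_equal(genes_bed$start, 82350000L)  # BED 0-based becomes 1-based
  expect_equal(genes_bed$gene_name, "VRTN")
})
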