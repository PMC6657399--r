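test_that("pooled heterozygosity matches the closed form and its bounds", {
  # fixed for the major allele
  expect_equal(pooled_heterozygosity(c(10, 20, 30), c(0, 0, 0)), 0)
  # maximum at equal sums
  expect_equal(pooled_heterozygosity(10, 10), 0.5)
  # sites {(30,5),(20,20),(40,0)}: a=90, b=25 -> 4500/13225
  expect_equal(pooled_heterozygosity(c(30, 20, 40), c(5, 20, 0)),
               4500 / 13225)
  expect_true(is.na(pooled_heterozygosity(0, 0)))

  # bound property over random counts; 0.5 only when a == b
  set.seed(11)
  for (i in 1:200) {
    a <- rpois(5, 20); b <- rpois(5, 5)
    hp <- pooled_heterozygosity(a, b)
    expect_true(hp >= 0 && hp <= 0.5)
    if (hp == 0.5) expect_equal(sum(a), sum(b))
  }
})

test_that("per-site Hudson FST matches hand-evaluated values", {
  # p1=0.8, p2=0.2, n1=n2=20
  s <- site_counts("c1", 100, 50, countA_major = 2, countA_minor = 8,
                   countB_major = 8, countB_minor = 2)
  f <- snp_fst(s, "hudson", haploids_A = 20, haploids_B = 20)
  expect_equal(f$num, 0.36 - 2 * (0.8 * 0.2 / 19), tolerance = 1e-12)
  expect_equal(f$den, 0.8 * 0.8 + 0.2 * 0.2, tolerance = 1e-12)
  expect_equal(f$num / f$den, 0.504644, tolerance = 1e-6)

  # fixed difference, large n: ratio tends to 1
  s2 <- site_counts("c1", 100, 50, 0, 30, 30, 0)
  f2 <- snp_fst(s2, "hudson", 1000, 1000)
  expect_equal(f2$num / f2$den, 1, tolerance = 1e-2)

  # identical frequencies: the correction makes the numerator <= 0
  s3 <- site_counts("c1", 100, 50, 15, 5, 30, 10)
  f3 <- snp_fst(s3, "hudson", 20, 20)
  expect_lte(f3$num, 0)

  # wright_mean drops the correction entirely
  f4 <- snp_fst(s3, "wright_mean")
  expect_equal(f4$num, 0)

  expect_error(snp_fst(s, "hudson", haploids_A = 1, haploids_B = 20),
               "exceed 1")
})

test_that("window FST is a ratio of sums", {
  expect_equal(window_fst(c(0.3431579, 0), c(0.68, 0.5)),
               0.3431579 / 1.18)
  expect_true(is.na(window_fst(numeric(0), numeric(0))))
  expect_true(is.na(window_fst(c(0.1), c(0))))
  # a window of identical fixed-difference sites gives exactly 1
  s <- site_counts("c1", c(100, 200), c(50, 50), c(0, 0), c(30, 30),
                   c(30, 30), c(0, 0))
  f <- snp_fst(s, "wright_mean")
  expect_equal(window_fst(f$num, f$den), 1)
})

test_that("window enumeration matches the closed form over a grid", {
  for (L in c(1, 49999, 50000, 50001, 99999, 100000, 123456, 1000000)) {
    for (W in c(50000, 45000)) {
      for (S in c(10000, 5000, W)) {
        w <- make_windows(data.frame(contig = "c", length = L), W, S)
        expected <- if (L < W) 0 else (L - W) %/% S + 1
        expect_equal(nrow(w), expected,
                     info = sprintf("L=%d W=%d S=%d", L, W, S))
        if (nrow(w) > 0) {
          expect_equal(w$start[1], 1)
          expect_true(all(w$end <= L))            # windows fit the contig
          expect_true(all(w$end - w$start + 1 == W))
          if (nrow(w) > 1) expect_equal(unique(diff(w$start)), S)
        }
      }
    }
  }
  # L=100000, 50-kb windows, 10-kb step -> 6 windows
  expect_equal(nrow(make_windows(data.frame(contig = "c", length = 1e5))), 6)
})

test_that("Z-transformation standardizes with the sample (n-1) sd", {
  expect_equal(z_transform(c(0, 2)), c(-1, 1) / sqrt(2))
  set.seed(4)
  x <- rnorm(500, mean = 3, sd = 7)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_error(z_transform(rep(1, 5)), "dispersion")
  expect_error(z_transform(2), "fewer than 2")
})

test_that("scan flags thin windows and floors zero heterozygosity", {
  cfg <- scan_config(window_size = 1000L, step = 1000L, min_sites = 10L)
  contigs <- data.frame(contig = "c1", length = 3000)
  # window 1: 9 sites (below min_sites); window 2: 12 polymorphic sites;
  # window 3: 12 sites with group A fixed (hpA = 0)
  mk <- function(pos, majA, minA) {
    site_counts("c1", pos, 50, majA, minA, 30, 10)
  }
  s <- rbind(
    mk(seq(10, 810, by = 100), 30, 10),
    mk(seq(1010, 1890, by = 80), 28, 12),
    mk(seq(2010, 2890, by = 80), 40, 0)
  )
  s <- s[order(s$pos), ]
  out <- scan_windows(s, contigs, cfg)
  expect_equal(out$n_sites, c(9, 12, 12))
  expect_true(out$discarded[1])
  expect_true(all(is.na(out[1, c("z_fst", "z_hp_ratio")])))
  # hpA = 0 triggers the floor: ln ratio = ln(hpB / hp_floor) > 0
  expect_equal(out$hpA[3], 0)
  expect_equal(out$ln_hp_ratio[3],
               log(out$hpB[3]) - log(cfg$hp_floor))

  # identical counts in both groups: ln ratio exactly 0 everywhere
  s_null <- s
  s_null$countB_major <- s_null$countA_major
  s_null$countB_minor <- s_null$countA_minor
  out_null <- scan_windows(s_null, contigs, cfg)
  expect_equal(out_null$ln_hp_ratio, rep(0, 3))
})

test_that("the window engine matches a from-scratch oracle bit for bit", {
  sim <- small_sim(seed = 21, length = 1.5e6)
  sites <- drop_uncovered(sim$sites)
  cfg <- scan_config()
  got <- scan_windows(sites, data.frame(contig = "chr1", length = 1.5e6), cfg)
  want <- naive_scan_oracle(sites,
                            data.frame(contig = "chr1", length = 1.5e6), cfg)
  expect_equal(got$n_sites, want$n_sites)
  expect_identical(got$hpA, want$hpA)
  expect_identical(got$hpB, want$hpB)
  expect_identical(got$fst, want$fst)
})

test_that("swapping groups negates the log HP ratio and preserves FST", {
  sim <- small_sim(seed = 5,
                   sweeps = data.frame(contig = "chr1", start = 5e5 + 1,
                                       end = 8e5, het_reduction = 0.1,
                                       divergence_shift = 0.3))
  sites <- drop_uncovered(sim$sites)
  contigs <- data.frame(contig = "chr1", length = 2e6)
  cfg <- scan_config()
  cfg_sw <- scan_config(haploids_A = cfg$haploids_B,
                        haploids_B = cfg$haploids_A)
  a <- scan_windows(sites, contigs, cfg)
  b <- scan_windows(swap_groups(sites), contigs, cfg_sw)
  expect_identical(b$ln_hp_ratio, -a$ln_hp_ratio)
  expect_identical(b$fst, a$fst)
  expect_identical(b$hpA, a$hpB)
  # the sweep's positive HP-ratio tail moves to the opposite tail:
  # the most negative swapped Z lies inside the planted interval
  expect_identical(b$z_hp_ratio, -a$z_hp_ratio)
  idx <- which.min(b$z_hp_ratio)
  expect_true(b$start[idx] <= 8e5 && b$end[idx] >= 5e5 + 1)
})

test_that("outlier extraction intersects both Z-scores strictly", {
  w <- data.frame(
    contig = "c1", start = c(1, 11, 21, 31), end = c(10, 20, 30, 40),
    z_fst = c(41.19, 6.0, 5.0, 7.2), z_hp_ratio = c(11.82, 4.9, 7.0, 5.0),
    discarded = FALSE
  )
  out <- extract_outliers(w, 5)
  expect_equal(out$start, 1)   # only the dual outlier; exact-5 rows fail
})
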