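test_that("per-bulk and delta indices respect their definitions and ranges", {
  expect_equal(snp_index(20, 0), 0)
  expect_equal(snp_index(0, 30), 1)
  expect_equal(snp_index(15, 15), 0.5)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(-1, 4), ">= 0")
  expect_equal(delta_index(0.9, 0.1), 0.8)
  expect_equal(delta_index(0.5, 0.5), 0)
  expect_equal(delta_index(0, 1), -1)
  expect_error(delta_index(1.2, 0.5), "\\[0, 1\\]")
  set.seed(1)
  r <- rpois(500, 20); a <- rpois(500, 20)
  idx <- snp_index(r, a)
  ok <- !is.na(idx)
  expect_true(all(idx[ok] >= 0 & idx[ok] <= 1))
  d <- delta_index(idx[ok], rev(idx[ok]))
  expect_true(all(d >= -1 & d <= 1))
})

test_that("site filters drop low-depth and double-low-index sites", {
  sites <- data.frame(chrom = "3", pos = c(100, 200, 300, 400),
                      ref_hi = c(20, 3, 18, 2), alt_hi = c(20, 2, 2, 28),
                      ref_lo = c(25, 20, 25, 10), alt_lo = c(15, 20, 3, 20))
  out <- index_sites(sites)
  expect_equal(out$pos, c(100, 400))  # pos 200 low depth, pos 300 both < 0.3
  expect_equal(out$delta, c(0.5 - 0.375, 28 / 30 - 20 / 30), tolerance = 1e-12)
  out2 <- index_sites(sites, min_depth = 0, min_index = 0)
  expect_equal(nrow(out2), 4)
})

test_that("window smoothing equals brute-force re-averaging", {
  const <- data.frame(chrom = "1", pos = seq(1e5, 5e6, by = 1e5), delta = 0.3)
  tr <- smooth_track(const)
  expect_true(all(abs(tr$delta - 0.3) < 1e-12, na.rm = TRUE))

  single <- data.frame(chrom = "1", pos = 2e6, delta = 0.42)
  tr1 <- smooth_track(single)
  expect_equal(tr1$delta, 0.42)

  set.seed(8)
  sites <- data.frame(chrom = "1", pos = sort(sample(1:3e6, 150)),
                      delta = runif(150, -1, 1))
  tr2 <- smooth_track(sites, window = 5e5, step = 1e5)
  for (i in seq_len(nrow(tr2))) {
    inw <- sites$pos >= tr2$start[i] & sites$pos <= tr2$end[i]
    if (!any(inw)) expect_true(is.na(tr2$delta[i]))
    else expect_equal(tr2$delta[i], mean(sites$delta[inw]), tolerance = 1e-12)
  }
  expect_error(smooth_track(sites[c(5, 1, 2), ]), "sorted")
  expect_error(smooth_track(sites, window = 1e4, step = 1e5), "window >= step")
})

test_that("null bands are symmetric, deterministic and shrink with depth", {
  one <- function(depth, n_sim = 1e4, seed = 42) {
    s <- data.frame(chrom = "1", pos = 1e6,
                    ref_hi = depth / 2, alt_hi = depth / 2,
                    ref_lo = depth / 2, alt_lo = depth / 2)
    null_band(s, pool_size = 30, n_sim = n_sim, seed = seed)
  }
  b30 <- one(30)
  expect_lt(abs(b30$hi_95 + b30$lo_95), 0.02)   # symmetry about 0
  expect_lt(abs(b30$hi_99 + b30$lo_99), 0.03)
  expect_gt(b30$hi_99, b30$hi_95)               # nested levels
  expect_identical(one(30), one(30))            # same seed, same band
  w <- vapply(c(10, 100, 1000), function(d) {
    b <- one(d); b$hi_95 - b$lo_95
  }, numeric(1))
  expect_true(all(diff(w) < 0))                 # width falls as depth grows
  s <- data.frame(chrom = "1", pos = 1, ref_hi = 5, alt_hi = 5,
                  ref_lo = 5, alt_lo = 5)
  expect_error(null_band(s, n_sim = 500), ">= 1000")
  expect_error(null_band(s, n_sim = 1000, levels = 0.999), "too small")
})

test_that("interval calling finds plateaus and respects the band", {
  mk_track <- function(delta) {
    sites <- data.frame(chrom = "1", pos = seq_along(delta) * 1e5,
                        delta = delta)
    tr <- smooth_track(sites, window = 1e5, step = 1e5)
    tr$lo_95 <- -0.3; tr$hi_95 <- 0.3
    tr
  }
  delta <- rep(0, 30); delta[11:15] <- 0.6
  calls <- call_intervals(mk_track(delta), 0.95)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$peak_delta, 0.6)
  expect_true(calls$start <= 11 * 1e5 && calls$end >= 15 * 1e5)

  expect_equal(nrow(call_intervals(mk_track(rep(0.1, 30)), 0.95)), 0)
  expect_error(call_intervals(mk_track(rep(0, 5)), 0.99), "no band")

  # orientation: negating delta mirrors the calls under a symmetric band
  neg <- call_intervals(mk_track(-delta), 0.95)
  expect_equal(neg[, c("chrom", "start", "end")],
               calls[, c("chrom", "start", "end")])
  expect_equal(neg$peak_delta, -calls$peak_delta)

  # opposite-sign runs are not merged
  d2 <- rep(0, 30); d2[5:8] <- 0.5; d2[9:12] <- -0.5
  expect_equal(nrow(call_intervals(mk_track(d2), 0.95)), 2)
})

test_that("swapping the pools negates every delta index", {
  set.seed(12)
  sites <- data.frame(chrom = "1", pos = sort(sample(1e6, 50)),
                      ref_hi = rpois(50, 15), alt_hi = rpois(50, 15),
                      ref_lo = rpois(50, 15), alt_lo = rpois(50, 15))
  a <- index_sites(sites, min_depth = 1, min_index = 0)
  swapped <- sites
  names(swapped)[3:6] <- c("ref_lo", "alt_lo", "ref_hi", "alt_hi")
  b <- index_sites(swapped, min_depth = 1, min_index = 0)
  expect_equal(b$delta, -a$delta)
})

test_that("oriented allele depths can be pulled from a VCF", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    # donor hom-alt, recipient hom-ref: orientation kept
    vcf_row(1000, "A", "G", c(0, 25), c(30, 0), c(18, 6), c(4, 16)),
    # donor hom-ref, recipient hom-alt: counts must flip
    vcf_row(2000, "T", "C", c(28, 1), c(0, 22), c(5, 15), c(12, 8)),
    # parents not opposite homozygotes: dropped
    vcf_row(3000, "G", "A", c(10, 12), c(30, 0), c(9, 9), c(9, 9)),
    # indel, kept and classified
    vcf_row(4000, "AT", "A", c(0, 20), c(25, 0), c(10, 10), c(10, 10))))
  d <- read_bulk_vcf(f, tolerant = "LTGpool", sensitive = "WTpool",
                     donor = "S6", recipient = "HJX74")
  expect_equal(d$pos, c(1000, 2000, 4000))
  expect_equal(d$class, c("SNP", "SNP", "InDel"))
  # site 1: donor allele is ALT
  expect_equal(d$alt_hi[1], 6); expect_equal(d$ref_hi[1], 18)
  # site 2: donor allele is REF, so depths flip
  expect_equal(d$alt_hi[2], 5); expect_equal(d$ref_hi[2], 15)
  expect_equal(d$alt_lo[2], 12); expect_equal(d$ref_lo[2], 8)
})
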