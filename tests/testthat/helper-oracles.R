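# Brute-force oracles and small generators shared across test files.

# Grid oracle for the interval engine: a grid point is a candidate iff it
# lies inside every member (closed) interval and not strictly inside any
# negative interval.  Returns the candidate membership vector.
grid_candidates <- function(grid, members, negatives) {
  ok <- rep(TRUE, length(grid))
  for (m in members) ok <- ok & grid >= m[1] - 1e-9 & grid <= m[2] + 1e-9
  for (n in negatives) ok <- ok & !(grid > n[1] + 1e-9 & grid < n[2] - 1e-9)
  ok
}

# membership of grid points in a set of [start, end] rows
grid_member <- function(grid, intervals) {
  ok <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(intervals))) {
    ok <- ok | (grid >= intervals$start[i] - 1e-9 &
                grid <= intervals$end[i] + 1e-9)
  }
  ok
}

# random closed interval with endpoints on the 0.1 grid in [0, 100]
rand_iv <- function() sort(sample(0:1000, 2, replace = TRUE)) / 10

# wrap bare cM intervals as segments on one chromosome
seg1 <- function(core, maximal = core) {
  substituted_segment("1", core, maximal)
}

# season-structured replicate draws around a mean
season_reps <- function(means, n = 5, sd = 0.03,
                        seasons = paste0("s", seq_along(means))) {
  stats::setNames(lapply(means, function(m) {
    pmin(1, pmax(0, stats::rnorm(n, m, sd)))
  }), seasons)
}

# tiny uncompressed VCF with AD fields for 4 samples
write_test_vcf <- function(path, rows) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##contig=<ID=3,length=30000000>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S6", "HJX74", "LTGpool", "WTpool",
                 sep = "\t"))
  writeLines(c(hdr, rows), path)
}

vcf_row <- function(pos, ref, alt, ad_donor, ad_recip, ad_hi, ad_lo) {
  fmt <- function(ad, gt) paste0(gt, ":", ad[1], ",", ad[2])
  gt_of <- function(ad) if (ad[2] >= ad[1]) "1/1" else "0/0"
  paste("3", pos, ".", ref, alt, ".", "PASS", ".", "GT:AD",
        fmt(ad_donor, gt_of(ad_donor)), fmt(ad_recip, gt_of(ad_recip)),
        fmt(ad_hi, "0/1"), fmt(ad_lo, "0/1"), sep = "\t")
}
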