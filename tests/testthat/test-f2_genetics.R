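test_that("segregation chi-square reproduces hand and published values", {
  r <- segregation_chi2(c(85, 173, 98))
  expect_equal(round(r$chi2, 2), 1.23)
  expect_equal(r$df, 2)
  expect_lt(r$chi2, qchisq(0.95, 2))  # accepted as 1:2:1
  expect_equal(segregation_chi2(c(89, 178, 89))$chi2, 0)
  expect_equal(segregation_chi2(c(30, 30, 30))$chi2, 10)  # 2.5 + 5 + 2.5
  expect_error(segregation_chi2(c(0, 0, 0)), "positive total")
  expect_error(segregation_chi2(c(10, 10), c(1, 0)), "zero")
})

test_that("segregation chi-square matches chisq.test on random count triples", {
  set.seed(9)
  for (i in 1:200) {
    cnt <- rpois(3, 40) + 1
    ratio <- sample(1:4, 3, replace = TRUE)
    got <- segregation_chi2(cnt, ratio)
    ref <- suppressWarnings(chisq.test(cnt, p = ratio / sum(ratio)))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("model-1 coefficients equal the group-mean contrasts", {
  # published genotype means 52 / 65 / 78 % -> a = 0.13, d = 0
  g <- rep(1:3, each = 20)
  y <- rep(c(0.52, 0.65, 0.78), each = 20)
  f <- suppressWarnings(fit_model1(g, y))
  expect_equal(f$a, 0.13, tolerance = 1e-12)
  expect_equal(f$d, 0, tolerance = 1e-12)

  # saturated model: contrasts hold exactly for arbitrary class sizes
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:30, 3)
    g <- rep(1:3, n)
    y <- rnorm(sum(n), 0.6 + 0.1 * (g - 2), 0.08)
    m <- tapply(y, g, mean)
    f <- fit_model1(g, y)
    expect_equal(f$a, unname((m[3] - m[1]) / 2), tolerance = 1e-10)
    expect_equal(f$d, unname(m[2] - (m[1] + m[3]) / 2), tolerance = 1e-10)
    expect_true(f$r2 >= 0 && f$r2 <= 1)
  }
})

test_that("model-1 degenerate designs are flagged", {
  f0 <- suppressWarnings(fit_model1(rep(1:3, each = 4), rep(0.5, 12)))
  expect_equal(f0$a, 0); expect_equal(f0$d, 0); expect_equal(f0$r2, 0)
  expect_error(fit_model1(rep(2, 10), runif(10)), "singular")
  expect_warning(f2c <- fit_model1(rep(c(1, 3), 5), runif(10)),
                 "two genotype classes")
  expect_false(f2c$estimable[["d"]])
  expect_error(fit_model1(c(0, 1, 2), c(0.1, 0.2, 0.3)), "codes")
  expect_message(fit_model1(c(1, 2, 3, NA, 2, 1, 3, 2), runif(8)), "dropped")
})

test_that("marker-trait association behaves as Pearson correlation should", {
  expect_equal(marker_trait_association(c(1, 2, 3, 1, 2, 3),
                                        c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3))$r, 1)
  set.seed(13)
  g <- sample(1:3, 2000, TRUE, prob = c(1, 2, 1))
  expect_lt(abs(marker_trait_association(g, runif(2000))$r), 0.08)
  # affine invariance of r
  y <- runif(30); g30 <- sample(1:3, 30, TRUE)
  expect_equal(marker_trait_association(g30, y)$r,
               marker_trait_association(g30, 5 - 3 * y)$r * -1,
               tolerance = 1e-12)
  expect_error(marker_trait_association(rep(2, 10), runif(10)), "zero variance")
  expect_error(marker_trait_association(c(1, 2), c(0.1, 0.2)), ">= 3")
})

test_that("association strength matches the Monte-Carlo oracle band", {
  set.seed(31)
  rs <- replicate(200, {
    g <- sample(1:3, 80, TRUE, prob = c(1, 2, 1))
    y <- 0.65 + 0.13 * (g - 2) + rnorm(80, 0, 0.1)
    marker_trait_association(g, y)$r
  })
  expect_gte(median(rs), 0.5)
  expect_lte(median(rs), 0.8)
})

test_that("fine mapping recovers the published topology on the fixture", {
  pops <- ltg_recombinants()
  res <- fine_map(pops)
  expect_equal(res$start, 6026000)
  expect_equal(res$end, 6358700)
  expect_equal((res$end - res$start) / 1000, 332.7)  # M6026-M6341 span

  one <- fine_map(pops[pops$recomb_id == "S6_R1", ])
  expect_equal(c(one$start, one$end), c(6026000, 6500000))

  bad <- data.frame(recomb_id = c("a", "b"), chrom = "3",
                    het_start_bp = c(100, 50), het_end_bp = c(200, 400),
                    p = c(0.001, 0.5))
  expect_error(fine_map(bad), "exclude")
  expect_error(fine_map(pops[pops$p > 0.05, ]), "no significant")
})

test_that("fine mapping equals the 1-bp grid oracle on small cases", {
  set.seed(77)
  for (case in 1:200) {
    n <- sample(2:5, 1)
    s <- sample(0:9000, n); e <- s + sample(200:1000, n, TRUE)
    p <- ifelse(runif(n) < 0.5, 1e-4, 0.5)
    if (!any(p < 0.01)) p[1] <- 1e-4
    pops <- data.frame(recomb_id = paste0("r", 1:n), chrom = "3",
                       het_start_bp = s, het_end_bp = e, p = p)
    got <- tryCatch(fine_map(pops), error = function(e) conditionMessage(e))
    sig <- pops[pops$p < 0.01, ]
    neg <- pops[pops$p >= 0.01, ]
    grid <- 0:10000
    want <- grid_candidates(grid,
                            lapply(seq_len(nrow(sig)), function(i) {
                              c(sig$het_start_bp[i], sig$het_end_bp[i])
                            }),
                            lapply(seq_len(nrow(neg)), function(i) {
                              c(neg$het_start_bp[i], neg$het_end_bp[i])
                            }))
    if (is.character(got)) {
      expect_true(grepl("conflict|exclude", got))
      # a conflict is legitimate only when intersection (possibly after
      # subtraction) is empty; oracle candidate runs must then be empty
      # or the empty-intersection case
      inter_lo <- max(sig$het_start_bp); inter_hi <- min(sig$het_end_bp)
      if (inter_lo <= inter_hi) expect_false(any(want))
    } else {
      expect_identical(grid_member(grid, got[, c("start", "end")]), want,
                       label = paste("case", case))
    }
  }
})
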