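test_that("arcsine transform maps boundaries correctly and rejects bad input", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(-0.01), "outside")
  expect_error(arcsine_transform(1.2), "outside")
  expect_true(is.na(arcsine_transform(NA_real_)))
})

test_that("effect estimation follows the half-difference / parent-relative formulas", {
  e <- estimate_effect(0.86, 0.54)
  expect_equal(e$a, 0.16)
  expect_equal(e$r2, 0.16 / 0.54, tolerance = 1e-12)
  expect_equal(estimate_effect(0.4, 0.4), list(a = 0, r2 = 0))
  expect_error(estimate_effect(0.5, 0), "parent mean")
  # antisymmetry: a +delta shift and a -delta shift negate a and r2
  for (delta in c(0.05, 0.2, 0.31)) {
    up <- estimate_effect(0.5 + delta, 0.5)
    dn <- estimate_effect(0.5 - delta, 0.5)
    expect_equal(up$a, -dn$a)
    expect_equal(up$r2, -dn$r2)
  }
})

test_that("published per-line effects are internally consistent", {
  # a = 0.16 at R2 = 29.8% implies a parent mean inside the printed
  # seasonal range of the recurrent parent (44.1-67.7%)
  implied <- 0.16 / 0.298
  expect_gt(implied, 0.441)
  expect_lt(implied, 0.677)
})

test_that("line QTL detection applies the two-season rule", {
  set.seed(42)
  parent <- season_reps(c(0.68, 0.57, 0.55, 0.44))
  # null: line drawn from the parent's distribution
  null_line <- season_reps(c(0.68, 0.57, 0.55, 0.44))
  r0 <- detect_line_qtl(null_line, parent, line_id = "null")
  expect_false(r0$detected)
  expect_length(r0$detected_seasons, 0)

  # +0.30 shift, within-season SD 0.03, 5 replicates, 4 seasons
  shifted <- season_reps(c(0.68, 0.57, 0.55, 0.44) + 0.30)
  r1 <- detect_line_qtl(shifted, parent, line_id = "shift")
  expect_true(r1$detected)
  expect_gte(length(r1$detected_seasons), 2)
  expect_equal(r1$effect_sign, 1)
  expect_true(r1$sign_consistent)

  # oracle: per-season p must equal the directly computed pooled t test
  for (i in seq_len(nrow(r1$seasons))) {
    s <- r1$seasons$season[i]
    x <- arcsine_transform(shifted[[s]]); y <- arcsine_transform(parent[[s]])
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_hand <- 2 * pt(-abs(tt), n1 + n2 - 2)
    expect_equal(r1$seasons$p[i], p_hand, tolerance = 1e-12)
  }

  # a shift in exactly one season never triggers a call
  one <- season_reps(c(0.68 + 0.3, 0.57, 0.55, 0.44))
  r2 <- detect_line_qtl(one, parent, line_id = "one")
  expect_false(r2$detected)
  expect_lte(length(r2$detected_seasons), 1)
})

test_that("alpha extremes flag every line or none", {
  set.seed(7)
  parent <- season_reps(c(0.6, 0.5))
  line <- season_reps(c(0.7, 0.6))
  expect_true(detect_line_qtl(line, parent, alpha = 1, line_id = "x")$detected)
  expect_false(detect_line_qtl(line, parent, alpha = 0, line_id = "x")$detected)
})

test_that("detection input errors and season skipping behave as specified", {
  parent <- list(s1 = c(0.5, 0.52, 0.49), s2 = c(0.4, 0.42, 0.44))
  expect_error(detect_line_qtl(list(z9 = c(0.5, 0.6)), parent, line_id = "x"),
               "no seasons")
  short <- list(s1 = 0.9, s2 = c(0.9, 0.92, 0.91, 0.93))
  expect_warning(r <- detect_line_qtl(short, parent, alpha = 0.05,
                                      line_id = "x"),
                 "fewer than 2 replicates")
  expect_false("s1" %in% r$seasons$season)
})

test_that("heritability hits its limits and stays in [0, 1]", {
  # all variance between lines
  d1 <- data.frame(line_id = rep(c("a", "b", "c"), each = 3),
                   season = "s1",
                   prop = rep(c(0.2, 0.5, 0.8), each = 3))
  # perfect-fit ANOVA warning is expected in this degenerate limit
  expect_equal(suppressWarnings(estimate_H2(d1))$per_season[["s1"]], 1)
  # identical line means, all variance within
  d2 <- data.frame(line_id = rep(c("a", "b"), each = 2), season = "s1",
                   prop = rep(c(0.4, 0.6), 2))
  expect_equal(estimate_H2(d2)$per_season[["s1"]], 0)
  expect_error(estimate_H2(d1[d1$line_id == "a", ]), ">= 2 lines")

  set.seed(11)
  for (i in 1:20) {
    d <- data.frame(line_id = rep(paste0("l", 1:8), each = 3),
                    season = rep(c("s1", "s2"), 12),
                    prop = runif(24))
    h <- estimate_H2(d)
    expect_true(all(h$per_season >= 0 & h$per_season <= 1, na.rm = TRUE))
    expect_gte(h$combined, 0); expect_lte(h$combined, 1)
  }
})

test_that("heritability recovers a planted variance ratio (Monte Carlo)", {
  # sigma2_G = sigma2_e  =>  H2 = 0.5; 200 lines x 10 replicates
  set.seed(101)
  h2 <- replicate(100, {
    g <- rnorm(200, 0, 0.05)
    d <- data.frame(line_id = rep(sprintf("l%03d", 1:200), each = 10),
                    season = "s1",
                    prop = 0.5 + rep(g, each = 10) + rnorm(2000, 0, 0.05))
    estimate_H2(d)$per_season[["s1"]]
  })
  expect_equal(mean(h2), 0.5, tolerance = 0.05)
})

test_that("block ANOVA matches hand computation and the t-test identity", {
  expect_equal(anova_blocks(list(c(1, 2, 3), c(1, 2, 3)),
                            transform = FALSE)$F, 0)
  r <- anova_blocks(list(c(1, 2, 3), c(4, 5, 6)), transform = FALSE)
  expect_equal(r$F, 13.5)
  expect_equal(r$df, c(1, 4))
  set.seed(3)
  b <- list(runif(6, 0.3, 0.5), runif(5, 0.4, 0.6))
  a2 <- anova_blocks(b)
  tt <- t.test(arcsine_transform(b[[1]]), arcsine_transform(b[[2]]),
               var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_blocks(list(c(0.4, 0.4), c(0.4, 0.4))), "zero total")
  expect_error(anova_blocks(list(c(0.4, 0.5))), ">= 2 blocks")
})
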