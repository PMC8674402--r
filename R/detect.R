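#' Additive effect and contribution of a substituted segment
#'
#' Under the one-QTL-per-SSSL assumption, the additive effect of a putative
#' QTL is half the phenotypic difference between the substitution line and
#' the recurrent parent, `a = (line_mean - parent_mean) / 2`, and its
#' contribution is the additive effect expressed relative to the recurrent
#' parent mean, `R2 = a / parent_mean` (sign carried).  Both are computed
#' on the raw proportion scale.
#'
#' @param line_mean,parent_mean Mean germination proportions.
#' @return List with components `a` (proportion units) and `r2` (signed
#'   fraction of the parent mean).
#' @examples
#' estimate_effect(0.86, 0.54)  # a = 0.16, r2 ~ 0.296
#' @export
estimate_effect <- function(line_mean, parent_mean) {
  if (!is.finite(parent_mean) || parent_mean <= 0) {
    stop("parent mean must be > 0: contribution undefined")
  }
  a <- (line_mean - parent_mean) / 2
  list(a = a, r2 = a / parent_mean)
}

#' Detect a putative QTL on one substitution line
#'
#' Compares a line's replicate germination proportions against the
#' recurrent parent's, season by season, with a two-sided pooled-variance
#' Student's t test on arcsine-square-root transformed values.  A putative
#' QTL is declared when p < `alpha` in at least `min_seasons` cropping
#' seasons.  Additive effects and contributions are computed from the raw
#' (untransformed) season means via [estimate_effect()] and averaged over
#' the detected seasons with their sample SD.
#'
#' @param line An [sssl_line()], or a named list season -> replicate
#'   proportions (then `line_id` must be given).
#' @param parent Named list season -> replicate germination proportions of
#'   the recurrent parent.
#' @param alpha Per-season significance level (default 0.001).
#' @param min_seasons Minimum number of significant seasons (default 2).
#' @param transform Apply [arcsine_transform()] before testing
#'   (default `TRUE`).
#' @param line_id Line identifier when `line` is a bare list.
#' @return A [detection_result()] with per-season statistics in
#'   `$seasons` (columns `season`, `n_line`, `n_parent`, `p`, `a`, `r2`;
#'   `r2` in percent).
#' @export
detect_line_qtl <- function(line, parent, alpha = 0.001, min_seasons = 2,
                            transform = TRUE, line_id = NULL) {
  if (inherits(line, "sssl_line")) {
    pheno <- line$phenotypes
    if (is.null(line_id)) line_id <- line$line_id
  } else {
    pheno <- line
    if (is.null(line_id)) stop("`line_id` required when `line` is a bare list")
  }
  shared <- intersect(names(pheno), names(parent))
  if (!length(shared)) stop("line and parent share no seasons")
  rows <- list()
  for (s in shared) {
    y1 <- pheno[[s]][!is.na(pheno[[s]])]
    y0 <- parent[[s]][!is.na(parent[[s]])]
    if (length(y1) < 2 || length(y0) < 2) {
      warning("season ", s, " skipped: fewer than 2 replicates")
      next
    }
    t1 <- if (transform) arcsine_transform(y1) else y1
    t0 <- if (transform) arcsine_transform(y0) else y0
    p <- stats::t.test(t1, t0, var.equal = TRUE)$p.value
    eff <- estimate_effect(mean(y1), mean(y0))
    rows[[s]] <- data.frame(season = s, n_line = length(y1),
                            n_parent = length(y0), p = p,
                            a = eff$a, r2 = 100 * eff$r2,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no season with >= 2 replicates in both line and parent")
  seasons <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  hit <- seasons$season[seasons$p < alpha]
  detected <- length(hit) >= min_seasons
  if (detected) {
    eh <- seasons[seasons$season %in% hit, ]
    a_mean <- mean(eh$a); a_sd <- stats::sd(eh$a)
    r2_mean <- mean(eh$r2); r2_sd <- stats::sd(eh$r2)
    consistent <- length(unique(sign(eh$a))) == 1
  } else {
    a_mean <- a_sd <- r2_mean <- r2_sd <- NA_real_
    consistent <- TRUE
  }
  detection_result(line_id, a_mean, a_sd, r2_mean, r2_sd,
                   detected_seasons = hit, detected = detected,
                   seasons = seasons, sign_consistent = consistent)
}

#' Broad-sense heritability from line replicates
#'
#' Partitions phenotypic variance into a genetic (between-line) and a
#' residual component.  Per season, a one-way random-effects
#' method-of-moments fit gives `H2 = sigma2_G / (sigma2_G + sigma2_e)`;
#' negative component estimates are truncated to zero.  When several
#' seasons are supplied, the combined estimate adds season and
#' line-by-season strata (two-way method of moments) and reports
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxE + sigma2_e)`.
#'
#' @param pheno Data frame with columns `line_id`, `season`, `prop`
#'   (replicate germination proportions), or a named list
#'   line -> numeric replicates (treated as one season).
#' @return A `heritability_result`: list with `per_season` (named numeric),
#'   `combined`, and `components` (named numeric vector of variance
#'   components from the combined fit).
#' @export
estimate_H2 <- function(pheno) {
  if (is.list(pheno) && !is.data.frame(pheno)) {
    pheno <- data.frame(
      line_id = rep(names(pheno), lengths(pheno)),
      season = "s1",
      prop = unlist(pheno, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("line_id", "season", "prop") %in% names(pheno)))
  pheno <- pheno[!is.na(pheno$prop), ]
  if (length(unique(pheno$line_id)) < 2) stop("need >= 2 lines")

  one_way <- function(d) {
    d <- d[stats::ave(d$prop, d$line_id, FUN = length) >= 2, ]
    if (length(unique(d$line_id)) < 2) return(NA_real_)
    ft <- stats::anova(stats::lm(prop ~ factor(line_id), data = d))
    msb <- ft$`Mean Sq`[1]; msw <- ft$`Mean Sq`[2]
    n_i <- table(d$line_id); N <- sum(n_i); k <- length(n_i)
    n0 <- (N - sum(n_i^2) / N) / (k - 1)
    sg <- max(0, (msb - msw) / n0)
    if (sg + msw == 0) return(0)
    sg / (sg + msw)
  }
  seasons <- sort(unique(pheno$season))
  per_season <- vapply(seasons, function(s) one_way(pheno[pheno$season == s, ]),
                       numeric(1))

  if (length(seasons) == 1) {
    combined <- per_season[[1]]
    components <- c(sigma2_G = NA_real_, sigma2_GxE = NA_real_,
                    sigma2_e = NA_real_)
  } else {
    d <- pheno
    d$line_id <- factor(d$line_id); d$season <- factor(d$season)
    cell_n <- table(d$line_id, d$season)
    r <- mean(cell_n[cell_n > 0])
    s <- length(seasons)
    ft <- stats::anova(stats::lm(prop ~ line_id + season + line_id:season,
                                 data = d))
    ms <- stats::setNames(ft$`Mean Sq`, rownames(ft))
    if ("Residuals" %in% names(ms) && ft["Residuals", "Df"] > 0) {
      se <- ms[["Residuals"]]
      sgxe <- max(0, (ms[["line_id:season"]] - se) / r)
      sg <- max(0, (ms[["line_id"]] - ms[["line_id:season"]]) / (s * r))
    } else {
      # one replicate per cell: interaction MS is the error stratum
      se <- ms[["line_id:season"]]
      sgxe <- 0
      sg <- max(0, (ms[["line_id"]] - se) / s)
    }
    tot <- sg + sgxe + se
    combined <- if (tot == 0) 0 else sg / tot
    components <- c(sigma2_G = sg, sigma2_GxE = sgxe, sigma2_e = se)
  }
  structure(list(per_season = per_season, combined = combined,
                 components = components),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("<heritability_result>\n  per season:",
      paste(sprintf("%s=%.2f", names(x$per_season), x$per_season),
            collapse = ", "),
      sprintf("\n  combined H2 = %.2f\n", x$combined))
  invisible(x)
}

#' One-way ANOVA across field blocks
#'
#' Tests whether germination differs among field blocks of the recurrent
#' parent (environment-consistency check).  Values are arcsine-square-root
#' transformed by default; pass `transform = FALSE` for pre-transformed or
#' non-proportion data.
#'
#' @param blocks List of numeric vectors, one per block (>= 2 blocks of
#'   >= 2 values each).
#' @param transform Apply [arcsine_transform()] first (default `TRUE`).
#' @return List with `F`, `df` (length-2), and `p`.
#' @export
anova_blocks <- function(blocks, transform = TRUE) {
  if (!is.list(blocks) || length(blocks) < 2) stop("need >= 2 blocks")
  if (any(lengths(blocks) < 2)) stop("each block needs >= 2 values")
  y <- unlist(blocks, use.names = FALSE)
  if (transform) y <- arcsine_transform(y)
  if (stats::var(y) == 0) stop("zero total variance: ANOVA degenerate")
  g <- factor(rep(seq_along(blocks), lengths(blocks)))
  ft <- stats::anova(stats::lm(y ~ g))
  list(F = ft$`F value`[1], df = ft$Df, p = ft$`Pr(>F)`[1])
}
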