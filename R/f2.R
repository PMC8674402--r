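# F2 genetics: segregation testing, additive/dominance estimation via the
# coded single-marker regression, marker-trait association, and
# recombinant-progeny fine mapping.

#' Chi-square test of a segregation ratio
#'
#' Pearson chi-square of observed genotype-class counts against an
#' expected Mendelian ratio (no continuity correction).
#'
#' @param counts Non-negative integer vector of class counts.
#' @param ratio Expected proportions (normalised to sum to 1); default the
#'   F2 codominant 1:2:1.
#' @return List with `chi2`, `df` (`length(counts) - 1`) and `p`.
#' @examples
#' segregation_chi2(c(85, 173, 98))  # chi2 = 1.23
#' @export
segregation_chi2 <- function(counts, ratio = c(1, 2, 1)) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with a positive total")
  }
  if (length(ratio) != length(counts)) stop("counts and ratio lengths differ")
  ratio <- ratio / sum(ratio)
  expected <- sum(counts) * ratio
  if (any(expected == 0)) stop("expected count of zero in some class")
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Additive/dominance model fit at one marker
#'
#' Ordinary least squares of phenotype on the additive dummy
#' `x in {-1, 0, +1}` and the dominance dummy `z in {0, 1, 0}` derived
#' from genotype codes 1 (recipient homozygote), 2 (heterozygote), 3
#' (donor homozygote): `y = mu + a x + d z + e`.  With balanced classes
#' the coefficients equal the group-mean contrasts
#' `a = (mean3 - mean1) / 2` and `d = mean2 - (mean1 + mean3) / 2`.
#'
#' @param genotype Integer codes in \{1, 2, 3\} (`NA` dropped listwise).
#' @param phenotype Numeric phenotypes (germination proportions).
#' @return A `model1_fit`: list with `mu`, `a`, `d`, `se` (named), `p`
#'   (named, two-sided coefficient t tests), `r2` (model R-squared),
#'   `sigma2` (residual variance), `n`, and `estimable` flags.
#' @export
fit_model1 <- function(genotype, phenotype) {
  keep <- !is.na(genotype) & !is.na(phenotype)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " individual(s) dropped (missing data)")
  g <- genotype[keep]; y <- phenotype[keep]
  if (!all(g %in% 1:3)) stop("genotype codes must be 1, 2 or 3")
  classes <- sort(unique(g))
  if (length(classes) < 2) stop("singular design: only one genotype class")
  x <- g - 2
  z <- as.numeric(g == 2)
  estimable <- c(a = length(setdiff(classes, 2)) == 2,
                 d = (2 %in% classes) && length(classes) == 3)
  fml <- if (estimable[["d"]]) y ~ x + z
         else if (2 %in% classes) y ~ z   # hom class + het only
         else y ~ x
  fit <- stats::lm(fml)
  cf <- summary(fit)$coefficients
  pick <- function(term) {
    if (term %in% rownames(cf)) {
      c(est = cf[term, 1], se = cf[term, 2], p = cf[term, 4])
    } else c(est = NA_real_, se = NA_real_, p = NA_real_)
  }
  ax <- pick("x"); dz <- pick("z")
  if (!all(estimable)) {
    warning("only two genotype classes: ",
            paste(names(estimable)[!estimable], collapse = " and "),
            " not estimable")
  }
  r2 <- if (stats::var(y) == 0) 0 else summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  structure(list(mu = unname(cf["(Intercept)", 1]),
                 a = unname(ax["est"]), d = unname(dz["est"]),
                 se = c(a = unname(ax["se"]), d = unname(dz["se"])),
                 p = c(a = unname(ax["p"]), d = unname(dz["p"])),
                 r2 = r2,
                 sigma2 = summary(fit)$sigma^2,
                 n = length(y), estimable = estimable),
            class = "model1_fit")
}

#' @export
print.model1_fit <- function(x, ...) {
  cat(sprintf("<model1_fit> n = %d: mu = %.3f, a = %.3f (p = %.3g), d = %.3f (p = %.3g), R2 = %.3f\n",
              x$n, x$mu, x$a, x$p[["a"]], x$d, x$p[["d"]], x$r2))
  invisible(x)
}

#' Marker-trait association by linear correlation
#'
#' Pearson correlation between the genotype code (1/2/3) and the
#' phenotype, with the two-sided test p-value.
#'
#' @inheritParams fit_model1
#' @return List with `r`, `p` and `n`.
#' @export
marker_trait_association <- function(genotype, phenotype) {
  keep <- !is.na(genotype) & !is.na(phenotype)
  g <- genotype[keep]; y <- phenotype[keep]
  if (length(g) < 3) stop("need >= 3 individuals with complete data")
  if (stats::var(g) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(g, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(g))
}

#' Fine-map a locus from recombinant progeny tests
#'
#' Applies the substitution-mapping interval engine in physical
#' coordinates: the locus lies in the intersection of the heterozygous
#' intervals of recombinants whose progeny show a significant marker-trait
#' association, minus the heterozygous intervals of recombinants whose
#' progeny do not.  Intervals are 1-based closed bp spans; subtraction
#' removes interiors, keeping shared boundary coordinates.
#'
#' @param populations Data frame with one row per recombinant-derived
#'   progeny population: columns `recomb_id`, `chrom`, `het_start_bp`,
#'   `het_end_bp` and `p` (marker-trait association p-value, e.g. from
#'   [marker_trait_association()]).
#' @param alpha Classification threshold (default 0.01).
#' @return Data frame with columns `chrom`, `start`, `end` (bp).
#' @export
fine_map <- function(populations, alpha = 0.01) {
  need <- c("recomb_id", "chrom", "het_start_bp", "het_end_bp", "p")
  stopifnot(is.data.frame(populations), all(need %in% names(populations)))
  if (!nrow(populations)) stop("no populations supplied")
  sig <- populations[populations$p < alpha, , drop = FALSE]
  if (!nrow(sig)) stop("no significant population: locus placement impossible")
  chrom <- unique(sig$chrom)
  if (length(chrom) > 1) {
    stop("significant populations span several chromosomes: ",
         paste(chrom, collapse = ", "))
  }
  region <- iv(sig$het_start_bp[1], sig$het_end_bp[1])
  if (nrow(sig) > 1) for (i in 2:nrow(sig)) {
    region <- iv_intersect(region, iv(sig$het_start_bp[i], sig$het_end_bp[i]))
    if (!nrow(region)) {
      stop("conflict: no common heterozygous interval among ",
           paste(sig$recomb_id, collapse = ", "))
    }
  }
  neg <- populations[populations$p >= alpha & populations$chrom == chrom, ,
                     drop = FALSE]
  if (nrow(neg)) {
    region <- iv_subtract(region, iv(neg$het_start_bp, neg$het_end_bp))
  }
  if (!nrow(region)) {
    stop("conflict: negative populations exclude the whole intersection")
  }
  cbind(data.frame(chrom = chrom), region)
}
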