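# Bulked-segregant delta SNP-index analysis: per-site indices, sliding
# window smoothing, simulated null confidence bands, candidate-interval
# calling.

#' SNP-index of one bulk at one site
#'
#' Fraction of reads carrying the donor allele:
#' `alt_depth / (ref_depth + alt_depth)`, with "alt" oriented to the donor
#' parent's allele.  Sites with zero total depth yield `NA` and are
#' excluded downstream.
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorised).
#' @return Numeric vector in \[0, 1\] (or `NA` where depth is zero).
#' @export
snp_index <- function(ref_depth, alt_depth) {
  if (any(c(ref_depth, alt_depth) < 0, na.rm = TRUE)) {
    stop("read depths must be >= 0")
  }
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

#' Delta SNP-index between the two bulks
#'
#' Tolerant-pool index minus sensitive-pool index; lies in \[-1, 1\].
#'
#' @param index_tolerant,index_sensitive SNP-indices in \[0, 1\]
#'   (vectorised; `NA` propagates).
#' @return Numeric vector in \[-1, 1\].
#' @export
delta_index <- function(index_tolerant, index_sensitive) {
  chk <- c(index_tolerant, index_sensitive)
  if (any(!is.na(chk) & (chk < 0 | chk > 1))) {
    stop("SNP-indices must lie in [0, 1]")
  }
  index_tolerant - index_sensitive
}

#' Per-site index table with standard site filters
#'
#' Computes both pools' SNP-indices and the delta index from allele
#' depths, then applies the usual QTL-seq site filters: minimum total
#' depth in each pool, and removal of sites whose index is below
#' `min_index` in *both* pools (likely alignment artefacts).
#'
#' @param sites Data frame with columns `chrom`, `pos` and the per-pool
#'   depths `ref_hi`, `alt_hi` (tolerant bulk), `ref_lo`, `alt_lo`
#'   (sensitive bulk); optional `class` (`"SNP"`/`"InDel"`).
#' @param min_depth Minimum total depth per pool (default 10).
#' @param min_index Both-pool lower index bound (default 0.3); set to 0
#'   to disable.
#' @return The filtered data frame with added columns `index_hi`,
#'   `index_lo`, `delta`, sorted by `chrom`, `pos`.
#' @export
index_sites <- function(sites, min_depth = 10, min_index = 0.3) {
  need <- c("chrom", "pos", "ref_hi", "alt_hi", "ref_lo", "alt_lo")
  stopifnot(is.data.frame(sites), all(need %in% names(sites)))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites$index_hi <- snp_index(sites$ref_hi, sites$alt_hi)
  sites$index_lo <- snp_index(sites$ref_lo, sites$alt_lo)
  keep <- !is.na(sites$index_hi) & !is.na(sites$index_lo) &
    (sites$ref_hi + sites$alt_hi >= min_depth) &
    (sites$ref_lo + sites$alt_lo >= min_depth) &
    !(sites$index_hi < min_index & sites$index_lo < min_index)
  sites <- sites[keep, , drop = FALSE]
  sites$delta <- delta_index(sites$index_hi, sites$index_lo)
  rownames(sites) <- NULL
  sites
}

# window centers shared by smooth_track() and null_band()
.window_centers <- function(pos, window, step) {
  lo <- min(pos); hi <- max(pos)
  if (hi - lo <= window) return(mean(c(lo, hi)))
  seq(lo + window / 2, hi - window / 2 + step, by = step)
}

# window-average an arbitrary per-site statistic matrix (cols = stats)
.window_average <- function(sites, values, window, step) {
  values <- as.matrix(values)
  out <- list()
  for (cc in unique(sites$chrom)) {
    at <- sites$chrom == cc
    pos <- sites$pos[at]
    v <- values[at, , drop = FALSE]
    centers <- .window_centers(pos, window, step)
    m <- matrix(NA_real_, length(centers), ncol(values))
    n <- integer(length(centers))
    for (i in seq_along(centers)) {
      inw <- pos >= centers[i] - window / 2 & pos <= centers[i] + window / 2
      n[i] <- sum(inw)
      if (n[i]) m[i, ] <- colMeans(v[inw, , drop = FALSE])
    }
    colnames(m) <- colnames(values)
    out[[cc]] <- data.frame(chrom = cc, center = centers,
                            start = centers - window / 2,
                            end = centers + window / 2,
                            n_sites = n, m, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "window") <- window
  attr(res, "step") <- step
  res
}

#' Sliding-window smoothing of the delta index
#'
#' Arithmetic mean of the per-site delta index over sliding windows along
#' each chromosome.  Windows with no sites yield `NA`.
#'
#' @param sites Per-site table from [index_sites()] (columns `chrom`,
#'   `pos`, `delta`), sorted by position within chromosome.
#' @param window Window width in bp (default 1 Mb).
#' @param step Step between window centers in bp (default 100 kb);
#'   must satisfy `window >= step > 0`.
#' @return A `delta_track` data frame: `chrom`, `center`, `start`, `end`,
#'   `n_sites`, `delta`.
#' @export
smooth_track <- function(sites, window = 1e6, step = 1e5) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "delta") %in% names(sites)))
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  srt <- unlist(tapply(sites$pos, sites$chrom, is.unsorted, simplify = FALSE))
  if (any(srt)) stop("sites must be sorted by position within chromosome")
  res <- .window_average(sites, cbind(delta = sites$delta), window, step)
  class(res) <- c("delta_track", "data.frame")
  res
}

# simulate null delta quantiles for one (depth_hi, depth_lo) pair
.null_quantiles <- function(depth_hi, depth_lo, pool_size, n_sim, probs) {
  p_hi <- stats::rbinom(n_sim, 2 * pool_size, 0.5) / (2 * pool_size)
  p_lo <- stats::rbinom(n_sim, 2 * pool_size, 0.5) / (2 * pool_size)
  d <- stats::rbinom(n_sim, depth_hi, p_hi) / depth_hi -
       stats::rbinom(n_sim, depth_lo, p_lo) / depth_lo
  stats::quantile(d, probs, names = FALSE)
}

#' Simulated null confidence band for the delta index
#'
#' Monte-Carlo band under no linkage: each bulk's allele frequency is
#' drawn as `Binomial(2 * pool_size, 0.5) / (2 * pool_size)` (random
#' sampling of F2 plants into the bulk), read counts as
#' `Binomial(depth, frequency)`, and the delta index is recorded.
#' Per-site two-sided empirical quantiles at each level are then
#' window-averaged exactly like the delta index itself in
#' [smooth_track()].  Identical seeds give identical bands.
#'
#' @inheritParams smooth_track
#' @param sites Per-site table from [index_sites()] (depth columns
#'   required).
#' @param pool_size Plants per bulk (default 30).
#' @param n_sim Simulations per site (>= 1000; default 10000).
#' @param levels Confidence levels (default `c(0.95, 0.99)`).
#' @param seed Optional integer seed governing all draws.
#' @return Data frame of window band bounds: `chrom`, `center`, `start`,
#'   `end`, `n_sites`, and `lo_<level>`, `hi_<level>` per level.
#' @export
null_band <- function(sites, pool_size = 30, n_sim = 10000,
                      levels = c(0.95, 0.99), seed = NULL,
                      window = 1e6, step = 1e5) {
  need <- c("chrom", "pos", "ref_hi", "alt_hi", "ref_lo", "alt_lo")
  stopifnot(is.data.frame(sites), all(need %in% names(sites)))
  if (pool_size <= 0) stop("pool_size must be > 0")
  if (n_sim < 1000) stop("n_sim must be >= 1000")
  if (n_sim * (1 - max(levels)) / 2 < 5) {
    stop("n_sim too small to resolve level ", max(levels))
  }
  if (!is.null(seed)) set.seed(seed)
  probs <- as.vector(rbind((1 - levels) / 2, 1 - (1 - levels) / 2))
  dh <- sites$ref_hi + sites$alt_hi
  dl <- sites$ref_lo + sites$alt_lo
  if (any(dh <= 0 | dl <= 0)) stop("sites with zero depth: filter first")
  key <- paste(dh, dl)
  uk <- unique(key)
  qs <- matrix(NA_real_, length(uk), length(probs))
  for (i in seq_along(uk)) {
    pair <- as.numeric(strsplit(uk[i], " ", fixed = TRUE)[[1]])
    qs[i, ] <- .null_quantiles(pair[1], pair[2], pool_size, n_sim, probs)
  }
  per_site <- qs[match(key, uk), , drop = FALSE]
  colnames(per_site) <- as.vector(rbind(paste0("lo_", 100 * levels),
                                        paste0("hi_", 100 * levels)))
  .window_average(sites, per_site, window, step)
}

#' Attach null bands to a smoothed track
#'
#' @param track A `delta_track` from [smooth_track()].
#' @param bands Band table from [null_band()] run on the same sites with
#'   the same `window`/`step`.
#' @return The track with the band columns merged in.
#' @export
band_track <- function(track, bands) {
  stopifnot(nrow(track) == nrow(bands),
            all(track$chrom == bands$chrom),
            all(track$center == bands$center))
  res <- cbind(as.data.frame(track),
               bands[, grep("^(lo|hi)_", names(bands)), drop = FALSE])
  attr(res, "window") <- attr(track, "window")
  attr(res, "step") <- attr(track, "step")
  class(res) <- c("delta_track", "data.frame")
  res
}

#' Call candidate intervals from a banded track
#'
#' Maximal runs of consecutive windows whose smoothed delta index exceeds
#' the simulated band (on either side; runs of opposite sign are never
#' merged).  Runs separated by less than one step (i.e. overlapping or
#' adjacent windows) are merged; windows with no sites break a run.
#'
#' @param track A banded `delta_track` (see [band_track()]).
#' @param level Confidence level whose band to use (default 0.95).
#' @return Data frame: `chrom`, `start`, `end`, `peak_delta`,
#'   `n_windows`, `level`; zero rows when nothing exceeds the band.
#' @export
call_intervals <- function(track, level = 0.95) {
  lo <- paste0("lo_", 100 * level); hi <- paste0("hi_", 100 * level)
  if (!all(c(lo, hi) %in% names(track))) {
    stop("track carries no band at level ", level)
  }
  step <- attr(track, "step")
  if (is.null(step)) step <- stats::median(diff(track$center))
  out <- list()
  for (cc in unique(track$chrom)) {
    tr <- track[track$chrom == cc, , drop = FALSE]
    state <- ifelse(is.na(tr$delta), 0L,
                    ifelse(tr$delta > tr[[hi]], 1L,
                           ifelse(tr$delta < tr[[lo]], -1L, 0L)))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0L)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc,
        start = min(tr$start[idx]), end = max(tr$end[idx]),
        peak_delta = tr$delta[idx][which.max(abs(tr$delta[idx]))],
        n_windows = length(idx), level = level,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_delta = numeric(),
                      n_windows = integer(), level = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
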