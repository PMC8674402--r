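# Forward simulation of the experimental designs: SSSL libraries with
# marker-defined donor segments and season-structured phenotypes, F2
# populations from a heterozygous cross, and two-bulk pooled sequencing
# depths.  All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Defaults mirror the experimental design the package targets: four
#' cropping seasons with recurrent-parent germination means 67.7, 57.4,
#' 55.3 and 44.1%; 4 plants per line and season, 150 seeds per plant;
#' binomial seed-count sampling on top of a small plant-level residual
#' (SD 0.03) and line-by-season shifts (SD 0.02); 12 chromosomes of
#' 120 cM / 30 Mb with markers every 5 cM; donor segments of 5-40 cM;
#' F2 populations of 356 plants with additive effect 0.13 (the genotype
#' means 52/65/78%) and residual SD 0.10; 30-plant bulks sequenced at
#' mean depth 30.
#'
#' @param seasons Season labels.
#' @param baseline Per-season recurrent-parent mean germination
#'   proportions (recycled to `length(seasons)`).
#' @param season_shift_sd SD of line-by-season shifts (proportion).
#' @param residual_sd Plant-level residual SD (proportion).
#' @param seeds_sown Seeds per replicate plant.
#' @param replicates Replicate plants per line and season.
#' @param n_chrom,chr_cm,chr_bp,marker_spacing_cm Genome layout.
#' @param segment_cm Range (min, max) of donor segment lengths in cM.
#' @param qtls Data frame of planted QTLs: `chr`, `cm`, `a`, `d`.
#' @param f2_n,f2_mu,f2_a,f2_d,f2_sd F2 design: population size, mid-parent
#'   mean, additive and dominance effects, residual SD.
#' @param pool_size,depth Plants per bulk and mean read depth.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seasons = c("2015E", "2015L", "2016E", "2016L"),
                       baseline = c(0.677, 0.574, 0.553, 0.441),
                       season_shift_sd = 0.02, residual_sd = 0.03,
                       seeds_sown = 150, replicates = 4,
                       n_chrom = 12, chr_cm = 120, chr_bp = 30e6,
                       marker_spacing_cm = 5, segment_cm = c(5, 40),
                       qtls = data.frame(chr = "3", cm = 26.8,
                                         a = 0.15, d = 0),
                       f2_n = 356, f2_mu = 0.65, f2_a = 0.13, f2_d = 0,
                       f2_sd = 0.10, pool_size = 30, depth = 30) {
  baseline <- rep_len(baseline, length(seasons))
  cfg <- list(seasons = seasons, baseline = baseline,
              season_shift_sd = season_shift_sd, residual_sd = residual_sd,
              seeds_sown = seeds_sown, replicates = replicates,
              n_chrom = n_chrom, chr_cm = chr_cm, chr_bp = chr_bp,
              marker_spacing_cm = marker_spacing_cm, segment_cm = segment_cm,
              qtls = qtls, f2_n = f2_n, f2_mu = f2_mu, f2_a = f2_a,
              f2_d = f2_d, f2_sd = f2_sd, pool_size = pool_size,
              depth = depth)
  if (season_shift_sd < 0 || residual_sd < 0 || f2_sd < 0) {
    stop("variance parameters must be >= 0")
  }
  if (any(baseline < 0 | baseline > 1)) stop("baselines must be in [0, 1]")
  if (seeds_sown < 1 || replicates < 1 || pool_size < 1) {
    stop("counts must be >= 1")
  }
  if (!is.data.frame(qtls) || !all(c("chr", "cm", "a") %in% names(qtls))) {
    stop("`qtls` needs columns chr, cm, a")
  }
  class(cfg) <- "sim_config"
  cfg
}

.clip01 <- function(p) pmin(0.99, pmax(0.01, p))

# one set of binomially sampled replicate proportions around mean `m`
.replicates <- function(cfg, m) {
  p <- .clip01(m + stats::rnorm(cfg$replicates, 0, cfg$residual_sd))
  stats::rbinom(cfg$replicates, cfg$seeds_sown, p) / cfg$seeds_sown
}

#' Simulate an SSSL library with season-structured phenotypes
#'
#' Each line receives one uniform-random marker-delimited donor segment;
#' its season mean is the parent baseline plus a line-by-season shift plus
#' `2a` for every planted QTL whose position falls inside the core
#' segment (homozygous substitution).  Replicate values are binomial
#' seed counts around plant-level means.
#'
#' @param config A [sim_config()].
#' @param n_lines Number of lines to simulate.
#' @param seed Integer seed (all randomness derives from it).
#' @return List with `map` (a [genetic_map()]), `lines` (list of
#'   [sssl_line()]), `parent` (named list season -> replicate
#'   proportions), and `truth` (data frame: `line_id`, `chr`, carried
#'   QTL position/effect or `NA` for empty lines).
#' @export
simulate_sssl_library <- function(config, n_lines, seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_lines >= 1)
  set.seed(seed)
  cfg <- config
  marks <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(cc) {
    cm <- seq(0, cfg$chr_cm, by = cfg$marker_spacing_cm)
    data.frame(marker = sprintf("M%02d_%03d", cc, seq_along(cm)),
               chr = as.character(cc), cm = cm, stringsAsFactors = FALSE)
  }))
  map <- genetic_map(marks$marker, marks$chr, marks$cm)
  n_mark <- length(unique(map$cm[map$chr == "1"]))

  parent <- stats::setNames(lapply(seq_along(cfg$seasons), function(k) {
    .replicates(cfg, cfg$baseline[k])
  }), cfg$seasons)

  lines <- vector("list", n_lines)
  truth <- vector("list", n_lines)
  spacing <- cfg$marker_spacing_cm
  for (i in seq_len(n_lines)) {
    id <- sprintf("L%04d", i)
    cc <- as.character(sample.int(cfg$n_chrom, 1))
    len <- stats::runif(1, cfg$segment_cm[1], cfg$segment_cm[2])
    span <- round(len / spacing)
    i0 <- sample.int(n_mark - span, 1)
    core <- c((i0 - 1) * spacing, (i0 - 1 + span) * spacing)
    maximal <- c(max(0, core[1] - spacing),
                 min(cfg$chr_cm, core[2] + spacing))
    seg <- substituted_segment(cc, core, maximal)
    carried <- cfg$qtls[cfg$qtls$chr == cc &
                        cfg$qtls$cm >= core[1] & cfg$qtls$cm <= core[2], ,
                        drop = FALSE]
    bump <- if (nrow(carried)) sum(2 * carried$a) else 0
    shifts <- stats::rnorm(length(cfg$seasons), 0, cfg$season_shift_sd)
    pheno <- stats::setNames(lapply(seq_along(cfg$seasons), function(k) {
      .replicates(cfg, cfg$baseline[k] + shifts[k] + bump)
    }), cfg$seasons)
    lines[[i]] <- sssl_line(id, "SIMDONOR", seg, pheno)
    truth[[i]] <- data.frame(
      line_id = id, chr = cc, core_start = core[1], core_end = core[2],
      qtl_cm = if (nrow(carried)) carried$cm[1] else NA_real_,
      qtl_a = if (nrow(carried)) carried$a[1] else NA_real_,
      carrier = nrow(carried) > 0, stringsAsFactors = FALSE)
  }
  list(map = map, lines = lines, parent = parent,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

# Haldane map function: recombination fraction for a distance in cM
haldane <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Simulate an F2 population segregating for one segment
#'
#' Gametes are formed from a heterozygous parent by a Markov walk along
#' the marker positions with Haldane recombination fractions (no
#' interference).  Genotypes are coded 1/2/3 (recipient homozygote /
#' heterozygote / donor homozygote).  The phenotype is
#' `mu + a x + d z + N(0, sd)` with the usual coding
#' (`x in {-1,0,1}`, `z in {0,1,0}`) at the causal position, then
#' binomially sampled as a germinated-seed proportion.
#'
#' @param config A [sim_config()] (`f2_*` fields are used).
#' @param n Number of F2 individuals (default `config$f2_n`).
#' @param marker_cm Marker positions in cM along the segment; must cover
#'   `qtl_cm`.
#' @param qtl_cm Causal position in cM (default the segment midpoint).
#' @param seed Integer seed.
#' @return Data frame: `id`, `phenotype`, one genotype column per marker
#'   (named `M@<cm>`), and `qtl` (the causal genotype code).  Marker
#'   positions are kept in `attr(, "marker_cm")`.
#' @export
simulate_f2 <- function(config, n = config$f2_n,
                        marker_cm = seq(0, 30, by = 2), qtl_cm = NULL,
                        seed = 1) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (is.null(qtl_cm)) qtl_cm <- stats::median(marker_cm)
  if (qtl_cm < min(marker_cm) || qtl_cm > max(marker_cm)) {
    stop("causal position lies outside the marker span")
  }
  set.seed(seed)
  pos <- sort(c(marker_cm, if (!qtl_cm %in% marker_cm) qtl_cm))
  m <- length(pos)
  r <- haldane(diff(pos))
  gamete <- function() {
    g <- matrix(0L, n, m)
    g[, 1] <- stats::rbinom(n, 1, 0.5)
    for (j in seq_len(m - 1)) {
      swap <- stats::rbinom(n, 1, r[j]) == 1
      g[, j + 1] <- ifelse(swap, 1L - g[, j], g[, j])
    }
    g
  }
  geno <- gamete() + gamete() + 1L   # codes 1/2/3
  qcol <- match(qtl_cm, pos)
  x <- geno[, qcol] - 2L
  z <- as.numeric(geno[, qcol] == 2L)
  mean_p <- .clip01(config$f2_mu + config$f2_a * x + config$f2_d * z +
                    stats::rnorm(n, 0, config$f2_sd))
  phen <- stats::rbinom(n, config$seeds_sown, mean_p) / config$seeds_sown
  out <- data.frame(id = sprintf("F2_%04d", seq_len(n)), phenotype = phen)
  gm <- as.data.frame(geno)
  names(gm) <- sprintf("M@%g", pos)
  out <- cbind(out, gm)
  out$qtl <- geno[, qcol]
  attr(out, "marker_cm") <- pos
  attr(out, "qtl_cm") <- qtl_cm
  out
}

#' Simulate pooled sequencing of the two phenotypic-extreme bulks
#'
#' Bulks are the `pool_size` highest- and lowest-phenotype F2 plants
#' (ties broken by individual id).  At every marker the pool allele
#' frequency is the mean donor-allele dosage over bulk members; read
#' depth is Poisson(`depth`) per pool and donor-allele ("alt") reads are
#' binomial in that frequency.
#'
#' @param f2 An F2 population from [simulate_f2()].
#' @param config A [sim_config()] (`pool_size`, `depth`, `chr_bp`,
#'   `chr_cm` are used).
#' @param chrom Chromosome label for the emitted sites (default `"3"`).
#' @param seed Integer seed.
#' @return Per-site data frame as consumed by [index_sites()]: `chrom`,
#'   `pos` (bp, via the config's cM-to-bp scaling), `class`, `ref_hi`,
#'   `alt_hi`, `ref_lo`, `alt_lo`.
#' @export
simulate_pools <- function(f2, config, chrom = "3", seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  pool_size <- config$pool_size
  if (nrow(f2) < 2 * pool_size) {
    stop("population smaller than twice the pool size")
  }
  set.seed(seed)
  ord <- order(-f2$phenotype, f2$id)
  hi <- f2[ord[seq_len(pool_size)], , drop = FALSE]
  lo <- f2[rev(ord)[seq_len(pool_size)], , drop = FALSE]
  pos_cm <- attr(f2, "marker_cm")
  cols <- sprintf("M@%g", pos_cm)
  freq <- function(bulk, col) mean(bulk[[col]] - 1) / 2
  n_sites <- length(cols)
  dep_hi <- stats::rpois(n_sites, config$depth)
  dep_lo <- stats::rpois(n_sites, config$depth)
  alt_hi <- alt_lo <- integer(n_sites)
  for (j in seq_len(n_sites)) {
    alt_hi[j] <- stats::rbinom(1, dep_hi[j], freq(hi, cols[j]))
    alt_lo[j] <- stats::rbinom(1, dep_lo[j], freq(lo, cols[j]))
  }
  data.frame(chrom = chrom,
             pos = round(pos_cm / config$chr_cm * config$chr_bp),
             class = "SNP",
             ref_hi = dep_hi - alt_hi, alt_hi = alt_hi,
             ref_lo = dep_lo - alt_lo, alt_lo = alt_lo,
             stringsAsFactors = FALSE)
}
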