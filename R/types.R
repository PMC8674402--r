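#' Genetic map of SSR/InDel markers
#'
#' A genetic map is a data frame with one row per marker: marker name,
#' chromosome, and position in centimorgans.  Marker names must be unique,
#' positions non-negative; rows are sorted by chromosome and position.
#'
#' @param marker Character vector of marker names.
#' @param chr Chromosome identifiers (coerced to character).
#' @param cm Numeric positions in centimorgans.
#' @return A `genetic_map` (data frame with columns `marker`, `chr`, `cm`).
#' @export
genetic_map <- function(marker, chr, cm) {
  marker <- as.character(marker)
  chr <- rep_len(as.character(chr), length(marker))
  cm <- rep_len(as.numeric(cm), length(marker))
  if (anyDuplicated(marker)) {
    stop("duplicated marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(is.na(cm)) || any(cm < 0)) stop("marker positions must be >= 0")
  ord <- order(chr, cm, marker)
  out <- data.frame(marker = marker[ord], chr = chr[ord], cm = cm[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Look up marker positions on a genetic map
#'
#' @param map A [genetic_map()].
#' @param marker Character vector of marker names.
#' @return Numeric vector of cM positions (same order as `marker`).
#' @export
marker_position <- function(map, marker) {
  i <- match(marker, map$marker)
  if (anyNA(i)) stop("markers absent from map: ",
                     paste(marker[is.na(i)], collapse = ", "))
  map$cm[i]
}

#' Substituted chromosome segment of an SSSL
#'
#' A segment is described by two nested closed cM intervals on one
#' chromosome: the `core` interval (the region certainly substituted,
#' between the inner marker pair) and the `maximal` interval (extending to
#' the outer flanking markers, inside which recombination may have placed
#' the true segment boundary).  The core must be contained in the maximal
#' interval.
#'
#' @param chr Chromosome identifier.
#' @param core Numeric length-2 vector `c(start, end)` in cM.
#' @param maximal Numeric length-2 vector `c(start, end)` in cM; defaults
#'   to `core` (no recombination uncertainty).
#' @return A `substituted_segment` object.
#' @export
substituted_segment <- function(chr, core, maximal = core) {
  core <- as.numeric(core); maximal <- as.numeric(maximal)
  stopifnot(length(core) == 2, length(maximal) == 2)
  if (core[1] > core[2] || maximal[1] > maximal[2]) {
    stop("interval start must be <= end")
  }
  if (core[1] < maximal[1] || core[2] > maximal[2]) {
    stop("core interval must be contained in the maximal interval")
  }
  structure(list(chr = as.character(chr), core = core, maximal = maximal),
            class = "substituted_segment")
}

#' Build a substituted segment from marker names
#'
#' Translates the four-marker description used in SSSL tables
#' (outer flank -- core start -- core end -- outer flank) into cM
#' intervals via a genetic map.  The token `"End"` denotes a chromosome
#' extremity: position 0 when used as the left maximal bound, the largest
#' mapped position on the chromosome when used as the right bound.
#'
#' @param map A [genetic_map()].
#' @param chr Chromosome identifier.
#' @param core_start,core_end Inner marker names.
#' @param max_start,max_end Outer marker names (default: the core markers,
#'   i.e. no uncertainty flank).
#' @return A [substituted_segment()].
#' @export
segment_from_markers <- function(map, chr, core_start, core_end,
                                 max_start = core_start, max_end = core_end) {
  chr <- as.character(chr)
  chr_cm <- map$cm[map$chr == chr]
  if (!length(chr_cm)) stop("no markers mapped on chromosome ", chr)
  pos1 <- function(m, side) {
    if (identical(m, "End")) {
      return(if (side == "left") 0 else max(chr_cm))
    }
    marker_position(map, m)
  }
  substituted_segment(
    chr,
    core = c(pos1(core_start, "left"), pos1(core_end, "right")),
    maximal = c(pos1(max_start, "left"), pos1(max_end, "right"))
  )
}

#' Single segment substitution line
#'
#' Couples a line identity, its donor, its substituted segment and its
#' season-structured germination phenotypes (replicate proportions in
#' \[0, 1\], one numeric vector per season).
#'
#' @param line_id,donor_id Character scalars.
#' @param segment A [substituted_segment()].
#' @param phenotypes Named list, season label -> numeric vector of
#'   replicate germination proportions in \[0, 1\].
#' @return An `sssl_line` object.
#' @export
sssl_line <- function(line_id, donor_id, segment, phenotypes) {
  stopifnot(inherits(segment, "substituted_segment"))
  if (!is.list(phenotypes) || is.null(names(phenotypes)) ||
      !length(phenotypes)) {
    stop("`phenotypes` must be a non-empty named list (season -> replicates)")
  }
  for (s in names(phenotypes)) {
    v <- phenotypes[[s]]
    if (!is.numeric(v) || any(!is.na(v) & (v < 0 | v > 1))) {
      stop("phenotypes for season ", s, " must be proportions in [0, 1]")
    }
  }
  structure(list(line_id = as.character(line_id),
                 donor_id = as.character(donor_id),
                 segment = segment, phenotypes = phenotypes),
            class = "sssl_line")
}

#' Per-line QTL detection result
#'
#' Usually produced by [detect_line_qtl()]; the constructor is exported so
#' that published summary tables (season-averaged effects with their sample
#' SDs) can be wrapped directly for substitution mapping.
#'
#' @param line_id Line identifier.
#' @param a_mean,a_sd Season-averaged additive effect (proportion units)
#'   and its sample SD over detected seasons.
#' @param r2_mean,r2_sd Season-averaged additive-effect contribution, as a
#'   percentage, and its sample SD.
#' @param detected_seasons Character vector of seasons where p < alpha.
#' @param detected Logical: does the line carry a putative QTL?
#' @param seasons Optional data frame of per-season statistics
#'   (columns `season`, `p`, `a`, `r2`).
#' @param sign_consistent Logical: was the effect sign uniform across
#'   detected seasons?
#' @param donor_id Optional donor identifier (carried into summaries).
#' @return A `detection_result` object; `effect_sign` is `sign(a_mean)`.
#' @export
detection_result <- function(line_id, a_mean, a_sd, r2_mean, r2_sd,
                             detected_seasons = character(),
                             detected = length(detected_seasons) > 0,
                             seasons = NULL, sign_consistent = TRUE,
                             donor_id = NA_character_) {
  structure(list(line_id = as.character(line_id),
                 donor_id = as.character(donor_id),
                 seasons = seasons,
                 detected = isTRUE(detected),
                 detected_seasons = as.character(detected_seasons),
                 a_mean = as.numeric(a_mean), a_sd = as.numeric(a_sd),
                 r2_mean = as.numeric(r2_mean), r2_sd = as.numeric(r2_sd),
                 effect_sign = sign(as.numeric(a_mean)),
                 sign_consistent = isTRUE(sign_consistent)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: %s\n", x$line_id,
              if (x$detected) "QTL detected" else "no QTL"))
  if (x$detected) {
    cat(sprintf("  seasons: %s\n  a = %.3f +/- %.3f, R2 = %.1f +/- %.1f %%\n",
                paste(x$detected_seasons, collapse = ","),
                x$a_mean, x$a_sd, x$r2_mean, x$r2_sd))
  }
  invisible(x)
}

#' @export
print.substituted_segment <- function(x, ...) {
  cat(sprintf("<substituted_segment> chr %s core [%.1f, %.1f] maximal [%.1f, %.1f] cM\n",
              x$chr, x$core[1], x$core[2], x$maximal[1], x$maximal[2]))
  invisible(x)
}

#' @export
print.sssl_line <- function(x, ...) {
  cat(sprintf("<sssl_line> %s (donor %s), %d season(s)\n",
              x$line_id, x$donor_id, length(x$phenotypes)))
  print(x$segment)
  invisible(x)
}
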