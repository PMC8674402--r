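# Substitution mapping: integrate per-line detections into loci and
# localize each locus by interval intersection / negative-evidence
# subtraction.

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Group per-line QTL detections into integrated loci
#'
#' Detections on the same chromosome whose maximal segment intervals
#' overlap (with positive length) and whose effects have the same sign are
#' taken to tag the same locus; groups are the connected components of
#' that overlap graph.  Names follow the rice convention
#' `q<trait><chromosome><letter>`: within a chromosome, groups are ordered
#' from the short-arm end (smallest cM) and suffixed `a`, `b`, ... only
#' when the chromosome carries more than one locus.
#'
#' @param detections List of [detection_result()]s (undetected entries are
#'   dropped with a message).
#' @param segments Named list, line id -> [substituted_segment()].
#' @param trait Trait tag used in names (default `"LTG"`).
#' @return List of `qtl_group` objects, ordered by chromosome then
#'   position.  Each has `name`, `chr`, `members` (detection results),
#'   `segments`, `effect_sign`.
#' @export
group_detections <- function(detections, segments, trait = "LTG") {
  if (!length(detections)) return(list())
  det <- Filter(function(d) isTRUE(d$detected), detections)
  if (length(det) < length(detections)) {
    message(length(detections) - length(det), " undetected line(s) ignored")
  }
  ids <- vapply(det, `[[`, character(1), "line_id")
  ord <- order(ids)  # canonical order: grouping is permutation-invariant
  det <- det[ord]; ids <- ids[ord]
  miss <- setdiff(ids, names(segments))
  if (length(miss)) stop("no segment for line(s): ", paste(miss, collapse = ", "))
  segs <- segments[ids]
  chr <- vapply(segs, `[[`, character(1), "chr")
  sgn <- vapply(det, `[[`, numeric(1), "effect_sign")

  n <- length(det)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (chr[i] == chr[j] && sgn[i] == sgn[j] &&
        iv_overlaps(segs[[i]]$maximal, segs[[j]]$maximal)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  groups <- lapply(unique(comp), function(k) {
    idx <- which(comp == k)
    start <- min(vapply(segs[idx], function(s) s$maximal[1], numeric(1)))
    structure(list(name = NA_character_, chr = chr[idx[1]],
                   members = det[idx], segments = segs[idx],
                   effect_sign = sgn[idx[1]], .start = start),
              class = "qtl_group")
  })

  g_chr <- vapply(groups, `[[`, character(1), "chr")
  g_start <- vapply(groups, `[[`, numeric(1), ".start")
  chr_key <- suppressWarnings(as.numeric(g_chr))
  if (anyNA(chr_key)) chr_key <- rank(g_chr)
  groups <- groups[order(chr_key, g_start)]
  g_chr <- vapply(groups, `[[`, character(1), "chr")
  for (cc in unique(g_chr)) {
    at <- which(g_chr == cc)
    suff <- if (length(at) > 1) letters[seq_along(at)] else ""
    for (k in seq_along(at)) {
      groups[[at[k]]]$name <- paste0("q", trait, cc, suff[k])
    }
  }
  groups
}

#' @export
print.qtl_group <- function(x, ...) {
  cat(sprintf("<qtl_group> %s (chr %s, sign %+d): %s\n", x$name, x$chr,
              x$effect_sign,
              paste(vapply(x$members, `[[`, character(1), "line_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Localize a QTL by substitution mapping
#'
#' The locus interval is the intersection of the member lines' maximal
#' segment intervals, minus the core intervals of overlapping lines in
#' which the QTL was *not* detected (negative evidence).  Subtraction
#' removes core interiors only, so an endpoint marker shared with a
#' negative line stays in the remainder.  The result may consist of
#' several disjoint intervals.
#'
#' @param group A `qtl_group` from [group_detections()], or a list of
#'   [substituted_segment()]s (all on one chromosome).
#' @param nonsignificant Named list, line id -> [substituted_segment()],
#'   of lines with no detected QTL; only those on the group's chromosome
#'   whose core overlaps the running interval are used.
#' @return Data frame with columns `start`, `end` (cM, closed intervals).
#'   An empty data frame, flagged with `attr(, "conflict")` and a warning,
#'   means the negative evidence excluded the whole intersection.
#' @export
localize_qtl <- function(group, nonsignificant = list()) {
  if (inherits(group, "qtl_group")) {
    segs <- group$segments
    ids <- vapply(group$members, `[[`, character(1), "line_id")
    label <- group$name
  } else {
    segs <- group
    ids <- names(segs)
    if (is.null(ids)) ids <- paste0("member", seq_along(segs))
    label <- "group"
  }
  if (!length(segs)) stop("empty group")
  chr <- segs[[1]]$chr
  stopifnot(all(vapply(segs, `[[`, character(1), "chr") == chr))

  region <- iv(segs[[1]]$maximal[1], segs[[1]]$maximal[2])
  for (s in segs[-1]) {
    region <- iv_intersect(region, iv(s$maximal[1], s$maximal[2]))
    if (!nrow(region)) {
      stop("conflict: no common interval among members ",
           paste(ids, collapse = ", "))
    }
  }
  for (k in seq_along(nonsignificant)) {
    ns <- nonsignificant[[k]]
    if (ns$chr != chr) next
    touches <- any(vapply(seq_len(nrow(region)), function(i) {
      iv_overlaps(c(region$start[i], region$end[i]), ns$core)
    }, logical(1)))
    if (!touches) next
    region <- iv_subtract(region, iv(ns$core[1], ns$core[2]))
    if (!nrow(region)) break
  }
  if (!nrow(region)) {
    warning("negative evidence excludes the whole interval for ", label)
    attr(region, "conflict") <- TRUE
  }
  rownames(region) <- NULL
  region
}

#' Summarize an integrated QTL (Table-2 style row)
#'
#' Member-averaged additive effect and contribution with their sample SDs
#' (n - 1).  A single-member group carries the member's season-averaged
#' value and its season SD through unchanged.
#'
#' @param group A `qtl_group`.
#' @return An `integrated_qtl`: list with `name`, `chr`, `donors`,
#'   `member_ids`, `a_mean`, `a_sd`, `r2_mean`, `r2_sd` (`r2` in percent).
#' @export
summarize_group <- function(group) {
  stopifnot(inherits(group, "qtl_group"))
  a <- vapply(group$members, `[[`, numeric(1), "a_mean")
  r2 <- vapply(group$members, `[[`, numeric(1), "r2_mean")
  if (length(a) == 1) {
    a_mean <- unname(a); a_sd <- group$members[[1]]$a_sd
    r2_mean <- unname(r2); r2_sd <- group$members[[1]]$r2_sd
  } else {
    a_mean <- mean(a); a_sd <- stats::sd(a)
    r2_mean <- mean(r2); r2_sd <- stats::sd(r2)
  }
  structure(list(name = group$name, chr = group$chr,
                 donors = unique(vapply(group$members, function(m) {
                   if (!is.null(m$donor_id)) m$donor_id else NA_character_
                 }, character(1))),
                 member_ids = vapply(group$members, `[[`, character(1),
                                     "line_id"),
                 a_mean = a_mean, a_sd = a_sd,
                 r2_mean = r2_mean, r2_sd = r2_sd),
            class = "integrated_qtl")
}

#' @export
print.integrated_qtl <- function(x, ...) {
  cat(sprintf("<integrated_qtl> %s (chr %s): a = %.2f +/- %.2f, R2 = %.1f +/- %.1f %%\n",
              x$name, x$chr, x$a_mean, x$a_sd, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Integrate detections into a QTL summary table
#'
#' Convenience wrapper: groups detections, localizes every group against
#' the non-significant lines and formats one row per integrated QTL.
#' Effects are rounded half-away-from-zero to 2 decimals (`a`) and 1
#' decimal (`R2` percent) in the formatted columns; unrounded values are
#' kept in `a_mean`, `a_sd`, `r2_mean`, `r2_sd`.
#'
#' @inheritParams group_detections
#' @param nonsignificant Named list of segments of undetected lines.
#' @return Data frame, one row per QTL: `qtl`, `chr`, `interval`
#'   (cM string), `length_cm`, `a`, `r2`, `members`, plus unrounded
#'   numeric columns.
#' @export
integrate_qtls <- function(detections, segments, nonsignificant = list(),
                           trait = "LTG") {
  groups <- group_detections(detections, segments, trait = trait)
  rows <- lapply(groups, function(g) {
    loc <- localize_qtl(g, nonsignificant)
    sm <- summarize_group(g)
    data.frame(
      qtl = g$name, chr = g$chr,
      interval = paste(sprintf("%.1f-%.1f", loc$start, loc$end),
                       collapse = "; "),
      length_cm = sum(loc$end - loc$start),
      a = sprintf("%.2f +/- %.2f", round_half_away(sm$a_mean, 2),
                  round_half_away(sm$a_sd, 2)),
      r2 = sprintf("%.1f +/- %.1f", round_half_away(sm$r2_mean, 1),
                   round_half_away(sm$r2_sd, 1)),
      members = paste(sm$member_ids, collapse = ","),
      a_mean = sm$a_mean, a_sd = sm$a_sd,
      r2_mean = sm$r2_mean, r2_sd = sm$r2_sd,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
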