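# Closed-interval algebra shared by substitution mapping (cM) and
# recombinant fine mapping (bp).
#
# Semantics (see the methods vignette):
#   * intervals are closed, [start, end], start <= end; degenerate points
#     are legal and preserved;
#   * two intervals "overlap" only when their intersection has positive
#     length (touching at a single shared marker does not connect lines);
#   * subtracting a negative interval removes its open interior, so a
#     boundary shared with negative evidence stays in the remainder.

iv <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (any(end < start)) stop("interval start must be <= end")
  data.frame(start = as.numeric(start), end = as.numeric(end))
}

iv_empty <- function() iv(numeric(), numeric())

# merge overlapping or touching pieces (closed union)
iv_normalize <- function(x) {
  if (!nrow(x)) return(x)
  x <- x[order(x$start, x$end), , drop = FALSE]
  out_s <- x$start[1]; out_e <- x$end[1]
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      k <- length(out_s)
      if (x$start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], x$end[i])
      } else {
        out_s <- c(out_s, x$start[i]); out_e <- c(out_e, x$end[i])
      }
    }
  }
  iv(out_s, out_e)
}

iv_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(iv_empty())
  res_s <- numeric(); res_e <- numeric()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start); hi <- pmin(a$end[i], b$end)
    keep <- lo <= hi
    res_s <- c(res_s, lo[keep]); res_e <- c(res_e, hi[keep])
  }
  iv_normalize(iv(res_s, res_e))
}

# remove the open interiors of `b` from `a`
iv_subtract <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  pieces <- a
  for (j in seq_len(nrow(b))) {
    bs <- b$start[j]; be <- b$end[j]
    if (bs == be) next  # zero-length negative: empty interior
    nxt_s <- numeric(); nxt_e <- numeric()
    for (i in seq_len(nrow(pieces))) {
      s <- pieces$start[i]; e <- pieces$end[i]
      if (be <= s || bs >= e) {        # interior misses this piece
        nxt_s <- c(nxt_s, s); nxt_e <- c(nxt_e, e)
        next
      }
      if (s <= bs) { nxt_s <- c(nxt_s, s); nxt_e <- c(nxt_e, bs) }
      if (be <= e) { nxt_s <- c(nxt_s, be); nxt_e <- c(nxt_e, e) }
    }
    pieces <- iv(nxt_s, nxt_e)
    if (!nrow(pieces)) break
  }
  pieces[order(pieces$start), , drop = FALSE]
}

# positive-length intersection between single intervals c(start, end)
iv_overlaps <- function(a, b) {
  max(a[1], b[1]) < min(a[2], b[2])
}
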