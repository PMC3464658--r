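#' Interval utilities
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`;
#' 1-based inclusive coordinates appear only in on-disk formats (FASTA
#' headers excepted) and are converted at the I/O boundary.
#'
#' @param start,end integer vectors, `0 <= start < end`.
#' @param seq optional sequence name(s).
#' @return a data.frame with columns `seq`, `start`, `end`.
#' @export
ts_interval <- function(start, end, seq = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0L) || any(end <= start))
    stop("invalid interval: need 0 <= start < end")
  data.frame(seq = seq, start = start, end = end, stringsAsFactors = FALSE)
}

#' Gap between two ordered non-overlapping intervals
#'
#' Distance d(u, v) = v_start - u_end between two intervals with u entirely
#' before v; 0 means the intervals abut.
#'
#' @param u,v intervals as returned by [ts_interval()] (single rows).
#' @return non-negative integer gap in bases.
#' @export
interval_gap <- function(u, v) {
  if (!is.na(u$seq) && !is.na(v$seq) && u$seq != v$seq)
    stop("intervals on different sequences")
  if (u$end > v$start)
    stop("intervals overlap or are wrongly ordered (need u.end <= v.start)")
  as.integer(v$start - u$end)
}

# vectorised gap on raw coordinates; returns NA where u is not before v
gap_vec <- function(ue, vs) {
  g <- vs - ue
  g[g < 0L] <- NA_integer_
  as.integer(g)
}

# vectorised overlap length of [s1,e1) and [s2,e2)
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Fractional overlap of two intervals
#'
#' @param u,v intervals (single rows).
#' @param denominator which interval's length divides the intersection:
#'   `"first"`, `"second"`, or `"smaller"`.
#' @return fraction in `[0, 1]`; 0 when disjoint.
#' @export
overlap_fraction <- function(u, v, denominator = c("smaller", "first", "second")) {
  denominator <- match.arg(denominator)
  if (!is.na(u$seq) && !is.na(v$seq) && u$seq != v$seq) return(0)
  ov <- overlap_len(u$start, u$end, v$start, v$end)
  len_u <- u$end - u$start
  len_v <- v$end - v$start
  den <- switch(denominator,
                first = len_u, second = len_v, smaller = min(len_u, len_v))
  as.numeric(ov) / den
}

# total length of the union of a set of [s,e) intervals
union_length <- function(s, e) {
  if (length(s) == 0L) return(0L)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0L; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}
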