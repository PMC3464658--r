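## Anchor detection: seeded gapped X-drop self-alignment of one sequence
## (both strands), tandem filtering and anchor deduplication.

# raw self-alignment of one sequence; returns unfiltered anchor rows
self_align <- function(seq, scheme, seq_name = "seq") {
  codes <- seq_codes(seq)
  ok <- !seq_mask(seq) & codes < 4L
  sm <- dna_matrix(scheme)
  plus <- cpp_seed_extend(codes, codes, ok, ok, sm, 4L,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$seed_k, scheme$xdrop,
                          scheme$min_anchor_score, TRUE, 100L, 500000L)
  n <- nchar(seq)
  rc <- revcomp_chr(seq)
  codes_rc <- seq_codes(rc)
  ok_rc <- !seq_mask(rc) & codes_rc < 4L
  minus <- cpp_seed_extend(codes, codes_rc, ok, ok_rc, sm, 4L,
                           scheme$gap_open, scheme$gap_extend,
                           scheme$seed_k, scheme$xdrop,
                           scheme$min_anchor_score, FALSE, 100L, 500000L)
  rows <- list()
  if (nrow(plus))
    rows$p <- data.frame(seq = seq_name, s0 = plus$qs, e0 = plus$qe,
                         s1 = plus$ss, e1 = plus$se, sign = "+",
                         score = plus$score, stringsAsFactors = FALSE)
  if (nrow(minus)) {
    ## subject coordinates are on the reverse complement; map back
    ms0 <- minus$qs; me0 <- minus$qe
    ms1 <- n - minus$se; me1 <- n - minus$ss
    swap <- ms1 < ms0
    mm <- data.frame(seq = seq_name,
                     s0 = ifelse(swap, ms1, ms0), e0 = ifelse(swap, me1, me0),
                     s1 = ifelse(swap, ms0, ms1), e1 = ifelse(swap, me0, me1),
                     sign = "-", score = minus$score, stringsAsFactors = FALSE)
    ## each inverted repeat is found twice (once from each copy); dedupe
    mm <- mm[!duplicated(mm[, c("s0", "e0", "s1", "e1")]), , drop = FALSE]
    rows$m <- mm
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_anchors()[, setdiff(names(empty_anchors()), "id")]
  rownames(out) <- NULL
  out
}

#' Find tandem-constrained anchors by self-alignment
#'
#' Indexes all unmasked exact k-mers of the sequence and of its reverse
#' complement, extends every non-trivial seed pair with gapped X-drop
#' alignment under the scoring scheme (the main diagonal and
#' self-overlapping extensions are excluded constructively), and keeps
#' local alignments whose paired intervals form a valid tandem anchor:
#' non-overlapping copies at most `T` apart, positive score.
#'
#' @param seq a single sequence (character scalar), possibly soft-masked.
#' @param scheme a [scoring_scheme()].
#' @param T maximum gap between the two copies (bases).
#' @param seq_name sequence identifier carried into the anchor table.
#' @return anchor data.frame (`id, seq, s0, e0, s1, e1, sign, score`).
#' @export
find_anchors <- function(seq, scheme = scoring_scheme(), T = 150000L,
                         seq_name = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  raw <- self_align(seq, scheme, seq_name)
  raw$id <- seq_len(nrow(raw))
  raw <- raw[, c("id", "seq", "s0", "e0", "s1", "e1", "sign", "score")]
  filter_tandem_anchors(raw, T)
}

#' Keep only anchors compatible with a tandem duplication
#'
#' Retains anchors whose first copy ends before the second starts and whose
#' gap is at most `T`; order is preserved.
#'
#' @param anchors anchor data.frame (first-copy-first normalised).
#' @param T maximum copy gap (bases).
#' @return filtered anchor data.frame; attribute `n_dropped` counts drops.
#' @export
filter_tandem_anchors <- function(anchors, T = 150000L) {
  if (nrow(anchors) == 0L) return(anchors)
  keep <- anchors$e0 <= anchors$s1 & (anchors$s1 - anchors$e0) <= T &
          anchors$score > 0L
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Remove anchors duplicated on both projections
#'
#' Among any pair of anchors whose first intervals overlap by more than
#' `max_mutual_overlap` (fraction of the smaller) *and* whose second
#' intervals do too, only the better anchor is kept (higher score, then
#' longer, then smaller id). The surviving set guarantees that single-anchor
#' chains are always mutually consistent, which makes the maximum-flow
#' fallback of the chaining step well defined.
#'
#' @param anchors tandem-filtered anchor data.frame.
#' @param max_mutual_overlap overlap fraction above which two anchors
#'   conflict (default 0.5).
#' @return deduplicated anchors in original order; attribute `n_dropped`.
#' @export
dedupe_anchors <- function(anchors, max_mutual_overlap = 0.5) {
  n <- nrow(anchors)
  if (n <= 1L) return(anchors)
  len <- (anchors$e0 - anchors$s0) + (anchors$e1 - anchors$s1)
  o <- order(-anchors$score, -len, anchors$id)
  kept <- integer(0)
  for (i in o) {
    if (length(kept)) {
      o0 <- overlap_len(anchors$s0[i], anchors$e0[i],
                        anchors$s0[kept], anchors$e0[kept])
      o1 <- overlap_len(anchors$s1[i], anchors$e1[i],
                        anchors$s1[kept], anchors$e1[kept])
      l0 <- pmin(anchors$e0[i] - anchors$s0[i],
                 anchors$e0[kept] - anchors$s0[kept])
      l1 <- pmin(anchors$e1[i] - anchors$s1[i],
                 anchors$e1[kept] - anchors$s1[kept])
      if (any(o0 / l0 > max_mutual_overlap & o1 / l1 > max_mutual_overlap))
        next
    }
    kept <- c(kept, i)
  }
  out <- anchors[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n - length(kept)
  out
}
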