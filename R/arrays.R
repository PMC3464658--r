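## Tandem array delineation: overlap graph (G2) over chains and residual
## anchors, connected components extended by L, and reference duplication
## unit extraction by iterative self-similarity trimming.

# projection intervals of the G2 vertices: two per chain, two per anchor
g2_vertices <- function(chains, residual_anchors) {
  v <- list()
  if (nrow(chains))
    v$c <- data.frame(kind = "chain", ref = chains$id, seq = chains$seq,
                      i0s = chains$c0s, i0e = chains$c0e,
                      i1s = chains$c1s, i1e = chains$c1e,
                      stringsAsFactors = FALSE)
  if (!is.null(residual_anchors) && nrow(residual_anchors))
    v$a <- data.frame(kind = "anchor", ref = residual_anchors$id,
                      seq = residual_anchors$seq,
                      i0s = residual_anchors$s0, i0e = residual_anchors$e0,
                      i1s = residual_anchors$s1, i1e = residual_anchors$e1,
                      stringsAsFactors = FALSE)
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(kind = character(), ref = integer(), seq = character(),
               i0s = integer(), i0e = integer(), i1s = integer(),
               i1e = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the chain/anchor overlap graph
#'
#' Vertices are the consistent chains plus the residual anchors (anchors in
#' no chain); two vertices are connected iff any projection interval of one
#' overlaps any projection interval of the other by at least `min_overlap`
#' of the smaller interval.
#'
#' @param chains chain data.frame.
#' @param residual_anchors anchor data.frame (may be empty or NULL).
#' @param min_overlap minimum fractional overlap (default 0.5).
#' @return list of class `ts_overlap_graph`: `vertices` (data.frame) and
#'   `graph` (igraph, undirected).
#' @export
build_overlap_graph <- function(chains, residual_anchors = NULL,
                                min_overlap = 0.5) {
  v <- g2_vertices(chains, residual_anchors)
  n <- nrow(v)
  ef <- integer(0); et <- integer(0)
  if (n > 1L) {
    S <- cbind(v$i0s, v$i1s); E <- cbind(v$i0e, v$i1e)
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      hit <- rep(FALSE, length(js))
      for (x in 1:2) for (y in 1:2) {
        ov <- overlap_len(S[i, x], E[i, x], S[js, y], E[js, y])
        sm <- pmin(E[i, x] - S[i, x], E[js, y] - S[js, y])
        hit <- hit | (ov / sm >= min_overlap)
      }
      hit <- hit & v$seq[js] == v$seq[i]
      if (any(hit)) { ef <- c(ef, rep.int(i, sum(hit))); et <- c(et, js[hit]) }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, as.vector(rbind(ef, et)))
  structure(list(vertices = v, graph = g), class = "ts_overlap_graph")
}

#' Delineate tandem arrays from the overlap graph
#'
#' Each connected component becomes a tandem array whose region is the
#' smallest interval encompassing all member projections, enlarged by `L`
#' on each side and clamped to the sequence bounds.
#'
#' @param og a `ts_overlap_graph`.
#' @param L extension margin in bases (default 40000).
#' @param seq_lengths named integer vector of sequence lengths.
#' @return tandem array data.frame (`array_id, seq, start, end, span_start,
#'   span_end, n_members`) with list columns `member_chains` and
#'   `member_anchors`; sorted by (seq, start).
#' @export
delineate_arrays <- function(og, L = 40000L, seq_lengths) {
  v <- og$vertices
  empty <- data.frame(array_id = character(), seq = character(),
                      start = integer(), end = integer(),
                      span_start = integer(), span_end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE)
  empty$member_chains <- I(list()); empty$member_anchors <- I(list())
  if (nrow(v) == 0L) return(empty)
  comp <- igraph::components(og$graph)$membership[seq_len(nrow(v))]
  rows <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    sq <- v$seq[idx[1L]]
    lo <- min(v$i0s[idx], v$i1s[idx])
    hi <- max(v$i0e[idx], v$i1e[idx])
    slen <- seq_lengths[[sq]]
    rows[[length(rows) + 1L]] <- list(
      seq = sq, start = as.integer(max(0, lo - L)),
      end = as.integer(min(slen, hi + L)),
      span_start = as.integer(lo), span_end = as.integer(hi),
      n_members = length(idx),
      member_chains = v$ref[idx][v$kind[idx] == "chain"],
      member_anchors = v$ref[idx][v$kind[idx] == "anchor"])
  }
  df <- data.frame(seq = vapply(rows, `[[`, "", "seq"),
                   start = vapply(rows, `[[`, 0L, "start"),
                   end = vapply(rows, `[[`, 0L, "end"),
                   span_start = vapply(rows, `[[`, 0L, "span_start"),
                   span_end = vapply(rows, `[[`, 0L, "span_end"),
                   n_members = vapply(rows, `[[`, 0L, "n_members"),
                   stringsAsFactors = FALSE)
  df$member_chains <- I(lapply(rows, `[[`, "member_chains"))
  df$member_anchors <- I(lapply(rows, `[[`, "member_anchors"))
  df <- df[order(df$seq, df$start, df$end), , drop = FALSE]
  df <- cbind(array_id = sprintf("ta%d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# off-diagonal local self-alignments of a candidate unit (both strands)
unit_self_hits <- function(residues, scheme) {
  h <- self_align(toupper(residues), scheme, "unit")
  if (nrow(h)) h <- h[order(h$score, h$s0, h$s1), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Fraction of a sequence covered by off-diagonal self-alignment
#'
#' Aligns the sequence against itself with the anchoring aligner (main
#' diagonal excluded) and returns the fraction of positions covered by at
#' least one local alignment interval.
#'
#' @param residues candidate unit sequence (character scalar).
#' @param scheme a [scoring_scheme()].
#' @return fraction in `[0, 1]`.
#' @export
self_similar_fraction <- function(residues, scheme = scoring_scheme()) {
  stopifnot(nchar(residues) > 0L)
  h <- unit_self_hits(residues, scheme)
  if (nrow(h) == 0L) return(0)
  union_length(c(h$s0, h$s1), c(h$e0, h$e1)) / nchar(residues)
}

#' Extract the reference duplication unit of a tandem array
#'
#' The candidate is the longest projection interval of the array's
#' minimum-cost chain (ties broken by length, then chain id; arrays with
#' only residual anchors use the longest anchor interval). While at least
#' half of the candidate is self-similar, the lowest-scoring self-alignment
#' is located, the candidate extremity closest to its nearer interval is
#' identified, and the candidate is trimmed past that interval's inner
#' boundary. Trimming stops when less than half the sequence is
#' self-similar; if the candidate would shrink below `ell` the untrimmed
#' candidate is returned flagged `"unresolved_unit"`.
#'
#' @param array single tandem array row from [delineate_arrays()].
#' @param chains chain data.frame.
#' @param anchors anchor data.frame.
#' @param seq the genome sequence (character scalar) the array lies on.
#' @param scheme a [scoring_scheme()].
#' @param ell minimum unit length (default 500).
#' @return a list (`seq`, `start`, `end`, `residues`, `source_chain`,
#'   `flag`) or NULL when every candidate is shorter than `ell`.
#' @export
select_reference_unit <- function(array, chains, anchors, seq,
                                  scheme = scoring_scheme(), ell = 500L) {
  mc <- array$member_chains[[1L]]
  ma <- array$member_anchors[[1L]]
  if (length(mc) == 0L && length(ma) == 0L)
    stop("array has no members")
  if (length(mc)) {
    cc <- chains[chains$id %in% mc, , drop = FALSE]
    span <- pmax(cc$c0e - cc$c0s, cc$c1e - cc$c1s)
    o <- order(cc$cost, -span, cc$id)
    best <- cc[o[1L], ]
    if (best$c0e - best$c0s >= best$c1e - best$c1s) {
      cand <- c(best$c0s, best$c0e)
    } else cand <- c(best$c1s, best$c1e)
    src <- best$id
  } else {
    aa <- anchors[anchors$id %in% ma, , drop = FALSE]
    lens <- pmax(aa$e0 - aa$s0, aa$e1 - aa$s1)
    best <- aa[order(-lens, aa$id)[1L], ]
    cand <- if (best$e0 - best$s0 >= best$e1 - best$s1) c(best$s0, best$e0)
            else c(best$s1, best$e1)
    src <- NA_integer_
  }
  if (cand[2L] - cand[1L] < ell) return(NULL)
  orig <- cand
  flag <- "ok"
  repeat {
    res <- substr(seq, cand[1L] + 1L, cand[2L])
    h <- unit_self_hits(res, scheme)
    frac <- if (nrow(h)) union_length(c(h$s0, h$s1), c(h$e0, h$e1)) / nchar(res)
            else 0
    if (frac < 0.5) break
    hsp <- h[1L, ] # lowest score, deterministic tie-break
    len <- cand[2L] - cand[1L]
    dl <- hsp$s0                 # left extremity to left interval start
    dr <- len - hsp$e1           # right extremity to right interval end
    nxt <- if (dl <= dr) c(cand[1L] + hsp$e0, cand[2L])
           else c(cand[1L], cand[1L] + hsp$s1)
    if (nxt[2L] - nxt[1L] < ell || nxt[2L] - nxt[1L] >= len) {
      cand <- orig
      flag <- "unresolved_unit"
      break
    }
    cand <- nxt
  }
  list(seq = array$seq, start = cand[1L], end = cand[2L],
       residues = toupper(substr(seq, cand[1L] + 1L, cand[2L])),
       source_chain = src, flag = flag)
}
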