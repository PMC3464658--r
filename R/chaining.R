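## Anchor chaining: the weighted anchor DAG (G1) and the extraction of an
## optimal set of mutually non-overlapping t-chains by successive-shortest-
## path minimum-cost flow (Busacker-Gowen), iterated until the chain set is
## consistent (every chain a t-chain, no pair overlapping on both axes).

mid0 <- function(a) (a$s0 + a$e0) / 2
mid1 <- function(a) (a$s1 + a$e1) / 2

#' Successor relation between two anchors
#'
#' Anchor `b` can follow anchor `a` in a chain iff they share sign, the
#' midpoint of `b`'s first interval lies after `a`'s, and the midpoints of
#' the second intervals are ordered the same way for sign `+` and the
#' opposite way for sign `-`. A strict partial order.
#'
#' @param a,b single anchor rows.
#' @return logical.
#' @export
precedes <- function(a, b) {
  a$sign == b$sign &&
    mid0(a) < mid0(b) &&
    (if (a$sign == "+") mid1(a) < mid1(b) else mid1(a) > mid1(b))
}

#' Gap-based distance between two chainable anchors
#'
#' `d(a, b) = 2 max(D0, D1) - min(D0, D1)` where `D0`/`D1` are the gaps
#' between the two anchors' projections on each axis, taken in traversal
#' order (for sign `-` the second-axis intervals run in decreasing
#' coordinates). Smaller when the anchors sit on the same diagonal.
#'
#' @param a,b single anchor rows with `precedes(a, b)` true.
#' @return non-negative distance in bases.
#' @export
anchor_distance <- function(a, b) {
  if (!precedes(a, b)) stop("b is not a successor of a")
  d0 <- a$e0 <= b$s0
  if (!d0) stop("projections overlap on the first axis: not chainable")
  D0 <- b$s0 - a$e0
  if (a$sign == "+") {
    if (a$e1 > b$s1) stop("projections overlap on the second axis")
    D1 <- b$s1 - a$e1
  } else {
    if (b$e1 > a$s1) stop("projections overlap on the second axis")
    D1 <- a$s1 - b$e1
  }
  as.numeric(2 * max(D0, D1) - min(D0, D1))
}

#' Per-base anchor coverage profile
#'
#' `c(i)` counts, for every position of the sequence, how many anchor
#' intervals (first or second copy, over all anchors) contain it.
#'
#' @param anchors anchor data.frame (one sequence).
#' @param seq_length length of the sequence.
#' @return integer vector of length `seq_length`.
#' @export
coverage_profile <- function(anchors, seq_length) {
  d <- integer(seq_length + 1L)
  if (nrow(anchors)) {
    st <- c(anchors$s0, anchors$s1) + 1L
    en <- c(anchors$e0, anchors$e1) + 1L
    for (x in st) d[x] <- d[x] + 1L
    for (x in en) d[x] <- d[x] - 1L
  }
  cumsum(d)[seq_len(seq_length)]
}

#' Mean coverage of an anchor's two intervals
#'
#' @param a single anchor row.
#' @param profile output of [coverage_profile()].
#' @return mean of `c(i)` over the positions of both intervals.
#' @export
mean_anchor_coverage <- function(a, profile) {
  pref <- c(0, cumsum(profile))
  s <- (pref[a$e0 + 1L] - pref[a$s0 + 1L]) + (pref[a$e1 + 1L] - pref[a$s1 + 1L])
  s / ((a$e0 - a$s0) + (a$e1 - a$s1))
}

# vectorised m_a for all anchors
mean_coverage_all <- function(anchors, profile) {
  pref <- c(0, cumsum(as.numeric(profile)))
  s <- (pref[anchors$e0 + 1L] - pref[anchors$s0 + 1L]) +
       (pref[anchors$e1 + 1L] - pref[anchors$s1 + 1L])
  s / ((anchors$e0 - anchors$s0) + (anchors$e1 - anchors$s1))
}

# mean coverage when the two projections live on different axes: each
# interval is measured against the profile of its own axis
cross_axis_coverage <- function(hits) {
  p0 <- coverage_profile(data.frame(s0 = hits$s0, e0 = hits$e0,
                                    s1 = hits$s0, e1 = hits$e0),
                         max(hits$e0)) / 2
  p1 <- coverage_profile(data.frame(s0 = hits$s1, e0 = hits$e1,
                                    s1 = hits$s1, e1 = hits$e1),
                         max(hits$e1)) / 2
  pf0 <- c(0, cumsum(p0)); pf1 <- c(0, cumsum(p1))
  s <- (pf0[hits$e0 + 1L] - pf0[hits$s0 + 1L]) +
       (pf1[hits$e1 + 1L] - pf1[hits$s1 + 1L])
  s / ((hits$e0 - hits$s0) + (hits$e1 - hits$s1))
}

#' Build the weighted anchor DAG
#'
#' Vertices are anchors with cost `-m_a * score` (`m_a` the mean coverage,
#' favouring anchors whose regions recur in other anchors). A candidate
#' edge (a, b) requires `precedes(a, b)`, gap distance at most `L`, and the
#' merged pair's two projection spans to be disjoint. Only the `k`
#' lowest-distance edges leave each vertex; edge costs are then rescaled so
#' their mean equals the absolute mean vertex cost.
#'
#' @param anchors anchor data.frame (one sequence, deduplicated).
#' @param L maximum gap distance between chained anchors (bases).
#' @param k maximum out-degree.
#' @param seq_length sequence length (defaults to the anchor extent).
#' @param coverage optional precomputed [coverage_profile()].
#' @param cross_axis set TRUE when the two projections live on different
#'   coordinate systems (unit-vs-region hit graphs): the same-sequence
#'   span-disjointness requirement is then dropped and per-axis coverage
#'   profiles are used for the vertex cost.
#' @return a list of class `ts_graph`: `anchors`, `vcost`, `edges`
#'   (`from, to, dist, cost`), `scale`.
#' @export
build_anchor_graph <- function(anchors, L, k = 15L, seq_length = NULL,
                               coverage = NULL, cross_axis = FALSE) {
  n <- nrow(anchors)
  if (cross_axis) {
    vcost <- if (n) -cross_axis_coverage(anchors) * anchors$score else numeric(0)
  } else {
    if (is.null(seq_length)) seq_length <- if (n) max(anchors$e1, anchors$e0) else 0L
    if (is.null(coverage)) coverage <- coverage_profile(anchors, seq_length)
    vcost <- if (n) -mean_coverage_all(anchors, coverage) * anchors$score else numeric(0)
  }
  m0 <- (anchors$s0 + anchors$e0) / 2
  m1 <- (anchors$s1 + anchors$e1) / 2
  ef <- integer(0); et <- integer(0); ed <- numeric(0)
  for (i in seq_len(n)) {
    same <- anchors$sign == anchors$sign[i] & m0[i] < m0
    ord1 <- if (anchors$sign[i] == "+") m1[i] < m1 else m1[i] > m1
    cand <- which(same & ord1)
    if (!length(cand)) next
    D0 <- anchors$s0[cand] - anchors$e0[i]
    D1 <- if (anchors$sign[i] == "+") anchors$s1[cand] - anchors$e1[i]
          else anchors$s1[i] - anchors$e1[cand]
    ok <- D0 >= 0 & D1 >= 0
    if (!cross_axis) {
      # merged projections must not overlap (t-chain feasibility of the pair)
      sp0s <- pmin(anchors$s0[i], anchors$s0[cand])
      sp0e <- pmax(anchors$e0[i], anchors$e0[cand])
      sp1s <- pmin(anchors$s1[i], anchors$s1[cand])
      sp1e <- pmax(anchors$e1[i], anchors$e1[cand])
      ok <- ok & (sp0e <= sp1s | sp1e <= sp0s)
    }
    d <- 2 * pmax(D0, D1) - pmin(D0, D1)
    ok <- ok & !is.na(d) & d <= L
    cand <- cand[ok]; d <- d[ok]
    if (!length(cand)) next
    if (length(cand) > k) {
      o <- order(d, cand)[seq_len(k)]
      cand <- cand[o]; d <- d[o]
    }
    ef <- c(ef, rep.int(i, length(cand))); et <- c(et, cand); ed <- c(ed, d)
  }
  scale <- 1
  if (length(ed) && mean(ed) > 0 && length(vcost)) {
    scale <- abs(mean(vcost)) / mean(ed)
  } else if (length(ed)) {
    message("degenerate edge rescale (mean edge distance 0); scale = 1")
  }
  edges <- data.frame(from = ef, to = et, dist = ed, cost = ed * scale)
  o <- order(edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(anchors = anchors, vcost = vcost, edges = edges,
                 scale = scale),
            class = "ts_graph")
}

#' Check a chain set for tandem consistency
#'
#' Reports every chain whose two projections overlap or lie more than `T`
#' apart (strict, per chain), and every pair of chains whose projections
#' overlap on both axes by more than `max_overlap` of the smaller interval
#' (the either/or non-overlap condition). The pairwise tolerance matches
#' the anchor dedup threshold, which is what guarantees that the maximum
#' flow fallback - all single-anchor chains - is always consistent.
#'
#' @param chains chain data.frame.
#' @param T maximum projection gap.
#' @param cross_axis TRUE for unit-vs-region chains, whose two projections
#'   live on different axes: only the pairwise overlap condition applies.
#' @param max_overlap pairwise overlap fraction above which two chains
#'   conflict (default 0.5, the dedup threshold).
#' @return data.frame of violations (`type`, `chain1`, `chain2`); zero rows
#'   means the set is consistent.
#' @export
check_chain_set <- function(chains, T = 150000L, cross_axis = FALSE,
                            max_overlap = 0.5) {
  v <- list()
  n <- nrow(chains)
  if (n == 0L) return(data.frame(type = character(), chain1 = integer(),
                                 chain2 = integer()))
  if (!cross_axis) for (i in seq_len(n)) {
    ol <- overlap_len(chains$c0s[i], chains$c0e[i], chains$c1s[i], chains$c1e[i])
    if (ol > 0L) {
      v[[length(v) + 1L]] <- data.frame(type = "self_overlap",
                                        chain1 = chains$id[i], chain2 = NA)
    } else {
      g <- if (chains$c0e[i] <= chains$c1s[i]) chains$c1s[i] - chains$c0e[i]
           else chains$c0s[i] - chains$c1e[i]
      if (g > T)
        v[[length(v) + 1L]] <- data.frame(type = "gap", chain1 = chains$id[i],
                                          chain2 = NA)
    }
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      o0 <- overlap_len(chains$c0s[i], chains$c0e[i], chains$c0s[j], chains$c0e[j])
      o1 <- overlap_len(chains$c1s[i], chains$c1e[i], chains$c1s[j], chains$c1e[j])
      l0 <- min(chains$c0e[i] - chains$c0s[i], chains$c0e[j] - chains$c0s[j])
      l1 <- min(chains$c1e[i] - chains$c1s[i], chains$c1e[j] - chains$c1s[j])
      if (o0 / l0 > max_overlap && o1 / l1 > max_overlap)
        v[[length(v) + 1L]] <- data.frame(type = "pair_overlap",
                                          chain1 = chains$id[i],
                                          chain2 = chains$id[j])
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(type = character(), chain1 = integer(), chain2 = integer())
}

# build chain records from a list of anchor-index paths
paths_to_chains <- function(paths, graph) {
  if (length(paths) == 0L) {
    ch <- data.frame(id = integer(), seq = character(), sign = character(),
                     c0s = integer(), c0e = integer(), c1s = integer(),
                     c1e = integer(), cost = numeric(), n_anchors = integer(),
                     stringsAsFactors = FALSE)
    ch$anchors <- I(list())
    return(ch)
  }
  a <- graph$anchors
  ecost <- graph$edges
  key <- paste(ecost$from, ecost$to)
  emap <- stats::setNames(ecost$cost, key)
  rows <- lapply(seq_along(paths), function(ci) {
    p <- paths[[ci]]
    cost <- sum(graph$vcost[p])
    if (length(p) > 1L)
      cost <- cost + sum(emap[paste(p[-length(p)], p[-1L])])
    data.frame(id = ci,
               seq = a$seq[p[1L]],
               sign = a$sign[p[1L]],
               c0s = min(a$s0[p]), c0e = max(a$e0[p]),
               c1s = min(a$s1[p]), c1e = max(a$e1[p]),
               cost = cost, n_anchors = length(p),
               stringsAsFactors = FALSE)
  })
  ch <- do.call(rbind, rows)
  ch$anchors <- I(lapply(paths, function(p) a$id[p]))
  ch
}

#' Extract an optimal consistent chain set by min-cost flow
#'
#' Transforms the anchor DAG into a unit-capacity transportation network
#' (split vertices carrying the vertex cost, a source and a sink) and
#' augments flow one unit at a time along the cheapest residual path
#' (successive shortest paths with node potentials; the initial potentials
#' come from a topological relaxation of the acyclic base network). After
#' each augmentation the flow is decomposed into chains; the first flow
#' value whose chain set passes [check_chain_set()] is returned. At maximum
#' flow every chain is a single anchor, which is always consistent for a
#' deduplicated anchor set.
#'
#' @param graph a `ts_graph` from [build_anchor_graph()].
#' @param T maximum projection gap for the consistency test.
#' @param cross_axis,max_overlap passed to [check_chain_set()].
#' @return list: `chains` (data.frame), `residual_anchors` (ids of anchors
#'   in no chain), `flow` (final flow value), `flow_costs` (total cost per
#'   iteration).
#' @export
min_cost_flow_chains <- function(graph, T = 150000L, cross_axis = FALSE,
                                 max_overlap = 0.5) {
  a <- graph$anchors
  n <- nrow(a)
  if (n == 0L)
    return(list(chains = paths_to_chains(list(), graph)[0, ],
                residual_anchors = integer(0), flow = 0L,
                flow_costs = numeric(0)))
  ## nodes: 1..n = in, n+1..2n = out, src = 2n+1, snk = 2n+2
  src <- 2L * n + 1L; snk <- 2L * n + 2L; N <- snk
  ef <- c(rep.int(src, n), seq_len(n), n + seq_len(n), n + graph$edges$from)
  et <- c(seq_len(n), n + seq_len(n), rep.int(snk, n), graph$edges$to)
  ec <- c(rep(0, n), graph$vcost, rep(0, n), graph$edges$cost)
  m <- length(ef)
  flow <- integer(m)
  ## deterministic arc order: by from, then to
  o <- order(ef, et)
  ef <- ef[o]; et <- et[o]; ec <- ec[o]
  adj_out <- split(seq_len(m), factor(ef, levels = seq_len(N)))
  adj_in <- split(seq_len(m), factor(et, levels = seq_len(N)))

  ## initial potentials: shortest distance from src on the acyclic base
  ## network, relaxing nodes in topological order
  topo <- order((a$s0 + a$e0) / 2, seq_len(n))
  node_order <- c(src, as.integer(rbind(topo, n + topo)), snk)
  pot <- rep(Inf, N); pot[src] <- 0
  for (u in node_order) {
    if (!is.finite(pot[u])) next
    for (ai in adj_out[[u]]) {
      v <- et[ai]
      nd <- pot[u] + ec[ai]
      if (nd < pot[v]) pot[v] <- nd
    }
  }
  pot[!is.finite(pot)] <- 0

  decompose <- function() {
    paths <- list()
    for (ai in adj_out[[src]]) {
      if (flow[ai] == 0L) next
      p <- integer(0)
      u <- et[ai]
      repeat {
        if (u == snk) break
        if (u <= n) { p <- c(p, u); u <- u + n; next }
        nxt <- NA_integer_
        for (bi in adj_out[[u]]) if (flow[bi] == 1L) { nxt <- et[bi]; break }
        u <- nxt
      }
      paths[[length(paths) + 1L]] <- p
    }
    paths
  }

  flow_costs <- numeric(0)
  total_cost <- 0
  fval <- 0L
  result <- NULL
  repeat {
    ## Dijkstra on reduced costs in the residual network
    dist <- rep(Inf, N); dist[src] <- 0
    done <- rep(FALSE, N)
    pred_arc <- integer(N); pred_dir <- integer(N)
    repeat {
      d <- dist; d[done] <- Inf
      u <- which.min(d)
      if (!is.finite(d[u])) break
      done[u] <- TRUE
      if (u == snk) next
      for (ai in adj_out[[u]]) {
        if (flow[ai] == 1L) next
        v <- et[ai]
        rc <- max(0, ec[ai] + pot[u] - pot[v])
        if (dist[u] + rc < dist[v]) {
          dist[v] <- dist[u] + rc
          pred_arc[v] <- ai; pred_dir[v] <- 1L
        }
      }
      for (ai in adj_in[[u]]) {
        if (flow[ai] == 0L) next
        v <- ef[ai]
        rc <- max(0, -ec[ai] + pot[u] - pot[v])
        if (dist[u] + rc < dist[v]) {
          dist[v] <- dist[u] + rc
          pred_arc[v] <- ai; pred_dir[v] <- -1L
        }
      }
    }
    if (!is.finite(dist[snk])) break # maximum flow reached
    pot <- pot + ifelse(is.finite(dist), dist, dist[snk])
    ## augment one unit along the path
    v <- snk
    while (v != src) {
      ai <- pred_arc[v]
      if (pred_dir[v] == 1L) { flow[ai] <- 1L; v <- ef[ai] }
      else { flow[ai] <- 0L; v <- et[ai] }
    }
    fval <- fval + 1L
    paths <- decompose()
    chains <- paths_to_chains(paths, graph)
    total_cost <- sum(chains$cost)
    flow_costs <- c(flow_costs, total_cost)
    if (nrow(check_chain_set(chains, T, cross_axis, max_overlap)) == 0L) {
      result <- list(paths = paths, chains = chains)
      break
    }
  }
  if (is.null(result)) {
    paths <- decompose()
    result <- list(paths = paths,
                   chains = if (length(paths)) paths_to_chains(paths, graph)
                            else paths_to_chains(list(), graph)[0, ])
  }
  used <- unlist(result$paths)
  list(chains = result$chains,
       residual_anchors = setdiff(a$id, a$id[used]),
       flow = fval, flow_costs = flow_costs)
}
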