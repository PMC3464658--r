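# Shared fixtures and independent oracles, all built in code.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

mk_anchor <- function(id, s0, e0, s1, e1, sign = "+", score = 50L,
                      seq = "chr1") {
  data.frame(id = id, seq = seq, s0 = s0, e0 = e0, s1 = s1, e1 = e1,
             sign = sign, score = as.integer(score), stringsAsFactors = FALSE)
}

# random valid tandem anchor set on a small coordinate space
rand_anchor_set <- function(n, span = 10000L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    len0 <- sample(50:400, 1); len1 <- sample(50:400, 1)
    s0 <- sample.int(span - len0 - len1 - 10L, 1)
    gap <- sample(0:2000, 1)
    s1 <- s0 + len0 + gap
    if (s1 + len1 > span) s1 <- span - len1
    if (s1 < s0 + len0) return(NULL)
    mk_anchor(i, s0, s0 + len0, s1, s1 + len1,
              sign = sample(c("+", "-"), 1), score = sample(20:100, 1))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out$id <- seq_len(nrow(out))
  out
}

# all simple source-to-sink paths of the anchor graph (vertex index lists)
all_graph_paths <- function(graph) {
  n <- nrow(graph$anchors)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  paths <- list()
  grow <- function(p) {
    paths[[length(paths) + 1L]] <<- p
    for (v in adj[[p[length(p)]]]) grow(c(p, v))
  }
  for (v in seq_len(n)) grow(v)
  paths
}

path_cost <- function(p, graph) {
  cost <- sum(graph$vcost[p])
  if (length(p) > 1L) {
    key <- paste(graph$edges$from, graph$edges$to)
    emap <- setNames(graph$edges$cost, key)
    cost <- cost + sum(emap[paste(p[-length(p)], p[-1L])])
  }
  cost
}

# minimum total cost over all sets of exactly k vertex-disjoint paths;
# exhaustive branch-and-bound over the path list
best_disjoint_paths_cost <- function(graph, k) {
  paths <- all_graph_paths(graph)
  if (k == 0L) return(0)
  costs <- vapply(paths, path_cost, 0, graph = graph)
  o <- order(costs)
  paths <- paths[o]; costs <- costs[o]
  n <- nrow(graph$anchors)
  best <- Inf
  rec <- function(start, used, left, acc) {
    if (left == 0L) { if (acc < best) best <<- acc; return(invisible()) }
    if (start > length(paths)) return(invisible())
    ## bound: every remaining path costs at least costs[start]
    if (acc + left * costs[start] >= best) return(invisible())
    for (i in start:length(paths)) {
      p <- paths[[i]]
      if (any(used[p])) next
      u2 <- used; u2[p] <- TRUE
      rec(i + 1L, u2, left - 1L, acc + costs[i])
    }
    invisible()
  }
  rec(1L, rep(FALSE, n), k, 0)
  best
}

# brute-force per-base coverage recount
brute_coverage <- function(anchors, seq_length) {
  cv <- integer(seq_length)
  for (i in seq_len(nrow(anchors))) {
    for (iv in list(c(anchors$s0[i], anchors$e0[i]),
                    c(anchors$s1[i], anchors$e1[i]))) {
      idx <- (iv[1] + 1L):iv[2]
      cv[idx] <- cv[idx] + 1L
    }
  }
  cv
}

# plant copies of `block` into background at given starts (0-based)
plant_genome <- function(background, block, starts, revcomp = logical(length(starts))) {
  out <- background
  for (i in seq_along(starts)) {
    b <- if (revcomp[i]) tandemscan:::revcomp_chr(block) else block
    substr(out, starts[i] + 1L, starts[i] + nchar(b)) <- b
  }
  out
}
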