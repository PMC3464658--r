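## Final reconstruction: re-search each tandem array region with its
## reference duplication unit (translated six-frame search by default, a la
## TBLASTX), chain the hits on the unit axis (graph G3) and call the
## individual tandem units.

# BLOSUM62 and its alphabet, loaded once per session from Biostrings
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

aa_codes <- function(p) {
  ab <- rownames(blosum62())
  x <- match(strsplit(p, "")[[1]], ab) - 1L
  x[is.na(x)] <- match("X", ab) - 1L
  x
}

# three forward-frame translations of a nucleotide string
three_frames <- function(dna) {
  d <- Biostrings::DNAString(gsub("[^ACGTN]", "N", toupper(dna)))
  lapply(0:2, function(f) {
    len <- (length(d) - f) %/% 3L * 3L
    if (len < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(d, f + 1L, f + len),
                                       if.fuzzy.codon = "X"))
  })
}

# protein-level seeded alignment of one frame pair, mapped back to
# nucleotide coordinates of the original strings
align_frames <- function(pq, ps, fq, fs, qlen_nt, slen_nt, s_strand,
                         word_size, min_score) {
  if (nchar(pq) < word_size || nchar(ps) < word_size) return(NULL)
  qc <- aa_codes(pq); sc <- aa_codes(ps)
  h <- cpp_seed_extend(qc, sc, rep(TRUE, length(qc)), rep(TRUE, length(sc)),
                       blosum62(), 20L, -11L, -1L, as.integer(word_size),
                       20L, as.integer(min_score), FALSE, 30L, 100000L)
  if (nrow(h) == 0L) return(NULL)
  u_s <- fq + 3L * h$qs; u_e <- fq + 3L * h$qe
  if (s_strand == "+") {
    r_s <- fs + 3L * h$ss; r_e <- fs + 3L * h$se
  } else {
    r_s <- slen_nt - (fs + 3L * h$se); r_e <- slen_nt - (fs + 3L * h$ss)
  }
  data.frame(u_s = u_s, u_e = u_e, r_s = r_s, r_e = r_e,
             sign = if (s_strand == "+") "+" else "-",
             score = h$score, stringsAsFactors = FALSE)
}

#' Search an array region with its reference duplication unit
#'
#' Translated mode (default) six-frame-translates the unit (forward frames)
#' and the region (both strands), runs seeded BLOSUM62 local alignment on
#' every frame pair and maps hits back to nucleotide coordinates;
#' nucleotide mode reuses the DNA anchoring aligner; external mode invokes
#' a `tblastx` executable. All modes return hits in region-local
#' coordinates with the unit on the first axis.
#'
#' @param unit_residues reference unit sequence (character scalar).
#' @param region_residues array region sequence (character scalar).
#' @param mode `"translated"`, `"nucleotide"` or `"external"`.
#' @param scheme [scoring_scheme()] for nucleotide mode.
#' @param word_size protein seed length for translated mode.
#' @param min_score minimum hit score (protein score units in translated
#'   mode, DNA units otherwise).
#' @return hit data.frame (`u_s, u_e, r_s, r_e, sign, score`).
#' @export
search_unit <- function(unit_residues, region_residues,
                        mode = c("translated", "nucleotide", "external"),
                        scheme = scoring_scheme(), word_size = 3L,
                        min_score = 40L) {
  mode <- match.arg(mode)
  unit_residues <- toupper(unit_residues)
  region_residues0 <- region_residues
  region_residues <- toupper(region_residues)
  empty <- data.frame(u_s = integer(), u_e = integer(), r_s = integer(),
                      r_e = integer(), sign = character(), score = integer(),
                      stringsAsFactors = FALSE)
  if (mode == "nucleotide") {
    sm <- dna_matrix(scheme)
    qc <- seq_codes(unit_residues); rc_ <- seq_codes(region_residues)
    okq <- qc < 4L; okr <- rc_ < 4L
    plus <- cpp_seed_extend(qc, rc_, okq, okr, sm, 4L, scheme$gap_open,
                            scheme$gap_extend, scheme$seed_k, scheme$xdrop,
                            scheme$min_anchor_score, FALSE, 100L, 200000L)
    rr <- revcomp_chr(region_residues)
    rcc <- seq_codes(rr)
    minus <- cpp_seed_extend(qc, rcc, okq, rcc < 4L, sm, 4L, scheme$gap_open,
                             scheme$gap_extend, scheme$seed_k, scheme$xdrop,
                             scheme$min_anchor_score, FALSE, 100L, 200000L)
    n <- nchar(region_residues)
    out <- rbind(
      if (nrow(plus)) data.frame(u_s = plus$qs, u_e = plus$qe, r_s = plus$ss,
                                 r_e = plus$se, sign = "+", score = plus$score,
                                 stringsAsFactors = FALSE),
      if (nrow(minus)) data.frame(u_s = minus$qs, u_e = minus$qe,
                                  r_s = n - minus$se, r_e = n - minus$ss,
                                  sign = "-", score = minus$score,
                                  stringsAsFactors = FALSE))
    if (is.null(out)) out <- empty
  } else if (mode == "translated") {
    qf <- three_frames(unit_residues)
    sf_p <- three_frames(region_residues)
    sf_m <- three_frames(revcomp_chr(region_residues))
    ul <- nchar(unit_residues); rl <- nchar(region_residues)
    res <- list()
    for (fq in 0:2) for (fs in 0:2) {
      res[[length(res) + 1L]] <-
        align_frames(qf[[fq + 1L]], sf_p[[fs + 1L]], fq, fs, ul, rl, "+",
                     word_size, min_score)
      res[[length(res) + 1L]] <-
        align_frames(qf[[fq + 1L]], sf_m[[fs + 1L]], fq, fs, ul, rl, "-",
                     word_size, min_score)
    }
    res <- res[!vapply(res, is.null, TRUE)]
    out <- if (length(res)) do.call(rbind, res) else empty
  } else {
    if (Sys.which("tblastx") == "")
      stop("external mode requires a tblastx executable on PATH; ",
           "use mode = \"translated\" for the built-in search")
    qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
    on.exit(unlink(c(qf, sf)), add = TRUE)
    writeLines(c(">unit", unit_residues), qf)
    writeLines(c(">region", region_residues0), sf)
    cmd <- system2("tblastx",
                   c("-query", qf, "-subject", sf, "-outfmt",
                     shQuote("6 qstart qend sstart send score"),
                     "-evalue", "1e-3"),
                   stdout = TRUE)
    out <- empty
    if (length(cmd)) {
      f <- do.call(rbind, strsplit(cmd, "\t"))
      qs <- as.integer(f[, 1]); qe <- as.integer(f[, 2])
      ss <- as.integer(f[, 3]); se <- as.integer(f[, 4])
      sign <- ifelse(ss <= se, "+", "-")
      out <- data.frame(u_s = pmin(qs, qe) - 1L, u_e = pmax(qs, qe),
                        r_s = pmin(ss, se) - 1L, r_e = pmax(ss, se),
                        sign = sign, score = as.integer(round(as.numeric(f[, 5]))),
                        stringsAsFactors = FALSE)
    }
  }
  out <- out[out$u_e > out$u_s & out$r_e > out$r_s & out$score > 0, ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("u_s", "u_e", "r_s", "r_e", "sign")]), ,
             drop = FALSE]
  if (nrow(out)) out <- out[order(out$r_s, out$u_s, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract best chains by successive shortest-path extraction
#'
#' On the unit-vs-region hit DAG, repeatedly finds the minimum-cost
#' source-to-sink path (a chain; vertex costs are negative, so the best
#' chain absorbs as many colinear hits as possible), removes its vertices
#' and iterates while negative-cost chains remain. Because chains are
#' monotone on the unit axis, one extraction gathers the fragments of one
#' unit traversal (one copy); leftovers fall to the unit-coverage filter.
#'
#' @param graph a `ts_graph` built with `cross_axis = TRUE`.
#' @return chain data.frame as in [min_cost_flow_chains()].
#' @export
extract_best_chains <- function(graph) {
  a <- graph$anchors
  n <- nrow(a)
  if (n == 0L) return(paths_to_chains(list(), graph))
  topo <- order((a$s0 + a$e0) / 2, seq_len(n))
  ein <- split(seq_len(nrow(graph$edges)),
               factor(graph$edges$to, levels = seq_len(n)))
  alive <- rep(TRUE, n)
  paths <- list()
  repeat {
    dp <- rep(Inf, n); back <- integer(n)
    for (v in topo) {
      if (!alive[v]) next
      best <- 0; barc <- 0L # 0 = chain starts here
      for (ai in ein[[v]]) {
        u <- graph$edges$from[ai]
        if (!alive[u] || !is.finite(dp[u])) next
        c2 <- dp[u] + graph$edges$cost[ai]
        if (c2 < best) { best <- c2; barc <- u }
      }
      dp[v] <- graph$vcost[v] + best
      back[v] <- barc
    }
    v <- which.min(dp)
    if (!is.finite(dp[v]) || dp[v] >= 0) break
    p <- integer(0)
    while (v != 0L) { p <- c(v, p); v <- back[v] }
    paths[[length(paths) + 1L]] <- p
    alive[p] <- FALSE
    if (!any(alive)) break
  }
  paths_to_chains(paths, graph)
}

#' Chain unit hits into tandem units
#'
#' Builds a weighted hit DAG exactly as the anchor graph (same vertex and
#' edge costs, same successor relation, gap at most `L`) with the unit on
#' one axis, extracts chains by successive shortest-path extraction
#' ([extract_best_chains()]), and keeps a chain as a tandem unit
#' iff the union of its hits covers at least `min_unit_fraction` of the
#' unit and its region-axis span is at least `ell` long. Region-overlapping
#' units are resolved by trimming the lower-scoring one.
#'
#' @param hits hit data.frame from [search_unit()].
#' @param unit_length length of the reference unit (bases).
#' @param L maximum chaining gap (bases).
#' @param ell minimum unit length (bases).
#' @param min_unit_fraction minimum covered fraction of the unit.
#' @param k out-degree cap of the hit graph.
#' @return data.frame (`start, end, score, n_hits`) in region-local
#'   coordinates, sorted by start.
#' @export
chain_unit_hits <- function(hits, unit_length, L = 40000L, ell = 500L,
                            min_unit_fraction = 0.5, k = 15L) {
  empty <- data.frame(start = integer(), end = integer(), score = numeric(),
                      n_hits = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  ha <- data.frame(id = seq_len(nrow(hits)), seq = "region",
                   s0 = hits$u_s, e0 = hits$u_e,
                   s1 = hits$r_s, e1 = hits$r_e,
                   sign = hits$sign, score = hits$score,
                   stringsAsFactors = FALSE)
  g <- build_anchor_graph(ha, L = L, k = k, cross_axis = TRUE)
  ch <- extract_best_chains(g)
  if (nrow(ch) == 0L) return(empty)
  keep <- logical(nrow(ch))
  score <- numeric(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    ids <- ch$anchors[[i]]
    hh <- ha[ha$id %in% ids, , drop = FALSE]
    cov <- union_length(hh$s0, hh$e0) / unit_length
    score[i] <- sum(hh$score)
    keep[i] <- cov >= min_unit_fraction && (ch$c1e[i] - ch$c1s[i]) >= ell
  }
  tu <- data.frame(start = ch$c1s[keep], end = ch$c1e[keep],
                   score = score[keep], n_hits = ch$n_anchors[keep],
                   stringsAsFactors = FALSE)
  if (nrow(tu) <= 1L) {
    tu <- tu[order(tu$start), , drop = FALSE]; rownames(tu) <- NULL
    return(tu)
  }
  ## enforce pairwise region non-overlap: trim the lower-scoring unit
  o <- order(-tu$score, tu$start)
  kept <- list()
  for (i in o) {
    s <- tu$start[i]; e <- tu$end[i]
    for (kk in kept) {
      if (s < kk$end && kk$start < e) {
        if (kk$start <= s) s <- max(s, kk$end) else e <- min(e, kk$start)
      }
    }
    if (e - s >= ell)
      kept[[length(kept) + 1L]] <- list(start = s, end = e,
                                        score = tu$score[i],
                                        n_hits = tu$n_hits[i])
  }
  tu <- do.call(rbind, lapply(kept, as.data.frame))
  tu <- tu[order(tu$start), , drop = FALSE]
  rownames(tu) <- NULL
  tu
}

#' Enlarge tandem units within their array
#'
#' Each unit is extended by up to `max_fraction` of its own length on each
#' side, staying inside the array region and never overlapping a
#' neighbouring unit: when two adjacent units both want more than the gap
#' between them, each takes half the gap.
#'
#' @param units data.frame (`start, end, ...`) of one array, region-local,
#'   non-overlapping.
#' @param max_fraction maximum per-side extension as a fraction of the unit
#'   length (default 0.25).
#' @param region_length length of the array region.
#' @return the units with adjusted `start`/`end` and a logical `enlarged`
#'   column.
#' @export
enlarge_units <- function(units, max_fraction = 0.25, region_length) {
  n <- nrow(units)
  if (n == 0L) { units$enlarged <- logical(0); return(units) }
  units <- units[order(units$start), , drop = FALSE]
  want <- floor(max_fraction * (units$end - units$start))
  ns <- units$start; ne <- units$end
  for (i in seq_len(n)) {
    gl <- if (i == 1L) units$start[i] else units$start[i] - ne[i - 1L]
    take_l <- if (i == 1L) min(want[i], gl) else {
      if (want[i] + want[i - 1L] <= units$start[i] - units$end[i - 1L])
        want[i]
      else min(want[i], (units$start[i] - units$end[i - 1L]) %/% 2L)
    }
    gr <- if (i == n) region_length - units$end[i]
          else units$start[i + 1L] - units$end[i]
    take_r <- if (i == n) min(want[i], gr) else {
      if (want[i] + want[i + 1L] <= gr) want[i]
      else min(want[i], gr %/% 2L)
    }
    ns[i] <- units$start[i] - max(0L, take_l)
    ne[i] <- units$end[i] + max(0L, take_r)
  }
  out <- units
  out$enlarged <- ns < units$start | ne > units$end
  out$start <- as.integer(ns); out$end <- as.integer(ne)
  rownames(out) <- NULL
  out
}
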