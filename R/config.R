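#' Alignment scoring scheme
#'
#' Defaults follow the standard DNA self-alignment scheme used for tandem
#' anchor detection: match +1, mismatch -3, gap open -5, gap extend -2.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores (match > 0,
#'   the others < 0).
#' @param min_anchor_score minimum local alignment score to report.
#' @param seed_k exact seed length for the seed-and-extend aligner.
#' @param xdrop X-drop termination threshold for gapped extension.
#' @return a list of class `ts_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L,
                           min_anchor_score = 30L, seed_k = 12L,
                           xdrop = 20L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            min_anchor_score > 0, seed_k >= 4L, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_anchor_score = as.integer(min_anchor_score),
                 seed_k = as.integer(seed_k), xdrop = as.integer(xdrop)),
            class = "ts_scheme")
}

# 5x5 DNA substitution matrix (A C G T N); N behaves as a mismatch
dna_matrix <- function(scheme) {
  m <- matrix(scheme$mismatch, 5L, 5L)
  diag(m) <- scheme$match
  m[5L, ] <- scheme$mismatch; m[, 5L] <- scheme$mismatch
  storage.mode(m) <- "integer"
  m
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the detection pipeline. The three
#' structural parameters are the minimum duplication unit length `ell`
#' (500 bp), the maximum distance `T` between the two copies of a tandem
#' duplication (150 kb) and the maximum chaining gap / array extension
#' margin `L` (40 kb).
#'
#' @param ell minimum duplication/tandem unit length (bases).
#' @param T maximum gap between the two copies of an anchor or chain (bases).
#' @param L maximum gap between chained anchors; also the margin added to
#'   each side of a tandem array region (bases).
#' @param k maximum out-degree kept per vertex in the anchor graph.
#' @param scheme a [scoring_scheme()].
#' @param min_overlap minimum fractional overlap (of the smaller interval)
#'   connecting two chains/anchors in the array overlap graph.
#' @param min_unit_fraction minimum fraction of the reference unit a chain
#'   of hits must cover to be called a tandem unit.
#' @param detect_threshold overlap fraction used by the evaluation layer.
#' @param max_enlarge maximum fractional enlargement of a tandem unit per
#'   side during final reconstruction.
#' @param max_mutual_overlap anchor dedup threshold: pairs overlapping more
#'   than this on both projections are reduced to the better anchor.
#' @param dust_window,dust_threshold low-complexity masking parameters.
#' @param search_mode re-search mode for reconstruction: `"translated"`
#'   (six-frame, BLOSUM62), `"nucleotide"`, or `"external"` (tblastx binary).
#' @param mask whether to DUST-mask the genome before anchoring.
#' @param seed integer seed for the (simulation-only) random components.
#' @return a list of class `ts_config`.
#' @export
tandem_config <- function(ell = 500L, T = 150000L, L = 40000L, k = 15L,
                          scheme = scoring_scheme(),
                          min_overlap = 0.5, min_unit_fraction = 0.5,
                          detect_threshold = 0.70, max_enlarge = 0.25,
                          max_mutual_overlap = 0.5,
                          dust_window = 64L, dust_threshold = 20L,
                          search_mode = c("translated", "nucleotide",
                                          "external"),
                          mask = TRUE, seed = 1L) {
  search_mode <- match.arg(search_mode)
  stopifnot(ell > 0, T > 0, L > 0, L <= T, k >= 1,
            min_overlap > 0, min_overlap <= 1,
            min_unit_fraction > 0, min_unit_fraction <= 1,
            detect_threshold > 0, detect_threshold <= 1,
            max_enlarge >= 0, inherits(scheme, "ts_scheme"))
  structure(list(ell = as.integer(ell), T = as.integer(T), L = as.integer(L),
                 k = as.integer(k), scheme = scheme,
                 min_overlap = min_overlap,
                 min_unit_fraction = min_unit_fraction,
                 detect_threshold = detect_threshold,
                 max_enlarge = max_enlarge,
                 max_mutual_overlap = max_mutual_overlap,
                 dust_window = as.integer(dust_window),
                 dust_threshold = as.integer(dust_threshold),
                 search_mode = search_mode, mask = isTRUE(mask),
                 seed = as.integer(seed)),
            class = "ts_config")
}

#' Read a plain key=value configuration file
#'
#' Unknown keys are an error; values are coerced to the type of the
#' corresponding [tandem_config()] (or [scoring_scheme()]) default.
#'
#' @param path config file; lines `key = value`, `#` comments.
#' @param base config to override (default [tandem_config()]).
#' @return a `ts_config`.
#' @export
read_config <- function(path, base = tandem_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0L) return(base)
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) stop("malformed config line in ", path)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  sch <- as.list(base$scheme)
  cfg <- unclass(base)
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% names(sch)) {
      sch[[k]] <- as.integer(v)
    } else if (k %in% names(cfg) && k != "scheme") {
      cur <- cfg[[k]]
      cfg[[k]] <- if (is.integer(cur)) as.integer(v)
                  else if (is.numeric(cur)) as.numeric(v)
                  else if (is.logical(cur)) as.logical(v)
                  else v
    } else stop("unknown config key: ", k)
  }
  cfg$scheme <- do.call(scoring_scheme, sch)
  do.call(tandem_config, cfg[setdiff(names(cfg), character(0))])
}
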