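## Evaluation against an annotation-derived truth set: reference tandem
## gene arrays (TGA) built from protein-level paralogy between nearby
## genes, and the 70% overlap detection criteria.

DETECT_FRACTION <- 0.70 # shared detection threshold (TGU >=, TGA strictly >)

# for each query interval, the maximum fraction of it covered by a single
# target interval (same sequence)
max_single_cov <- function(qseq, qs, qe, tseq, ts, te) {
  n <- length(qs)
  out <- numeric(n)
  if (n == 0L || length(ts) == 0L) return(out)
  for (i in seq_len(n)) {
    sel <- tseq == qseq[i]
    if (!any(sel)) next
    ov <- overlap_len(qs[i], qe[i], ts[sel], te[sel])
    out[i] <- max(ov) / (qe[i] - qs[i])
  }
  out
}

#' Read gene records from a GFF3 annotation
#'
#' Keeps features of type `gene` longer than `min_length`; when transcript
#' features (`mRNA`/`transcript`) are present the longest one per gene is
#' recorded as the reference transcript.
#'
#' @param path GFF3 file.
#' @param min_length genes at most this long are discarded (default 500,
#'   strict).
#' @return data.frame (`gene_id, seq, start, end, reference_transcript`),
#'   0-based half-open.
#' @export
read_gene_records <- function(path, min_length = 500L) {
  gr <- rtracklayer::import(path)
  ty <- as.character(gr$type)
  g <- gr[ty == "gene"]
  if (length(g) == 0L) stop("no gene features in ", path)
  ids <- if (!is.null(g$ID)) as.character(g$ID) else
    sprintf("gene%d", seq_along(g))
  tx <- gr[ty %in% c("mRNA", "transcript")]
  ref_tx <- rep(NA_character_, length(g))
  if (length(tx) && !is.null(tx$Parent)) {
    par <- vapply(tx$Parent, function(p) if (length(p)) p[[1]] else NA, "")
    w <- GenomicRanges::width(tx)
    for (i in seq_along(g)) {
      sel <- which(par == ids[i])
      if (length(sel)) {
        tid <- if (!is.null(tx$ID)) as.character(tx$ID[sel]) else
          sprintf("tx%d", sel)
        ref_tx[i] <- tid[which.max(w[sel])]
      }
    }
  }
  out <- data.frame(gene_id = ids,
                    seq = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g) - 1L,
                    end = GenomicRanges::end(g),
                    reference_transcript = ref_tx,
                    stringsAsFactors = FALSE)
  out <- out[out$end - out$start > min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build reference tandem gene arrays from protein paralogy
#'
#' Two genes are linked iff they hit each other with e-value at most 1e-5,
#' coverage at least 0.70 of both proteins, and lie less than `T` apart on
#' the same sequence. Connected components with at least two genes become
#' reference tandem gene arrays (TGAs); their member genes are the tandem
#' gene units (TGUs).
#'
#' @param genes data.frame (`gene_id, seq, start, end`).
#' @param hits data.frame (`query, subject, evalue, qcov, scov`).
#' @param T maximum gene separation (strict, bases).
#' @param max_evalue,min_coverage linkage thresholds.
#' @return data.frame (`tga_id, seq, start, end, n_genes`) with list column
#'   `gene_ids`.
#' @export
build_reference_tgas <- function(genes, hits, T = 150000L,
                                 max_evalue = 1e-5, min_coverage = 0.70) {
  unknown <- setdiff(c(hits$query, hits$subject), genes$gene_id)
  if (length(unknown))
    stop("hits reference unknown genes: ", paste(unknown, collapse = ", "))
  idx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  qi <- idx[hits$query]; si <- idx[hits$subject]
  ok <- hits$evalue <= max_evalue & hits$qcov >= min_coverage &
        hits$scov >= min_coverage & qi != si &
        genes$seq[qi] == genes$seq[si]
  gap <- pmax(0L, pmax(genes$start[qi], genes$start[si]) -
                   pmin(genes$end[qi], genes$end[si]))
  ok <- ok & gap < T
  g <- igraph::make_empty_graph(n = nrow(genes), directed = FALSE)
  if (any(ok))
    g <- igraph::add_edges(g, as.vector(rbind(qi[ok], si[ok])))
  comp <- igraph::components(g)$membership
  empty <- data.frame(tga_id = character(), seq = character(),
                      start = integer(), end = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  empty$gene_ids <- I(list())
  rows <- list()
  for (cid in sort(unique(comp))) {
    m <- which(comp == cid)
    if (length(m) < 2L) next
    rows[[length(rows) + 1L]] <- list(
      seq = genes$seq[m[1]], start = as.integer(min(genes$start[m])),
      end = as.integer(max(genes$end[m])), n_genes = length(m),
      gene_ids = genes$gene_id[m])
  }
  if (!length(rows)) return(empty)
  df <- data.frame(seq = vapply(rows, `[[`, "", "seq"),
                   start = vapply(rows, `[[`, 0L, "start"),
                   end = vapply(rows, `[[`, 0L, "end"),
                   n_genes = vapply(rows, `[[`, 0L, "n_genes"),
                   stringsAsFactors = FALSE)
  df$gene_ids <- I(lapply(rows, `[[`, "gene_ids"))
  df <- df[order(df$seq, df$start), , drop = FALSE]
  df <- cbind(tga_id = sprintf("tga%d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Score predicted arrays/units against the reference TGAs
#'
#' A TGU (member gene) is detected when a single predicted tandem unit
#' covers at least 70% of it; a TGA is detected when a predicted tandem
#' array covers strictly more than 70% of its span *and* at least one of
#' its TGUs is detected.
#'
#' @param tgas output of [build_reference_tgas()].
#' @param genes the gene data.frame the TGAs were built from.
#' @param arrays predicted tandem array data.frame.
#' @param units predicted tandem unit data.frame.
#' @return list: `summary` (rows TGA/TGU: total, detected, pct),
#'   `tga_detected`, `tgu_detected` (logical vectors).
#' @export
score_detection <- function(tgas, genes, arrays, units) {
  gsel <- genes$gene_id %in% unlist(tgas$gene_ids)
  tgu <- genes[gsel, , drop = FALSE]
  tgu_cov <- max_single_cov(tgu$seq, tgu$start, tgu$end,
                            units$seq, units$start, units$end)
  tgu_det <- tgu_cov >= DETECT_FRACTION
  names(tgu_det) <- tgu$gene_id
  tga_det <- logical(nrow(tgas))
  if (nrow(tgas)) {
    span_cov <- max_single_cov(tgas$seq, tgas$start, tgas$end,
                               arrays$seq, arrays$start, arrays$end)
    for (i in seq_len(nrow(tgas))) {
      member_det <- tgu_det[tgas$gene_ids[[i]]]
      tga_det[i] <- span_cov[i] > DETECT_FRACTION && any(member_det)
    }
  }
  summary <- data.frame(
    class = c("TGA", "TGU"),
    total = c(nrow(tgas), nrow(tgu)),
    detected = c(sum(tga_det), sum(tgu_det)),
    stringsAsFactors = FALSE)
  summary$pct <- ifelse(summary$total > 0,
                        round(100 * summary$detected / summary$total, 1), NA)
  list(summary = summary, tga_detected = tga_det, tgu_detected = tgu_det)
}

#' Per-class annotation overlap of predicted tandem units
#'
#' A feature counts as detected when a single tandem unit covers at least
#' 70% of it.
#'
#' @param units predicted tandem unit data.frame.
#' @param features data.frame (`class, seq, start, end`).
#' @return data.frame (`class, total, detected, pct`).
#' @export
annotation_overlap_report <- function(units, features) {
  cls <- unique(features$class)
  rows <- lapply(cls, function(cl) {
    f <- features[features$class == cl, , drop = FALSE]
    cov <- max_single_cov(f$seq, f$start, f$end,
                          units$seq, units$start, units$end)
    det <- sum(cov >= DETECT_FRACTION)
    data.frame(class = cl, total = nrow(f), detected = det,
               pct = round(100 * det / nrow(f), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Orphan statistics of predicted arrays
#'
#' A tandem unit is an orphan when it neither covers (at least 70% of the
#' feature) nor is covered by (at least 70% of the unit) any annotated
#' feature; a tandem array is an orphan when it does not contain a single
#' non-orphan unit.
#'
#' @param arrays,units predicted arrays and units.
#' @param features annotation data.frame (`class, seq, start, end`).
#' @return data.frame with rows `orphan`/`other`: `n_tas, n_tus,
#'   mean_tu_size, mean_tu_per_ta`.
#' @export
orphan_stats <- function(arrays, units, features) {
  cov_feat <- covered <- logical(nrow(units))
  tu_orphan <- rep(TRUE, nrow(units))
  if (nrow(units) && nrow(features)) {
    for (i in seq_len(nrow(units))) {
      sel <- features$seq == units$seq[i]
      if (!any(sel)) next
      ov <- overlap_len(units$start[i], units$end[i],
                        features$start[sel], features$end[sel])
      covers <- ov / (features$end[sel] - features$start[sel]) >=
        DETECT_FRACTION
      is_cov <- ov / (units$end[i] - units$start[i]) >= DETECT_FRACTION
      tu_orphan[i] <- !any(covers | is_cov)
    }
  }
  ta_orphan <- vapply(seq_len(nrow(arrays)), function(i) {
    sel <- units$array_id == arrays$array_id[i]
    !any(!tu_orphan[sel])
  }, TRUE)
  mk <- function(sel_ta, sel_tu) {
    data.frame(n_tas = sum(sel_ta), n_tus = sum(sel_tu),
               mean_tu_size = if (any(sel_tu))
                 round(mean(units$end[sel_tu] - units$start[sel_tu]), 1)
                 else NA,
               mean_tu_per_ta = if (any(sel_ta))
                 round(sum(sel_tu) / sum(sel_ta), 2) else NA)
  }
  tu_in_orphan_ta <- units$array_id %in% arrays$array_id[ta_orphan]
  out <- rbind(cbind(group = "orphan", mk(ta_orphan, tu_in_orphan_ta)),
               cbind(group = "other", mk(!ta_orphan, !tu_in_orphan_ta)))
  rownames(out) <- NULL
  out
}
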