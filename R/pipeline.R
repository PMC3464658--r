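## Pipeline orchestration: anchors -> chains -> arrays -> reconstruction,
## with every intermediate serialized and a run manifest of parameters and
## per-stage counts.

#' Write / read the chain table
#'
#' Tab-separated: chain id, sequence, sign, both projections (1-based
#' inclusive), cost, number of anchors and comma-joined member anchor ids.
#'
#' @param chains chain data.frame.
#' @param path file path.
#' @export
write_chain_table <- function(chains, path) {
  hdr <- "#id\tseq\tsign\tc0_start\tc0_end\tc1_start\tc1_end\tcost\tn_anchors\tanchors"
  if (nrow(chains) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  lines <- sprintf("%d\t%s\t%s\t%d\t%d\t%d\t%d\t%.6g\t%d\t%s",
                   chains$id, chains$seq, chains$sign,
                   chains$c0s + 1L, chains$c0e, chains$c1s + 1L, chains$c1e,
                   chains$cost, chains$n_anchors,
                   vapply(chains$anchors, paste, "", collapse = ","))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_chain_table
#' @export
read_chain_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(id = integer(), seq = character(), sign = character(),
                      c0s = integer(), c0e = integer(), c1s = integer(),
                      c1e = integer(), cost = numeric(), n_anchors = integer(),
                      stringsAsFactors = FALSE)
  empty$anchors <- I(list())
  if (!length(lines)) return(empty)
  p <- do.call(rbind, strsplit(lines, "\t"))
  out <- data.frame(id = as.integer(p[, 1]), seq = p[, 2], sign = p[, 3],
                    c0s = as.integer(p[, 4]) - 1L, c0e = as.integer(p[, 5]),
                    c1s = as.integer(p[, 6]) - 1L, c1e = as.integer(p[, 7]),
                    cost = as.numeric(p[, 8]), n_anchors = as.integer(p[, 9]),
                    stringsAsFactors = FALSE)
  out$anchors <- I(lapply(strsplit(p[, 10], ","), as.integer))
  out
}

# detect one sequence: anchors through tandem units (region-local stages)
detect_sequence <- function(seq, seq_name, config) {
  sch <- config$scheme
  masked <- if (config$mask)
    mask_low_complexity(seq, config$dust_window, config$dust_threshold)
  else seq
  anchors <- find_anchors(masked, sch, config$T, seq_name)
  n_raw <- nrow(anchors)
  anchors <- dedupe_anchors(anchors, config$max_mutual_overlap)
  graph <- build_anchor_graph(anchors, L = config$L, k = config$k,
                              seq_length = nchar(seq))
  fl <- min_cost_flow_chains(graph, T = config$T,
                             max_overlap = config$max_mutual_overlap)
  chains <- fl$chains
  residual <- anchors[anchors$id %in% fl$residual_anchors, , drop = FALSE]
  og <- build_overlap_graph(chains, residual, config$min_overlap)
  slen <- stats::setNames(nchar(seq), seq_name)
  arrays <- delineate_arrays(og, L = config$L, seq_lengths = slen)
  units <- list()
  keep <- logical(nrow(arrays))
  unit_info <- vector("list", nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    u <- select_reference_unit(arrays[i, ], chains, anchors, seq,
                               scheme = sch, ell = config$ell)
    if (is.null(u)) next
    keep[i] <- TRUE
    region <- toupper(substr(seq, arrays$start[i] + 1L, arrays$end[i]))
    hits <- search_unit(u$residues, region, mode = config$search_mode,
                        scheme = sch)
    tus <- chain_unit_hits(hits, nchar(u$residues), L = config$L,
                           ell = config$ell,
                           min_unit_fraction = config$min_unit_fraction,
                           k = config$k)
    tus <- enlarge_units(tus, config$max_enlarge,
                         region_length = arrays$end[i] - arrays$start[i])
    u$flag <- if (nrow(tus) == 0L) "unit_only" else u$flag
    unit_info[[i]] <- u
    if (nrow(tus))
      units[[length(units) + 1L]] <- data.frame(
        local_key = paste0(seq_name, ":", i), seq = seq_name,
        start = arrays$start[i] + tus$start,
        end = arrays$start[i] + tus$end,
        score = tus$score, n_hits = tus$n_hits, enlarged = tus$enlarged,
        stringsAsFactors = FALSE)
  }
  arrays$local_key <- paste0(seq_name, ":", seq_len(nrow(arrays)))
  arrays$unit_start <- vapply(unit_info, function(u)
    if (is.null(u)) NA_integer_ else as.integer(u$start), 0L)
  arrays$unit_end <- vapply(unit_info, function(u)
    if (is.null(u)) NA_integer_ else as.integer(u$end), 0L)
  arrays$unit_flag <- vapply(unit_info, function(u)
    if (is.null(u)) NA_character_ else u$flag, "")
  arrays <- arrays[keep, , drop = FALSE]
  units <- if (length(units)) do.call(rbind, units) else
    data.frame(local_key = character(), seq = character(), start = integer(),
               end = integer(), score = numeric(), n_hits = integer(),
               enlarged = logical(), stringsAsFactors = FALSE)
  list(anchors = anchors, n_raw_anchors = n_raw, chains = chains,
       residual = residual, arrays = arrays, units = units,
       unit_info = unit_info[keep])
}

#' Run the full tandem duplication detection pipeline
#'
#' Executes anchor detection, chaining, array delineation and final
#' reconstruction on every sequence of a genome, writes all intermediate
#' artifacts to `out_dir` and returns the results with a run manifest.
#'
#' @param genome a named character vector of sequences or a FASTA path.
#' @param config a [tandem_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return list: `anchors`, `chains`, `arrays`, `units`, `manifest`.
#' @export
run_pipeline <- function(genome, config = tandem_config(), out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (!length(genome) || any(!nzchar(genome)))
    stop("stage anchors failed: empty genome")
  if (is.null(names(genome)))
    names(genome) <- sprintf("seq%d", seq_along(genome))
  res <- lapply(names(genome), function(nm)
    detect_sequence(genome[[nm]], nm, config))
  ## merge per-sequence results with global ids
  anchors <- do.call(rbind, c(lapply(res, `[[`, "anchors"),
                              list(make.row.names = FALSE)))
  chains <- do.call(rbind, c(lapply(res, `[[`, "chains"),
                             list(make.row.names = FALSE)))
  arrays <- do.call(rbind, c(lapply(res, `[[`, "arrays"),
                             list(make.row.names = FALSE)))
  units <- do.call(rbind, c(lapply(res, `[[`, "units"),
                            list(make.row.names = FALSE)))
  unit_info <- do.call(c, lapply(res, `[[`, "unit_info"))
  if (nrow(arrays)) {
    o <- order(arrays$seq, arrays$start)
    arrays <- arrays[o, , drop = FALSE]
    unit_info <- unit_info[o]
    arrays$array_id <- sprintf("ta%d", seq_len(nrow(arrays)))
  }
  ## remap unit rows to the renumbered arrays
  if (nrow(units)) {
    units$array_id <- arrays$array_id[match(units$local_key,
                                            arrays$local_key)]
    units <- units[order(units$seq, units$start), , drop = FALSE]
    units$tu_id <- sprintf("tu%d", seq_len(nrow(units)))
    units <- units[, c("tu_id", "array_id", "seq", "start", "end", "score",
                       "n_hits", "enlarged")]
  } else {
    units <- data.frame(tu_id = character(), array_id = character(),
                        seq = character(), start = integer(), end = integer(),
                        score = numeric(), n_hits = integer(),
                        enlarged = logical(), stringsAsFactors = FALSE)
  }
  arrays$local_key <- NULL
  rownames(arrays) <- rownames(units) <- NULL
  glen <- sum(nchar(genome))
  manifest <- list(
    tool = "tandemscan",
    version = as.character(utils::packageVersion("tandemscan")),
    config = config_echo(config),
    counts = list(
      n_sequences = length(genome),
      genome_length = glen,
      n_raw_anchors = sum(vapply(res, `[[`, 0L, "n_raw_anchors")),
      n_anchors = nrow(anchors),
      n_chains = nrow(chains),
      mean_anchors_per_chain = if (nrow(chains))
        round(mean(chains$n_anchors), 2) else 0,
      n_tandem_arrays = nrow(arrays),
      n_tandem_units = nrow(units),
      ta_genome_fraction = if (nrow(arrays))
        round(sum(vapply(split(seq_len(nrow(arrays)), arrays$seq), function(ii)
          union_length(arrays$start[ii], arrays$end[ii]), 0L)) / glen, 4)
        else 0,
      tu_genome_fraction = if (nrow(units))
        round(sum(vapply(split(seq_len(nrow(units)), units$seq), function(ii)
          union_length(units$start[ii], units$end[ii]), 0L)) / glen, 4)
        else 0))
  out <- list(anchors = anchors, chains = chains, arrays = arrays,
              units = units, unit_info = unit_info, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

config_echo <- function(config) {
  c(unclass(config)[setdiff(names(config), "scheme")],
    as.list(config$scheme))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_anchor_table(out$anchors, file.path(out_dir, "anchors.tsv"))
  write_chain_table(out$chains, file.path(out_dir, "chains.tsv"))
  write_features(out$arrays, out$units, file.path(out_dir, "tandem.gff3"),
                 "gff3")
  write_features(out$arrays, out$units, file.path(out_dir, "tandem.bed"),
                 "bed")
  if (length(out$unit_info)) {
    fa <- stats::setNames(vapply(out$unit_info, `[[`, "", "residues"),
                          sprintf("%s_unit", out$arrays$array_id))
    write_fasta(fa, file.path(out_dir, "units.fa"))
  } else writeLines(character(0), file.path(out_dir, "units.fa"))
  ## per-array summary: region, number of TUs, mean TU size
  s <- out$arrays
  ntu <- vapply(seq_len(nrow(s)), function(i)
    sum(out$units$array_id == s$array_id[i]), 0L)
  mean_tu <- vapply(seq_len(nrow(s)), function(i) {
    sel <- out$units$array_id == s$array_id[i]
    if (any(sel)) round(mean(out$units$end[sel] - out$units$start[sel]), 1)
    else NA_real_
  }, 0)
  hdr <- "#array_id\tseq\tstart\tend\tn_tus\tmean_tu_size"
  lines <- if (nrow(s)) sprintf("%s\t%s\t%d\t%d\t%d\t%s", s$array_id, s$seq,
                                s$start, s$end, ntu, ifelse(is.na(mean_tu),
                                                            "NA", mean_tu))
           else character(0)
  writeLines(c(hdr, lines), file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
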