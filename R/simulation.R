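## Synthetic genomes with planted tandem arrays: ground truth for every
## other module. Background is i.i.d. at a plant-like GC; each array is a
## drawn unit replicated with substitutions, geometric indels and optional
## inversion, copies separated by short spacers.

#' Simulation parameters
#'
#' Defaults describe the calibration setting used throughout the package:
#' a 300 kb genome carrying 8 arrays of 2-6 copies of a 600-3000 bp unit at
#' 3% substitutions and 0.5% indels.
#'
#' @param genome_length total genome length (bases).
#' @param n_arrays number of planted tandem arrays.
#' @param unit_length_range min/max unit length (bases).
#' @param copies_range min/max copies per array.
#' @param spacer_range min/max spacer between consecutive copies (bases);
#'   `unit_length_range[2] + spacer_range[2]` must stay below `T`.
#' @param substitution_rate per-base substitution probability per copy.
#' @param indel_rate per-base indel initiation probability per copy.
#' @param indel_length_geometric_p geometric length parameter of indels
#'   (lengths capped at 50 bp).
#' @param inversion_prob per-copy probability of reverse-complementing.
#' @param gc_content background GC fraction.
#' @param n_decoys decoy genes placed in the background by
#'   [simulate_annotation()].
#' @param seed integer seed fixing all randomness.
#' @return list of class `ts_sim_params`.
#' @export
sim_params <- function(genome_length = 300000L, n_arrays = 8L,
                       unit_length_range = c(600L, 3000L),
                       copies_range = c(2L, 6L),
                       spacer_range = c(50L, 2000L),
                       substitution_rate = 0.03, indel_rate = 0.005,
                       indel_length_geometric_p = 0.7,
                       inversion_prob = 0, gc_content = 0.36,
                       n_decoys = 5L, seed = 1L) {
  stopifnot(genome_length > 0, n_arrays >= 0,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            inversion_prob >= 0, inversion_prob <= 1,
            gc_content > 0, gc_content < 1,
            unit_length_range[1] <= unit_length_range[2],
            copies_range[1] >= 2L, copies_range[1] <= copies_range[2],
            spacer_range[1] >= 0, spacer_range[1] <= spacer_range[2])
  structure(as.list(environment()), class = "ts_sim_params")
}

rand_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# mutate one copy of a unit; returns the mutated string and the realised
# substitution divergence
mutate_copy <- function(unit, sub_rate, indel_rate, geom_p, cap = 50L) {
  x <- strsplit(unit, "")[[1]]
  n <- length(x)
  nsub <- stats::rbinom(1L, n, sub_rate)
  if (nsub > 0L) {
    pos <- sample.int(n, nsub)
    for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
  }
  nind <- stats::rbinom(1L, n, indel_rate)
  if (nind > 0L) {
    pos <- sort(sample.int(n, nind), decreasing = TRUE)
    for (p in pos) {
      len <- min(cap, stats::rgeom(1L, geom_p) + 1L)
      if (stats::runif(1L) < 0.5) { # deletion
        x <- x[-(p:min(n, p + len - 1L))]
      } else {                       # insertion
        ins <- sample(c("A", "C", "G", "T"), len, TRUE)
        x <- append(x, ins, after = p)
      }
      n <- length(x)
    }
  }
  list(seq = paste(x, collapse = ""), divergence = nsub / nchar(unit))
}

#' Simulate a genome with planted tandem arrays
#'
#' @param params a [sim_params()].
#' @return list: `genome` (named character vector of one sequence `chr1`)
#'   and `truth` (data.frame: `array_id, copy, seq, start, end, inverted,
#'   divergence`, 0-based half-open final coordinates).
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "ts_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    ## draw array structures first so we know the space they take
    arrays <- lapply(seq_len(p$n_arrays), function(ai) {
      ulen <- sample(p$unit_length_range[1]:p$unit_length_range[2], 1L)
      ncp <- sample(p$copies_range[1]:p$copies_range[2], 1L)
      unit <- rand_dna(ulen, p$gc_content)
      copies <- lapply(seq_len(ncp), function(ci) {
        m <- mutate_copy(unit, p$substitution_rate, p$indel_rate,
                         p$indel_length_geometric_p)
        m$inverted <- stats::runif(1L) < p$inversion_prob
        if (m$inverted) m$seq <- revcomp_chr(m$seq)
        m
      })
      spacers <- if (ncp > 1L)
        vapply(seq_len(ncp - 1L), function(i)
          rand_dna(sample(p$spacer_range[1]:p$spacer_range[2], 1L),
                   p$gc_content), "")
      else character(0)
      list(unit = unit, copies = copies, spacers = spacers)
    })
    alens <- vapply(arrays, function(a) {
      sum(nchar(vapply(a$copies, `[[`, "", "seq"))) + sum(nchar(a$spacers))
    }, 0)
    free <- p$genome_length - sum(alens)
    min_gap <- 1000L
    if (free < (p$n_arrays + 1L) * min_gap)
      stop("arrays cannot fit in the requested genome length")
    ## split the free background into n_arrays + 1 gaps of >= min_gap
    ng <- p$n_arrays + 1L
    extra <- free - ng * min_gap
    cuts <- sort(sample.int(extra + 1L, ng - 1L, replace = TRUE) - 1L)
    gaps <- min_gap + diff(c(0L, cuts, extra))
    parts <- character(0)
    truth <- list()
    pos <- 0L
    for (ai in seq_len(p$n_arrays)) {
      bg <- rand_dna(gaps[ai], p$gc_content)
      parts <- c(parts, bg); pos <- pos + nchar(bg)
      a <- arrays[[ai]]
      for (ci in seq_along(a$copies)) {
        cp <- a$copies[[ci]]
        parts <- c(parts, cp$seq)
        truth[[length(truth) + 1L]] <- data.frame(
          array_id = ai, copy = ci, seq = "chr1",
          start = pos, end = pos + nchar(cp$seq),
          inverted = cp$inverted, divergence = cp$divergence,
          unit_length = nchar(a$unit), stringsAsFactors = FALSE)
        pos <- pos + nchar(cp$seq)
        if (ci < length(a$copies)) {
          parts <- c(parts, a$spacers[ci])
          pos <- pos + nchar(a$spacers[ci])
        }
      }
    }
    bg <- rand_dna(gaps[ng], p$gc_content)
    parts <- c(parts, bg)
    genome <- c(chr1 = paste(parts, collapse = ""))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(array_id = integer(), copy = integer(), seq = character(),
                 start = integer(), end = integer(), inverted = logical(),
                 divergence = numeric(), unit_length = integer(),
                 stringsAsFactors = FALSE)
    list(genome = genome, truth = truth)
  })
}

#' Simulate an annotation and protein-hit table for the truth set
#'
#' Each planted copy becomes a "gene"; decoy genes are placed in the
#' background and get no hits. Copies of the same array hit each other with
#' e-value 1e-10 and coverages drawn in [0.7, 1], so the reference
#' tandem-gene-array construction recovers exactly the planted arrays.
#'
#' @param sim output of [simulate_genome()].
#' @param params the same [sim_params()].
#' @return list: `genes` (`gene_id, seq, start, end, class`), `hits`
#'   (`query, subject, evalue, qcov, scov`).
#' @export
simulate_annotation <- function(sim, params) {
  truth <- sim$truth
  glen <- nchar(sim$genome[[1]])
  withr::with_seed(params$seed + 1L, {
    genes <- data.frame(
      gene_id = sprintf("g_a%d_c%d", truth$array_id, truth$copy),
      seq = truth$seq, start = truth$start, end = truth$end,
      class = "gene", stringsAsFactors = FALSE)
    ## decoys in background, away from any planted copy
    occ <- truth[, c("start", "end")]
    dec <- list()
    tries <- 0L
    while (length(dec) < params$n_decoys && tries < 1000L) {
      tries <- tries + 1L
      st <- sample.int(max(1L, glen - 1100L), 1L) - 1L
      en <- st + 1000L
      if (en > glen) next
      if (nrow(occ) && any(pmin(occ$end, en) - pmax(occ$start, st) > 0L)) next
      dec[[length(dec) + 1L]] <- c(st, en)
      occ <- rbind(occ, data.frame(start = st, end = en))
    }
    if (length(dec)) {
      dd <- do.call(rbind, dec)
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("decoy%d", seq_along(dec)),
        seq = "chr1", start = dd[, 1], end = dd[, 2], class = "gene",
        stringsAsFactors = FALSE))
    }
    hits <- list()
    for (ai in unique(truth$array_id)) {
      ids <- genes$gene_id[seq_len(nrow(truth))][truth$array_id == ai]
      if (length(ids) < 2L) next
      prs <- utils::combn(ids, 2L)
      hits[[length(hits) + 1L]] <- data.frame(
        query = prs[1, ], subject = prs[2, ], evalue = 1e-10,
        qcov = stats::runif(ncol(prs), 0.7, 1),
        scov = stats::runif(ncol(prs), 0.7, 1), stringsAsFactors = FALSE)
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(query = character(), subject = character(),
                 evalue = numeric(), qcov = numeric(), scov = numeric(),
                 stringsAsFactors = FALSE)
    list(genes = genes, hits = hits)
  })
}

#' Write simulated genes as GFF3
#'
#' @param genes gene data.frame from [simulate_annotation()].
#' @param path output file.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                   genes$seq, genes$class, genes$start + 1L, genes$end,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a protein hit table
#'
#' @param hits hit data.frame (`query, subject, evalue, qcov, scov`).
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  hdr <- "#query\tsubject\tevalue\tqcov\tscov"
  lines <- sprintf("%s\t%s\t%g\t%.4f\t%.4f", hits$query, hits$subject,
                   hits$evalue, hits$qcov, hits$scov)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a protein hit table
#'
#' @param path tab-separated file with columns query, subject, evalue,
#'   qcov, scov (`#` header).
#' @return hit data.frame.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("query", "subject", "evalue",
                                        "qcov", "scov"),
                          stringsAsFactors = FALSE)
  df
}
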