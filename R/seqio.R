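## Sequence and feature I/O. Genomes are held as named character vectors of
## residues over {A,C,G,T,N} with lowercase marking soft-masked positions.

.enc_table <- local({
  t <- rep(4L, 256)
  up <- utf8ToInt("ACGT"); lo <- utf8ToInt("acgt")
  t[up + 1L] <- 0:3; t[lo + 1L] <- 0:3
  t
})

# integer codes 0..3 = ACGT (case-insensitive), 4 = N/other
seq_codes <- function(s) .enc_table[utf8ToInt(s) + 1L]

# TRUE where the residue is lowercase (soft-masked)
seq_mask <- function(s) {
  x <- utf8ToInt(s)
  x >= 97L & x <= 122L
}

.rc_table <- local({
  t <- seq_len(256) - 1L
  from <- utf8ToInt("ACGTacgtNn")
  to   <- utf8ToInt("TGCAtgcaNn")
  t[from + 1L] <- to
  t
})

# reverse complement preserving case (soft-masking)
revcomp_chr <- function(s) {
  intToUtf8(rev(.rc_table[utf8ToInt(s) + 1L]))
}

#' Read a (multi-)FASTA genome
#'
#' Residues outside `{A,C,G,T,N}` (either case) are mapped to `N`; a warning
#' reports how many were replaced. Lowercase (soft-masked) residues are kept.
#'
#' @param path FASTA file.
#' @return named character vector of sequences; attribute `n_replaced` holds
#'   the count of normalised residues.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  seqs <- as.character(ss)
  names(seqs) <- nm
  n_replaced <- 0L
  for (i in seq_along(seqs)) {
    x <- utf8ToInt(seqs[[i]])
    bad <- .enc_table[x + 1L] == 4L & !(x %in% utf8ToInt("NnNn"))
    if (any(bad)) {
      low <- x >= 97L & x <= 122L
      x[bad] <- ifelse(low[bad], utf8ToInt("n"), utf8ToInt("N"))
      seqs[[i]] <- intToUtf8(x)
      n_replaced <- n_replaced + sum(bad)
    }
  }
  if (n_replaced > 0L)
    warning(n_replaced, " non-ACGTN residues replaced by N")
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in ", path)
  attr(seqs, "n_replaced") <- n_replaced
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Soft-mask low-complexity regions (DUST)
#'
#' Slides a window over the sequence, scores triplet over-representation
#' (`10 * sum c_t (c_t-1)/2 / (L-1)` over the window's `L` triplet slots) and
#' lowercases every position of windows whose score exceeds `threshold`.
#' Masked positions are skipped when seeding anchors but keep their
#' coordinates.
#'
#' @param seq a single sequence (character scalar).
#' @param window window size in bases (>= 3), default 64.
#' @param threshold score threshold, default 20.
#' @return the sequence with low-complexity positions lowercased.
#' @export
mask_low_complexity <- function(seq, window = 64L, threshold = 20L) {
  stopifnot(window >= 3L)
  codes <- seq_codes(seq)
  m <- cpp_dust_mask(codes, as.integer(window), as.integer(threshold))
  if (!any(m)) return(seq)
  x <- utf8ToInt(seq)
  up <- m & x >= 65L & x <= 90L
  x[up] <- x[up] + 32L
  intToUtf8(x)
}

#' Read an anchor table
#'
#' Tab-separated, one anchor per line: seq_name, a0_start, a0_end, a1_start,
#' a1_end, sign (+|-), score; 1-based inclusive on disk; lines starting with
#' `#` are comments. Anchors are normalised so the lower-coordinate copy
#' comes first; anchors whose two intervals overlap or lie more than `T`
#' apart are dropped (count in attribute `n_dropped`).
#'
#' @param path file path.
#' @param T maximum gap between the two copies of an anchor (bases).
#' @return anchor data.frame (`id, seq, s0, e0, s1, e1, sign, score`),
#'   0-based half-open.
#' @export
read_anchor_table <- function(path, T = 150000L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !startsWith(trimws(lines), "#")
  body <- lines[keep]
  if (length(body) == 0L) return(empty_anchors())
  parts <- strsplit(body, "[\t ]+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("malformed anchor line ", which(keep)[bad[1]], " in ", path)
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.integer))
  num <- matrix(num, ncol = 4L)
  score <- suppressWarnings(as.integer(m[, 7]))
  if (any(is.na(num)) || any(is.na(score)))
    stop("malformed anchor line ", which(keep)[which(is.na(num %% 1))[1]],
         " in ", path)
  a <- data.frame(seq = m[, 1],
                  s0 = num[, 1] - 1L, e0 = num[, 2],
                  s1 = num[, 3] - 1L, e1 = num[, 4],
                  sign = m[, 6], score = score,
                  stringsAsFactors = FALSE)
  if (!all(a$sign %in% c("+", "-"))) stop("invalid sign in ", path)
  if (any(a$s0 < 0L | a$e0 <= a$s0 | a$s1 < 0L | a$e1 <= a$s1))
    stop("invalid interval coordinates in ", path)
  # normalise: interval with the smaller start first
  swap <- a$s1 < a$s0
  if (any(swap)) {
    tmp <- a[swap, c("s0", "e0")]
    a[swap, c("s0", "e0")] <- a[swap, c("s1", "e1")]
    a[swap, c("s1", "e1")] <- tmp
  }
  n0 <- nrow(a)
  ok <- a$e0 <= a$s1 & (a$s1 - a$e0) <= T & a$score > 0L
  a <- a[ok, , drop = FALSE]
  a$id <- seq_len(nrow(a))
  rownames(a) <- NULL
  a <- a[, c("id", "seq", "s0", "e0", "s1", "e1", "sign", "score")]
  attr(a, "n_dropped") <- n0 - nrow(a)
  if (n0 > nrow(a))
    message(n0 - nrow(a), " anchors dropped at load (overlap or gap > T)")
  a
}

empty_anchors <- function() {
  data.frame(id = integer(), seq = character(),
             s0 = integer(), e0 = integer(),
             s1 = integer(), e1 = integer(),
             sign = character(), score = integer(),
             stringsAsFactors = FALSE)
}

#' Write an anchor table
#'
#' @param anchors anchor data.frame (0-based half-open).
#' @param path output file.
#' @export
write_anchor_table <- function(anchors, path) {
  hdr <- "#seq\ta0_start\ta0_end\ta1_start\ta1_end\tsign\tscore"
  if (nrow(anchors) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%d",
                   anchors$seq, anchors$s0 + 1L, anchors$e0,
                   anchors$s1 + 1L, anchors$e1, anchors$sign, anchors$score)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write tandem arrays and units as GFF3 or BED
#'
#' GFF3 output is 1-based inclusive with feature types `tandem_array` and
#' `tandem_unit` (units carry a `Parent` attribute); BED6 is 0-based
#' half-open with the array id as name and the score clipped to
#' `[0, 1000]`. Features are sorted by (seq, start).
#'
#' @param arrays tandem array data.frame.
#' @param units tandem unit data.frame.
#' @param path output file.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_features <- function(arrays, units, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  feats <- rbind(
    if (nrow(arrays)) data.frame(seq = arrays$seq, start = arrays$start,
                                 end = arrays$end, type = "tandem_array",
                                 id = arrays$array_id, parent = NA_character_,
                                 score = 0, stringsAsFactors = FALSE),
    if (nrow(units)) data.frame(seq = units$seq, start = units$start,
                                end = units$end, type = "tandem_unit",
                                id = units$tu_id, parent = units$array_id,
                                score = units$score, stringsAsFactors = FALSE))
  if (is.null(feats) || nrow(feats) == 0L) {
    writeLines(if (format == "gff3") "##gff-version 3" else character(0), path)
    return(invisible(path))
  }
  feats <- feats[order(feats$seq, feats$start,
                       match(feats$type, c("tandem_array", "tandem_unit"))), ]
  if (format == "gff3") {
    attrs <- ifelse(is.na(feats$parent),
                    sprintf("ID=%s", feats$id),
                    sprintf("ID=%s;Parent=%s", feats$id, feats$parent))
    lines <- sprintf("%s\ttandemscan\t%s\t%d\t%d\t%s\t.\t.\t%s",
                     feats$seq, feats$type, feats$start + 1L, feats$end,
                     format(feats$score, trim = TRUE), attrs)
    writeLines(c("##gff-version 3", lines), path)
  } else {
    name <- ifelse(is.na(feats$parent), feats$id, feats$parent)
    sc <- pmin(pmax(round(feats$score), 0), 1000)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                     feats$seq, feats$start, feats$end, name, as.integer(sc))
    writeLines(lines, path)
  }
  invisible(path)
}
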