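# Interval arithmetic helpers on BED-style (0-based, half-open) tables,
# backed by IRanges. All conversions to the 1-based closed IRanges
# convention happen here and nowhere else.

as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

# For each query interval: does it overlap (>= 1 bp) any subject interval?
interval_overlaps_any <- function(qchrom, qstart, qend,
                                  schrom, sstart, send) {
  out <- logical(length(qchrom))
  for (ch in unique(qchrom)) {
    qi <- which(qchrom == ch)
    si <- which(schrom == ch)
    if (!length(si)) next
    hits <- IRanges::overlapsAny(as_iranges0(qstart[qi], qend[qi]),
                                 as_iranges0(sstart[si], send[si]))
    out[qi] <- hits
  }
  out
}

# For each query interval: number of overlapping subject intervals.
interval_count_overlaps <- function(qchrom, qstart, qend,
                                    schrom, sstart, send) {
  out <- integer(length(qchrom))
  for (ch in unique(qchrom)) {
    qi <- which(qchrom == ch)
    si <- which(schrom == ch)
    if (!length(si)) next
    out[qi] <- IRanges::countOverlaps(as_iranges0(qstart[qi], qend[qi]),
                                      as_iranges0(sstart[si], send[si]))
  }
  out
}

# For each query interval: total bp covered by the union of the subjects.
interval_covered_bp <- function(qchrom, qstart, qend,
                                schrom, sstart, send) {
  out <- numeric(length(qchrom))
  for (ch in unique(qchrom)) {
    qi <- which(qchrom == ch)
    si <- which(schrom == ch)
    if (!length(si)) next
    q <- as_iranges0(qstart[qi], qend[qi])
    s <- IRanges::reduce(as_iranges0(sstart[si], send[si]))
    hits <- IRanges::findOverlaps(q, s)
    ov <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                              s[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out[qi[as.integer(names(w))]] <- as.numeric(w)
  }
  out
}

# Union (merge) of intervals; returns a sorted data.frame(chrom, start, end).
interval_union <- function(chrom, start, end) {
  res <- lapply(sort(unique(chrom)), function(ch) {
    i <- chrom == ch
    r <- IRanges::reduce(as_iranges0(start[i], end[i]))
    data.frame(chrom = ch, start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write BED-style interval tables
#'
#' Writes chrom/start/end plus any extra columns, tab-separated, no header —
#' readable by any BED-aware tool.
#' @param df data.frame with at least chrom, start, end.
#' @param path output path.
#' @param extra_cols further columns to append after the first three.
#' @export
write_bed <- function(df, path, extra_cols = setdiff(names(df),
                                                     c("chrom", "start", "end"))) {
  out <- df[, c("chrom", "start", "end", extra_cols), drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-style file
#' @param path input path.
#' @param col_names names for the columns beyond chrom/start/end.
#' @export
read_bed <- function(path, col_names = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  extra <- if (!is.null(col_names)) col_names
           else if (ncol(df) > 3) paste0("V", seq_len(ncol(df) - 3)) else NULL
  names(df) <- c(base, extra)[seq_len(ncol(df))]
  df
}
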