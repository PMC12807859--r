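#' Create a genome view
#'
#' A genome view is an ordered, non-overlapping partition of (part of) a
#' genome into named regions, typically chromosome arms. All per-region
#' computations (expected profiles, eigenvectors, insulation, pileups) are
#' performed within view regions. Coordinates are 0-based, half-open
#' (BED convention) throughout the package.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` and optionally `name`.
#' @param start,end integer-like region bounds in bp (half-open).
#' @param name optional region names; defaults to `chrom:start-end`.
#' @return a `genome_view` data.frame with columns chrom, start, end, name.
#' @export
genome_view <- function(chrom, start = NULL, end = NULL, name = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    if (is.null(df$name)) df$name <- paste0(df$chrom, ":", df$start, "-", df$end)
  } else {
    if (is.null(name)) name <- paste0(chrom, ":", start, "-", end)
    df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                     end = as.numeric(end), name = as.character(name),
                     stringsAsFactors = FALSE)
  }
  df <- df[, c("chrom", "start", "end", "name")]
  df$chrom <- as.character(df$chrom)
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start)) stop("view regions must have end > start")
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("view regions overlap on ", ch)
  }
  class(df) <- c("genome_view", "data.frame")
  df
}

#' Whole-chromosome view from chromosome sizes
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @return a [genome_view()] with one region per chromosome.
#' @export
view_from_sizes <- function(chrom_sizes) {
  genome_view(names(chrom_sizes), 0, as.numeric(chrom_sizes), names(chrom_sizes))
}

#' Assign matrix bins to view regions
#'
#' @param view a [genome_view()].
#' @param bins bin table (chrom, start, end).
#' @param require_cover error if some bin is not covered by any region.
#' @return integer vector: region index (row of `view`) per bin, NA if
#'   uncovered.
#' @export
view_assign_bins <- function(view, bins, require_cover = TRUE) {
  idx <- rep(NA_integer_, nrow(bins))
  for (r in seq_len(nrow(view))) {
    hit <- bins$chrom == view$chrom[r] &
      bins$start >= view$start[r] & bins$start < view$end[r]
    if (any(!is.na(idx[hit])))
      stop("bin assigned to more than one view region")
    idx[hit] <- r
  }
  if (require_cover && anyNA(idx))
    stop("some bins are not covered by the view")
  idx
}

#' Read / write a view as 4-column TSV (chrom, start, end, name)
#' @param path file path.
#' @return [genome_view()] for the reader; invisibly the path for the writer.
#' @export
read_view <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric", "character"))
  genome_view(df)
}

#' @rdname read_view
#' @param view a [genome_view()] to write.
#' @export
write_view <- function(view, path) {
  utils::write.table(as.data.frame(view)[, c("chrom", "start", "end", "name")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
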