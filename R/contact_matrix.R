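#' Binned contact matrix
#'
#' Sparse symmetric binned contact counts stored as an upper-triangle pixel
#' table, the substrate of all downstream analyses. Bin ids are global,
#' 0-based, ordered by chromosome then start. Balancing weights live in the
#' bin table (`weight`, NA for masked bins) and are absent until
#' [balance_ic()] has been run.
#'
#' @param bins data.frame with columns chrom, start, end (fixed width except
#'   possibly terminal bins per chromosome) and optionally weight.
#' @param pixels data.frame with columns bin1_id, bin2_id (0-based,
#'   bin1_id <= bin2_id) and count (non-negative).
#' @param resolution bin width in bp.
#' @return a `contact_matrix` object (list with bins, pixels, resolution).
#' @export
contact_matrix <- function(bins, pixels, resolution) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)),
            all(c("bin1_id", "bin2_id", "count") %in% names(pixels)))
  bins <- as.data.frame(bins)
  bins$chrom <- as.character(bins$chrom)
  if (is.null(bins$weight)) bins$weight <- NA_real_
  pixels <- as.data.frame(pixels)[, c("bin1_id", "bin2_id", "count")]
  if (nrow(pixels)) {
    flip <- pixels$bin1_id > pixels$bin2_id
    if (any(flip)) {
      tmp <- pixels$bin1_id[flip]
      pixels$bin1_id[flip] <- pixels$bin2_id[flip]
      pixels$bin2_id[flip] <- tmp
    }
    if (any(pixels$count < 0)) stop("counts must be non-negative")
    if (max(pixels$bin2_id) >= nrow(bins)) stop("pixel bin id out of range")
    pixels <- pixels[order(pixels$bin1_id, pixels$bin2_id), , drop = FALSE]
    rownames(pixels) <- NULL
  }
  obj <- list(bins = bins, pixels = pixels, resolution = as.numeric(resolution))
  class(obj) <- "contact_matrix"
  obj
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins @ %g bp, %d pixels, %s\n",
              nrow(x$bins), x$resolution, nrow(x$pixels),
              if (is_balanced(x)) "balanced" else "unbalanced"))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param m a [contact_matrix()].
#' @export
n_bins <- function(m) nrow(m$bins)

#' Is the matrix balanced (weights present)?
#' @param m a [contact_matrix()].
#' @export
is_balanced <- function(m) !all(is.na(m$bins$weight))

#' Bin table for a genome binned at fixed resolution
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param resolution bin width in bp.
#' @return data.frame (chrom, start, end) with global 0-based implicit ids.
#' @export
make_bins <- function(chrom_sizes, resolution) {
  out <- lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Balanced pixel values
#'
#' Multiplies raw counts by the per-bin weights; pixels touching masked bins
#' get NA.
#' @param m a balanced [contact_matrix()].
#' @return numeric vector aligned with `m$pixels`.
#' @export
balanced_values <- function(m) {
  if (!is_balanced(m)) stop("weights required")
  w <- m$bins$weight
  m$pixels$count * w[m$pixels$bin1_id + 1L] * w[m$pixels$bin2_id + 1L]
}

# 0-based first-bin offset of each chromosome, named by chromosome
chrom_offsets <- function(bins) {
  rle_ch <- rle(bins$chrom)
  off <- cumsum(c(0L, rle_ch$lengths))
  stats::setNames(off[-length(off)], rle_ch$values)
}

#' Read / write the plain-text triplet format
#'
#' The on-disk format is two TSV files: `<prefix>.bins.tsv` with header
#' `chrom start end weight` (weight column written as `NA` when unbalanced or
#' masked) and `<prefix>.pixels.tsv` with header `bin1_id bin2_id count`
#' (0-based upper-triangle ids). This mirrors a single-resolution cooler
#' dump bit-exactly for integer counts.
#'
#' @param prefix path prefix for the two files.
#' @param resolution bin width in bp (reader infers it from the bin table
#'   when omitted).
#' @return the [contact_matrix()] for the reader.
#' @export
read_contacts <- function(prefix, resolution = NULL) {
  bins <- utils::read.table(paste0(prefix, ".bins.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  px <- utils::read.table(paste0(prefix, ".pixels.tsv"), header = TRUE,
                          sep = "\t")
  if (is.null(resolution)) resolution <- max(bins$end - bins$start)
  contact_matrix(bins, px, resolution)
}

#' @rdname read_contacts
#' @param m a [contact_matrix()] to write.
#' @export
write_contacts <- function(m, prefix) {
  utils::write.table(m$bins[, c("chrom", "start", "end", "weight")],
                     paste0(prefix, ".bins.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$pixels, paste0(prefix, ".pixels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

# Dense symmetric matrix of balanced values for a bin-id range [lo, hi]
# (0-based, inclusive). Masked rows/cols are NA. Used region-wise; never
# materializes the genome-wide map.
dense_balanced_block <- function(m, lo, hi) {
  n <- hi - lo + 1L
  w <- m$bins$weight
  px <- m$pixels
  sel <- px$bin1_id >= lo & px$bin2_id <= hi
  px <- px[sel, , drop = FALSE]
  out <- matrix(0, n, n)
  if (nrow(px)) {
    i <- px$bin1_id - lo + 1L
    j <- px$bin2_id - lo + 1L
    v <- px$count * w[px$bin1_id + 1L] * w[px$bin2_id + 1L]
    out[cbind(i, j)] <- v
    out[cbind(j, i)] <- v
  }
  bad <- is.na(w[(lo:hi) + 1L])
  out[bad, ] <- NA_real_
  out[, bad] <- NA_real_
  out
}
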