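#' All-pairs grid over MCD anchors
#'
#' Projects all unordered pairs of anchors into a pair table: cis pairs
#' within one view region (summit-to-summit separation within bounds),
#' trans pairs across chromosomes. Pairs spanning two regions of the same
#' chromosome are excluded (no expected model there).
#'
#' @param anchors anchor table (chrom, start, end, summit).
#' @param view a [genome_view()].
#' @param min_sep,max_sep separation bounds for cis pairs (bp,
#'   summit-to-summit; defaults 0 and Inf).
#' @return a `pair_grid` data.frame: chrom1, pos1, chrom2, pos2 (summits,
#'   genome order), kind ("cis"/"trans"), separation (bp, NA for trans)
#'   plus anchor indices a1, a2.
#' @export
make_pairwise_grid <- function(anchors, view, min_sep = 0, max_sep = Inf) {
  n <- nrow(anchors)
  if (n < 2)
    return(structure(data.frame(chrom1 = character(0), pos1 = numeric(0),
                                chrom2 = character(0), pos2 = numeric(0),
                                kind = character(0), separation = numeric(0),
                                a1 = integer(0), a2 = integer(0)),
                     class = c("pair_grid", "data.frame")))
  reg <- rep(NA_integer_, n)
  for (r in seq_len(nrow(view))) {
    hit <- anchors$chrom == view$chrom[r] &
      anchors$summit >= view$start[r] & anchors$summit < view$end[r]
    reg[hit] <- r
  }
  ord <- order(anchors$chrom, anchors$summit)
  idx <- t(utils::combn(ord, 2))
  i <- idx[, 1]; j <- idx[, 2]
  same_chrom <- anchors$chrom[i] == anchors$chrom[j]
  sep <- abs(anchors$summit[j] - anchors$summit[i])
  kind <- ifelse(same_chrom, "cis", "trans")
  keep <- (!same_chrom) |
    (reg[i] == reg[j] & !is.na(reg[i]) & sep >= min_sep & sep <= max_sep & sep > 0)
  i <- i[keep]; j <- j[keep]; kind <- kind[keep]; sep <- sep[keep]
  out <- data.frame(chrom1 = anchors$chrom[i], pos1 = anchors$summit[i],
                    chrom2 = anchors$chrom[j], pos2 = anchors$summit[j],
                    kind = kind,
                    separation = ifelse(kind == "cis", sep, NA_real_),
                    a1 = i, a2 = j, stringsAsFactors = FALSE)
  # genome order within pair rows
  flip <- out$chrom1 == out$chrom2 & out$pos1 > out$pos2
  if (any(flip)) {
    tmp <- out[flip, c("chrom1", "pos1", "a1")]
    out[flip, c("chrom1", "pos1", "a1")] <- out[flip, c("chrom2", "pos2", "a2")]
    out[flip, c("chrom2", "pos2", "a2")] <- tmp
  }
  rownames(out) <- NULL
  class(out) <- c("pair_grid", "data.frame")
  out
}

# dense O/E block between two view regions (r1 may equal r2); list(mat, lo1,
# lo2). Full symmetric values for cis; trans block as stored orientation.
oe_dense_pair <- function(oe, r1, r2) {
  if (r1 == r2) {
    mat <- oe_dense_region(oe, r1)
    return(list(mat = mat, lo1 = attr(mat, "lo"), lo2 = attr(mat, "lo")))
  }
  ids1 <- which(oe$region == r1) - 1L
  ids2 <- which(oe$region == r2) - 1L
  lo1 <- min(ids1); hi1 <- max(ids1)
  lo2 <- min(ids2); hi2 <- max(ids2)
  px <- oe$pixels
  sel <- px$bin1_id >= lo1 & px$bin1_id <= hi1 &
    px$bin2_id >= lo2 & px$bin2_id <= hi2
  mat <- matrix(0, hi1 - lo1 + 1L, hi2 - lo2 + 1L)
  mat[cbind(px$bin1_id[sel] - lo1 + 1L, px$bin2_id[sel] - lo2 + 1L)] <- px$oe[sel]
  # pixels stored with bin1 in r2 (when r2 precedes r1 in bin order)
  sel2 <- px$bin1_id >= lo2 & px$bin1_id <= hi2 &
    px$bin2_id >= lo1 & px$bin2_id <= hi1
  if (any(sel2))
    mat[cbind(px$bin2_id[sel2] - lo1 + 1L, px$bin1_id[sel2] - lo2 + 1L)] <- px$oe[sel2]
  bad1 <- is.na(oe$bins$weight[(lo1:hi1) + 1L])
  bad2 <- is.na(oe$bins$weight[(lo2:hi2) + 1L])
  mat[bad1, ] <- NA; mat[, bad2] <- NA
  list(mat = mat, lo1 = lo1, lo2 = lo2)
}

#' Aggregate snippet pileup over 2D features
#'
#' Extracts, for every feature pair, the observed/expected sub-matrix
#' centred on the pair with a fixed flank, and averages the stack with
#' NaN-ignoring means (cells beyond the region edge are missing). Features
#' may be grouped; each group is then averaged separately.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @param features a [make_pairwise_grid()] table or any data.frame with
#'   chrom1, pos1, chrom2, pos2 (bp point coordinates, e.g. loop anchors).
#' @param flank flank size (bp) on each side of the centre pixel.
#' @param groups optional factor (length nrow(features)) for grouped
#'   pileups.
#' @return a `pileup` (list mat, n_snippets, flank, resolution), or a named
#'   list of pileups when `groups` is given.
#' @export
aggregate_pileup <- function(oe, features, flank = 100e3, groups = NULL) {
  res <- oe$resolution
  h <- round(flank / res)
  side <- 2L * h + 1L
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(features))
    gs <- split(seq_len(nrow(features)), groups)
    return(lapply(gs, function(idx)
      aggregate_pileup(oe, features[idx, , drop = FALSE], flank = flank)))
  }
  offs <- chrom_offsets(oe$bins)
  # region of each feature side
  bin1 <- offs[features$chrom1] + floor(features$pos1 / res)
  bin2 <- offs[features$chrom2] + floor(features$pos2 / res)
  r1 <- oe$region[bin1 + 1L]
  r2 <- oe$region[bin2 + 1L]
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  n_used <- 0L
  for (key in unique(paste(r1, r2))) {
    sel <- which(paste(r1, r2) == key)
    rr <- c(r1[sel[1]], r2[sel[1]])
    if (anyNA(rr)) next
    blk <- oe_dense_pair(oe, rr[1], rr[2])
    nr <- nrow(blk$mat); nc <- ncol(blk$mat)
    for (f in sel) {
      ci <- bin1[f] - blk$lo1 + 1L
      cj <- bin2[f] - blk$lo2 + 1L
      ii <- (ci - h):(ci + h)
      jj <- (cj - h):(cj + h)
      oki <- ii >= 1 & ii <= nr
      okj <- jj >= 1 & jj <= nc
      snip <- matrix(NA_real_, side, side)
      snip[oki, okj] <- blk$mat[ii[oki], jj[okj], drop = FALSE]
      if (all(is.na(snip))) next
      good <- !is.na(snip)
      acc[good] <- acc[good] + snip[good]
      cnt <- cnt + good
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("zero usable snippets")
  structure(list(mat = ifelse(cnt > 0, acc / cnt, NA_real_),
                 n_snippets = n_used, flank = flank, resolution = res),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %dx%d @ %g bp, %d snippets, centre %.3f\n",
              nrow(x$mat), ncol(x$mat), x$resolution, x$n_snippets,
              x$mat[(nrow(x$mat) + 1) / 2, (ncol(x$mat) + 1) / 2]))
  invisible(x)
}

# centre/corner window sizes (kb) per quantification mode
strength_windows <- function(mode) {
  switch(mode,
         cis_grid = c(centre = 50e3, corner = 60e3),
         trans_grid = c(centre = 25e3, corner = 50e3),
         loop = c(centre = 30e3, corner = 70e3),
         stop("unknown strength mode: ", mode))
}

#' Centre-over-periphery strength of a pileup
#'
#' Quantifies a pileup as the ratio of the mean over a centred window to
#' the mean over four corner windows flush with the pileup's corners. The
#' window sizes follow the quantification scheme of the method: 50 kb
#' centre with 60 kb corners for the cis MCD grid (10 kb maps), a single
#' 25 kb centre pixel with 50 kb corners for the trans grid (25 kb maps),
#' and 30 kb centre with 70 kb corners for loops.
#'
#' @param pileup a [aggregate_pileup()] result.
#' @param mode one of "cis_grid", "trans_grid", "loop".
#' @return strength (numeric scalar).
#' @export
feature_strength <- function(pileup, mode = c("cis_grid", "trans_grid", "loop")) {
  mode <- match.arg(mode)
  w <- strength_windows(mode)
  res <- pileup$resolution
  cb <- w[["centre"]] / res
  kb <- w[["corner"]] / res
  if (abs(cb - round(cb)) > 1e-9 || abs(kb - round(kb)) > 1e-9)
    stop("window sizes are not whole bins at this resolution")
  cb <- as.integer(round(cb)); kb <- as.integer(round(kb))
  if (cb %% 2L != 1L)
    stop("centre window must span an odd number of bins at this resolution")
  side <- nrow(pileup$mat)
  mid <- (side + 1L) %/% 2L
  ch <- (cb - 1L) %/% 2L
  centre_idx <- (mid - ch):(mid + ch)
  if (kb >= mid - ch)
    stop("corner windows would overlap the centre window")
  corner_idx <- list(lo = 1:kb, hi = (side - kb + 1L):side)
  centre_mean <- mean(pileup$mat[centre_idx, centre_idx], na.rm = TRUE)
  corners <- c(pileup$mat[corner_idx$lo, corner_idx$lo],
               pileup$mat[corner_idx$lo, corner_idx$hi],
               pileup$mat[corner_idx$hi, corner_idx$lo],
               pileup$mat[corner_idx$hi, corner_idx$hi])
  periph <- mean(corners, na.rm = TRUE)
  if (!is.finite(periph) || periph == 0) stop("degenerate periphery")
  as.numeric(centre_mean / periph)
}

#' 1D signal stackup over centred intervals
#'
#' Extracts a coverage signal around the centre of each interval
#' (centre +/- flank), aggregates every window into `n_bins` equal bins
#' (bp-weighted means; bases not covered by the track count as 0), and
#' returns the per-row matrix with its NaN-ignoring column-mean profile.
#' Window parts beyond the chromosome (or below 0) are missing.
#'
#' @param track coverage data.frame (chrom, start, end, value), bedGraph
#'   semantics.
#' @param intervals data.frame (chrom, start, end); rows are centred.
#' @param flank half window (bp).
#' @param n_bins number of aggregation bins per row.
#' @param chrom_sizes optional named vector for off-end detection.
#' @return list(mat = rows x n_bins matrix, profile = column means).
#' @export
stackup_track <- function(track, intervals, flank = 100e3, n_bins = 100,
                          chrom_sizes = NULL) {
  centres <- floor((intervals$start + intervals$end) / 2)
  width <- 2 * flank
  binw <- width / n_bins
  mat <- matrix(NA_real_, nrow(intervals), n_bins)
  for (ch in unique(intervals$chrom)) {
    tsub <- track[track$chrom == ch, , drop = FALSE]
    tsub <- tsub[order(tsub$start), , drop = FALSE]
    # prefix integral of the step function at its breakpoints
    brk <- c(tsub$start, tsub$end)
    o <- order(brk)
    # integral of track value over [0, x): evaluate via cumulative segments
    integ <- function(x) {
      if (!nrow(tsub)) return(numeric(length(x)))
      clow <- pmin(pmax(outer(x, tsub$start, "-"), 0),
                   matrix(rep(tsub$end - tsub$start, each = length(x)),
                          length(x)))
      as.numeric(clow %*% tsub$value)
    }
    rows <- which(intervals$chrom == ch)
    cs <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]] else Inf
    for (rw in rows) {
      edges <- centres[rw] - flank + binw * (0:n_bins)
      vals <- diff(integ(pmax(pmin(edges, cs), 0))) / binw
      vals[edges[-1] <= 0 | edges[-(n_bins + 1)] >= cs] <- NA_real_
      mat[rw, ] <- vals
    }
  }
  list(mat = mat, profile = colMeans(mat, na.rm = TRUE))
}
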