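#' Prominence-based 1D peak detection
#'
#' Finds local maxima of a numeric signal and their topographic prominence
#' (height above the highest saddle separating the peak from higher ground),
#' keeping peaks above a prominence threshold and enforcing a minimum peak
#' separation by greedily retaining the higher peak. Plateau maxima report
#' their middle index. NA values act as barriers.
#'
#' @param x numeric signal.
#' @param prominence minimum prominence to keep a peak.
#' @param min_distance minimum index separation between kept peaks.
#' @return data.frame(index, value, prominence), index 1-based.
#' @export
find_peaks_1d <- function(x, prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), value = numeric(0),
                               prominence = numeric(0)))
  xx <- ifelse(is.na(x), -Inf, x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (xx[i] > xx[i - 1L]) {
      # scan forward over any plateau
      j <- i
      while (j < n && xx[j + 1L] == xx[i]) j <- j + 1L
      if (j < n && xx[j + 1L] < xx[i]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks)) return(data.frame(index = integer(0), value = numeric(0),
                                        prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    h <- xx[p]
    # left side: walk until a strictly higher point or the edge
    lmin <- h
    k <- p - 1L
    while (k >= 1L && xx[k] <= h) { lmin <- min(lmin, xx[k]); k <- k - 1L }
    lbase <- if (k >= 1L) lmin else min(lmin, xx[1L])
    rmin <- h
    k <- p + 1L
    while (k <= n && xx[k] <= h) { rmin <- min(rmin, xx[k]); k <- k + 1L }
    rbase <- if (k <= n) rmin else min(rmin, xx[n])
    h - max(lbase, rbase)
  }, numeric(1))
  keep <- prom >= prominence & is.finite(xx[peaks])
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) > 1 && min_distance > 1) {
    ord <- order(xx[peaks], prom, decreasing = TRUE)
    kept <- logical(length(peaks))
    taken <- integer(0)
    for (k in ord) {
      if (!length(taken) || all(abs(peaks[k] - taken) >= min_distance)) {
        kept[k] <- TRUE
        taken <- c(taken, peaks[k])
      }
    }
    peaks <- peaks[kept]; prom <- prom[kept]
    o <- order(peaks); peaks <- peaks[o]; prom <- prom[o]
  }
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}
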