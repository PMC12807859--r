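#' Per-region compartment eigenvectors with phasing
#'
#' Eigendecomposes, separately for each view region, the observed/expected
#' matrix minus one (masked bins zeroed), keeping the leading eigenvectors
#' by algebraic eigenvalue. Each eigenvector is unit-normalized over valid
#' bins and sign-flipped to correlate positively with the phasing track
#' (typically gene density), so that positive EV1 marks the active A
#' compartment.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @param phasing_track optional numeric per-bin track used to fix signs.
#' @param n_eigs number of leading eigenvectors per region (default 3).
#' @param min_valid regions with fewer valid bins are skipped with a
#'   warning.
#' @return an `eigen_result`: list(vectors = bins x n_eigs matrix (NA on
#'   masked/skipped bins), values = data.frame(region, eig, value),
#'   flips = data.frame(region, eig, flipped)).
#' @export
eigs_cis_phased <- function(oe, phasing_track = NULL, n_eigs = 3,
                            min_valid = 10) {
  nb <- nrow(oe$bins)
  vecs <- matrix(NA_real_, nb, n_eigs)
  vals <- list(); flips <- list()
  for (r in sort(unique(oe$region))) {
    ids <- which(oe$region == r)
    dense <- oe_dense_region(oe, r)
    valid <- !is.na(oe$bins$weight[ids])
    if (sum(valid) < min_valid) {
      warning("region ", r, " has fewer than ", min_valid,
              " valid bins; skipped")
      next
    }
    A <- dense - 1
    A[is.na(A)] <- 0
    n <- nrow(A)
    k <- min(n_eigs, n - 1L)
    er <- igraph::arpack(function(x, extra) as.numeric(A %*% x),
                         options = list(n = n, nev = k,
                                        ncv = min(n, max(20, 4 * k)),
                                        which = "LA", maxiter = 10000),
                         sym = TRUE)
    ord <- order(er$values, decreasing = TRUE)
    ev <- matrix(er$vectors, ncol = k)[, ord, drop = FALSE]
    lambda <- er$values[ord]
    for (e in seq_len(k)) {
      v <- ev[, e]
      v[!valid] <- NA
      v <- v / sqrt(sum(v^2, na.rm = TRUE))
      flipped <- FALSE
      if (!is.null(phasing_track)) {
        ph <- phasing_track[ids]
        cc <- suppressWarnings(stats::cor(v, ph, use = "complete.obs"))
        if (is.finite(cc) && cc < 0) { v <- -v; flipped <- TRUE }
      }
      vecs[ids, e] <- v
      vals[[length(vals) + 1L]] <- data.frame(region = r, eig = e,
                                              value = lambda[e])
      flips[[length(flips) + 1L]] <- data.frame(region = r, eig = e,
                                                flipped = flipped)
    }
  }
  structure(list(vectors = vecs,
                 values = do.call(rbind, vals),
                 flips = do.call(rbind, flips)),
            class = "eigen_result")
}

#' Saddle analysis and compartment strength
#'
#' Digitizes a per-bin track into quantiles (after trimming a fraction of
#' extreme values from each end), averages observed/expected over every
#' quantile pair within view regions (zeros of the sparse map counted over
#' valid bin pairs), and quantifies compartment strength as
#' `AA / ((AB + BA) / 2)` where AA averages the saddle cells between the
#' quantiles with the strongest A identity (`top_fraction` of quantiles)
#' and AB the cells between the strongest A and strongest B quantiles;
#' `BB / ((AB + BA) / 2)` analogously. A categorical track (factor) is
#' used as classes directly, without digitization.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @param track numeric per-bin track (e.g. EV1), or factor for
#'   categorical classes.
#' @param n_quantiles number of quantile classes (default 38).
#' @param trim_fraction fraction of extreme track values dropped at each
#'   end before digitization (default 0.025).
#' @param top_fraction fraction of quantiles forming the "strong A" and
#'   "strong B" blocks for the strength ratio (default 0.20).
#' @return a `saddle_result`: list(saddle (K x K mean O/E), counts (valid
#'   pair counts), strength_A, strength_B, levels).
#' @export
saddle_strength <- function(oe, track, n_quantiles = 38,
                            trim_fraction = 0.025, top_fraction = 0.20) {
  nb <- nrow(oe$bins)
  stopifnot(length(track) == nb)
  valid <- !is.na(oe$bins$weight)
  categorical <- is.factor(track) || is.character(track)
  if (categorical) {
    f <- factor(track)
    K <- nlevels(f)
    q <- as.integer(f)
    q[!valid | is.na(track)] <- NA
    lev <- levels(f)
  } else {
    K <- n_quantiles
    tv <- track
    tv[!valid] <- NA
    lo <- stats::quantile(tv, trim_fraction, na.rm = TRUE)
    hi <- stats::quantile(tv, 1 - trim_fraction, na.rm = TRUE)
    tv[tv < lo | tv > hi] <- NA
    # rank-based digitization into K near-equal-occupancy classes
    rk <- rank(tv, na.last = "keep", ties.method = "first")
    q <- as.integer(ceiling(rk / sum(!is.na(rk)) * K))
    q[q == 0L] <- 1L
    lev <- paste0("Q", seq_len(K))
  }
  Ssum <- matrix(0, K, K)
  Scnt <- matrix(0, K, K)
  for (r in sort(unique(oe$region))) {
    ids <- which(oe$region == r)
    dense <- oe_dense_region(oe, r)
    qq <- q[ids]
    ok <- !is.na(qq)
    if (!sum(ok)) next
    Q <- matrix(0, length(ids), K)
    Q[cbind(which(ok), qq[ok])] <- 1
    Vd <- !is.na(dense)
    D0 <- dense; D0[!Vd] <- 0
    Ssum <- Ssum + t(Q) %*% D0 %*% Q
    Scnt <- Scnt + t(Q) %*% (Vd + 0) %*% Q
  }
  saddle <- ifelse(Scnt > 0, Ssum / Scnt, NA_real_)
  kA <- max(1L, round(top_fraction * K))
  strength_A <- strength_B <- NA_real_
  if (!categorical) {
    Aq <- (K - kA + 1L):K
    Bq <- 1:kA
    blk <- function(qi, qj) {
      s <- sum(Ssum[qi, qj]); n <- sum(Scnt[qi, qj])
      if (n > 0) s / n else NA_real_
    }
    AA <- blk(Aq, Aq); BB <- blk(Bq, Bq)
    AB <- blk(Aq, Bq); BA <- blk(Bq, Aq)
    strength_A <- AA / ((AB + BA) / 2)
    strength_B <- BB / ((AB + BA) / 2)
  }
  structure(list(saddle = saddle, counts = Scnt,
                 strength_A = strength_A, strength_B = strength_B,
                 levels = lev),
            class = "saddle_result")
}

#' Diamond insulation score
#'
#' For every bin, the mean observed/expected over the square window of
#' upstream x downstream bins around it (the insulation diamond),
#' log2-normalized to the mean over its view region. Bins closer than the
#' window to a region edge, or masked, are NA. Local minima of the score
#' mark insulating boundaries.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @param window window size in bp (default 100 kb).
#' @return numeric per-bin score (log2 units).
#' @export
insulation_score <- function(oe, window = 100e3) {
  w <- round(window / oe$resolution)
  nb <- nrow(oe$bins)
  out <- rep(NA_real_, nb)
  for (r in sort(unique(oe$region))) {
    ids <- which(oe$region == r)
    dense <- oe_dense_region(oe, r)
    n <- nrow(dense)
    raw <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - w < 1 || i + w > n) next
      blk <- dense[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
      if (all(is.na(blk))) next
      raw[i] <- mean(blk, na.rm = TRUE)
    }
    raw[is.na(oe$bins$weight[ids])] <- NA
    mu <- mean(raw, na.rm = TRUE)
    out[ids] <- log2(raw / mu)
  }
  out
}
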