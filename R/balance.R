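#' Iterative-correction balancing with MAD-based bin masking
#'
#' Computes multiplicative per-bin weights such that the row sums of the
#' weight-scaled symmetric matrix are uniform over unmasked bins, excluding
#' the first `ignore_diags` diagonals from the marginals (short-range
#' ligation artefacts). Before iterating, bins whose log10 raw marginal
#' deviates from the median by more than `madmax_threshold` median absolute
#' deviations are masked, as are bins with zero marginal.
#'
#' @param m a [contact_matrix()].
#' @param ignore_diags number of leading diagonals (|bin2-bin1| <
#'   `ignore_diags`) to exclude from marginals. Default 2.
#' @param madmax_threshold MAD multiple for the coverage filter (two-sided,
#'   on log10 marginals). Default 5. `Inf` disables the filter.
#' @param tol convergence tolerance: maximum relative deviation of the
#'   marginals from their mean.
#' @param max_iter maximum number of iterations.
#' @return the matrix with `bins$weight` filled (NA on masked bins), scaled
#'   so the mean unmasked marginal of the balanced matrix is 1.
#' @export
balance_ic <- function(m, ignore_diags = 2, madmax_threshold = 5,
                       tol = 1e-6, max_iter = 1000) {
  px <- m$pixels
  if (nrow(px) == 0 || all(px$count == 0)) stop("degenerate matrix")
  stopifnot(ignore_diags >= 0)
  n <- n_bins(m)

  keep <- abs(px$bin2_id - px$bin1_id) >= ignore_diags
  pk <- px[keep & px$count > 0, , drop = FALSE]
  if (nrow(pk) == 0) stop("degenerate matrix")

  # symmetric sparse matrix of raw counts, ignored diagonals removed
  off <- pk$bin1_id != pk$bin2_id
  A <- Matrix::sparseMatrix(
    i = c(pk$bin1_id, pk$bin2_id[off]) + 1L,
    j = c(pk$bin2_id, pk$bin1_id[off]) + 1L,
    x = c(pk$count, pk$count[off]), dims = c(n, n))

  marg <- as.numeric(A %*% rep(1, n))
  mask <- marg <= 0
  if (is.finite(madmax_threshold)) {
    lm <- log10(marg[!mask])
    med <- stats::median(lm)
    madv <- stats::median(abs(lm - med))
    if (madv > 0)
      mask[!mask][abs(lm - med) > madmax_threshold * madv] <- TRUE
  }
  if (all(mask)) stop("degenerate matrix: all bins masked")

  w <- as.numeric(!mask)
  active <- which(!mask)
  for (it in seq_len(max_iter)) {
    s <- w * as.numeric(A %*% w)            # current marginals
    sa <- s[active]
    if (any(sa <= 0)) {                      # isolated after masking
      newly <- active[sa <= 0]
      mask[newly] <- TRUE
      w[newly] <- 0
      active <- which(!mask)
      if (!length(active)) stop("degenerate matrix: all bins masked")
      next
    }
    rel <- sa / mean(sa)
    if (max(abs(rel - 1)) < tol) break
    w[active] <- w[active] / rel
    if (it == max_iter)
      stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                   max_iter, max(abs(rel - 1))))
  }
  # scale weights so the mean unmasked balanced marginal equals 1
  s <- w * as.numeric(A %*% w)
  w <- w / sqrt(mean(s[active]))
  w[mask] <- NA_real_
  m$bins$weight <- w
  attr(m, "ignore_diags") <- ignore_diags
  m
}
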