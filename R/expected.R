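#' Distance-decay expected profiles
#'
#' Computes, per view region, the mean balanced contact value at each
#' genomic separation (counting zero pixels over valid bins), plus a
#' log-space smoothed variant, and per-region-pair mean balanced trans
#' values. These are the denominators used to flatten maps to
#' observed/expected.
#'
#' @param m a balanced [contact_matrix()].
#' @param view a [genome_view()] covering the bins.
#' @param ignore_diags separations (in bins) below this are reported NA.
#' @param smooth_ratio half-width of the geometric smoothing window: the
#'   smoothed value at separation d is the n_valid-weighted running mean of
#'   the raw profile over separations in [d/r, d*r]. Default 1.05 (+/-5%),
#'   a constant-relative-width window so a pure power law is preserved up
#'   to a constant factor.
#' @return an `expected_profile`: list with `cis` (region, dist, n_valid,
#'   avg_raw, avg_smoothed), `trans` (region1, region2, n_valid, avg),
#'   `resolution`, `ignore_diags`.
#' @export
compute_expected <- function(m, view, ignore_diags = 2, smooth_ratio = 1.05) {
  if (!is_balanced(m)) stop("weights required")
  reg <- view_assign_bins(view, m$bins)
  w <- m$bins$weight
  px <- m$pixels
  bal <- px$count * w[px$bin1_id + 1L] * w[px$bin2_id + 1L]
  r1 <- reg[px$bin1_id + 1L]
  r2 <- reg[px$bin2_id + 1L]
  ch1 <- m$bins$chrom[px$bin1_id + 1L]
  ch2 <- m$bins$chrom[px$bin2_id + 1L]

  cis_list <- vector("list", nrow(view))
  for (r in seq_len(nrow(view))) {
    ids <- which(reg == r)            # 1-based bin rows
    nr <- length(ids)
    if (nr == 0) next
    v <- as.numeric(!is.na(w[ids]))
    dmax <- nr - 1L
    nv <- numeric(dmax + 1L)          # index d+1
    for (d in 0:dmax) nv[d + 1L] <- sum(v[seq_len(nr - d)] * v[seq_len(nr - d) + d])
    sel <- which(r1 == r & r2 == r & !is.na(bal))
    d_px <- px$bin2_id[sel] - px$bin1_id[sel]
    sums <- numeric(dmax + 1L)
    if (length(sel)) {
      agg <- rowsum(bal[sel], d_px)
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    d_all <- 0:dmax
    avg <- ifelse(nv > 0, sums / nv, NA_real_)
    avg[d_all < ignore_diags] <- NA_real_
    cis_list[[r]] <- data.frame(region = view$name[r], dist = d_all,
                                n_valid = nv, avg_raw = avg,
                                sum_bal = sums, stringsAsFactors = FALSE)
  }
  cis <- do.call(rbind, cis_list)
  cis$avg_smoothed <- NA_real_
  for (rn in unique(cis$region)) {
    i <- which(cis$region == rn)
    cis$avg_smoothed[i] <- smooth_geometric(cis$dist[i], cis$avg_raw[i],
                                            cis$n_valid[i], smooth_ratio)
  }

  # trans: per unordered region pair on different chromosomes
  nvalid_reg <- vapply(seq_len(nrow(view)),
                       function(r) sum(!is.na(w[reg == r])), numeric(1))
  tr <- which(ch1 != ch2 & !is.na(bal))
  trans <- NULL
  if (nrow(view) > 1) {
    combs <- utils::combn(seq_len(nrow(view)), 2)
    keep <- view$chrom[combs[1, ]] != view$chrom[combs[2, ]]
    combs <- combs[, keep, drop = FALSE]
    if (ncol(combs)) {
      key_px <- paste(pmin(r1[tr], r2[tr]), pmax(r1[tr], r2[tr]))
      sums <- tapply(bal[tr], key_px, sum)
      key <- paste(combs[1, ], combs[2, ])
      s <- ifelse(key %in% names(sums), sums[key], 0)
      nv <- nvalid_reg[combs[1, ]] * nvalid_reg[combs[2, ]]
      trans <- data.frame(region1 = view$name[combs[1, ]],
                          region2 = view$name[combs[2, ]],
                          n_valid = nv,
                          avg = ifelse(nv > 0, as.numeric(s) / nv, NA_real_),
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(cis = cis, trans = trans, resolution = m$resolution,
                 ignore_diags = ignore_diags, view = view),
            class = "expected_profile")
}

# n-weighted running mean over geometric windows [d/r, d*r]; NA-aware.
smooth_geometric <- function(d, avg, n, ratio) {
  ok <- !is.na(avg)
  nn <- ifelse(ok, n, 0)
  sv <- ifelse(ok, avg * n, 0)
  out <- rep(NA_real_, length(d))
  pos <- which(d > 0 & ok)
  if (!length(pos)) return(out)
  csum_v <- cumsum(sv)
  csum_n <- cumsum(nn)
  lo <- findInterval(d / ratio, d)           # last index with d <= bound is tricky;
  lo <- pmax(lo, 1L)                          # d is sorted increasing integers
  hi <- findInterval(d * ratio + 1e-9, d)
  for (k in pos) {
    a <- lo[k]; b <- hi[k]
    # ensure window actually within [d/r, d*r]
    while (a <= length(d) && d[a] < d[k] / ratio - 1e-9) a <- a + 1L
    tot_n <- csum_n[b] - if (a > 1) csum_n[a - 1] else 0
    tot_v <- csum_v[b] - if (a > 1) csum_v[a - 1] else 0
    if (tot_n > 0) out[k] <- tot_v / tot_n
  }
  out[d == 0] <- NA_real_
  out
}

#' Observed/expected flattening
#'
#' Replaces each valid pixel by its balanced value divided by the expected
#' at its separation (cis, within a view region) or by the region-pair trans
#' level. Pixels on masked bins, below `ignore_diags`, spanning two regions
#' of the same chromosome, or whose expected is zero/undefined are dropped
#' and counted in the report attribute.
#'
#' @param m a balanced [contact_matrix()].
#' @param expected an [compute_expected()] result on the same view/resolution.
#' @param view the same [genome_view()].
#' @param smoothed use the smoothed cis expected instead of the raw one.
#' @return an `oe_map`: list(pixels = data.frame(bin1_id, bin2_id, oe),
#'   bins, resolution, view, region). `attr(,"report")` counts dropped
#'   pixels by reason.
#' @export
observed_over_expected <- function(m, expected, view, smoothed = FALSE) {
  if (!is_balanced(m)) stop("weights required")
  stopifnot(expected$resolution == m$resolution)
  reg <- view_assign_bins(view, m$bins)
  w <- m$bins$weight
  px <- m$pixels
  bal <- px$count * w[px$bin1_id + 1L] * w[px$bin2_id + 1L]
  r1 <- reg[px$bin1_id + 1L]
  r2 <- reg[px$bin2_id + 1L]
  ch1 <- m$bins$chrom[px$bin1_id + 1L]
  ch2 <- m$bins$chrom[px$bin2_id + 1L]

  n_masked <- sum(is.na(bal))
  oe <- rep(NA_real_, nrow(px))
  colname <- if (smoothed) "avg_smoothed" else "avg_raw"

  cis_sel <- which(!is.na(bal) & r1 == r2)
  if (length(cis_sel)) {
    d <- px$bin2_id[cis_sel] - px$bin1_id[cis_sel]
    # lookup per region
    for (r in unique(r1[cis_sel])) {
      tab <- expected$cis[expected$cis$region == view$name[r], ]
      e <- rep(NA_real_, max(tab$dist) + 1L)
      e[tab$dist + 1L] <- tab[[colname]]
      k <- cis_sel[r1[cis_sel] == r]
      oe[k] <- bal[k] / e[px$bin2_id[k] - px$bin1_id[k] + 1L]
    }
  }
  n_same_chrom_cross <- sum(!is.na(bal) & r1 != r2 & ch1 == ch2)

  trans_sel <- which(!is.na(bal) & ch1 != ch2)
  if (length(trans_sel) && !is.null(expected$trans)) {
    tt <- expected$trans
    key_tab <- paste(pmin(match(tt$region1, view$name), match(tt$region2, view$name)),
                     pmax(match(tt$region1, view$name), match(tt$region2, view$name)))
    key_px <- paste(pmin(r1[trans_sel], r2[trans_sel]),
                    pmax(r1[trans_sel], r2[trans_sel]))
    e <- tt$avg[match(key_px, key_tab)]
    oe[trans_sel] <- bal[trans_sel] / e
  }

  keep <- is.finite(oe)
  n_zero_expected <- sum(!is.finite(oe) & !is.na(bal)) - n_same_chrom_cross
  out <- data.frame(bin1_id = px$bin1_id[keep], bin2_id = px$bin2_id[keep],
                    oe = oe[keep])
  res <- structure(list(pixels = out, bins = m$bins, resolution = m$resolution,
                        view = view, region = reg,
                        ignore_diags = expected$ignore_diags),
                   class = "oe_map")
  attr(res, "report") <- c(masked = n_masked,
                           zero_expected = n_zero_expected,
                           cross_region_cis = n_same_chrom_cross)
  res
}

#' @export
print.oe_map <- function(x, ...) {
  cat(sprintf("<oe_map> %d pixels over %d bins @ %g bp\n",
              nrow(x$pixels), nrow(x$bins), x$resolution))
  invisible(x)
}

#' Contact scaling P(s) and its log-log slope
#'
#' Aggregates the cis expected profile across view regions into a single
#' contact-probability-versus-separation curve, computes the slope
#' d log P / d log s by central differences, and reports the position of a
#' prominent local slope maximum (the extruded-loop "shoulder") when one
#' exists.
#'
#' @param m a balanced [contact_matrix()].
#' @param view a [genome_view()].
#' @param smooth aggregate separations into geometric bins (ratio
#'   `log_bin_ratio`) before taking the derivative; without it the curve is
#'   reported at every bin separation, which is only sensible for noiseless
#'   input.
#' @param ignore_diags separations (bins) excluded from the curve.
#' @param log_bin_ratio geometric spacing of the distance bins used when
#'   `smooth = TRUE`.
#' @param shoulder_prominence minimum prominence (slope units) for the
#'   reported shoulder.
#' @return a `scaling_curve`: list(dist_bp, P, slope, shoulder_bp).
#' @export
contact_scaling <- function(m, view, smooth = TRUE, ignore_diags = 2,
                            log_bin_ratio = 1.12,
                            shoulder_prominence = 0.1) {
  exp_prof <- compute_expected(m, view, ignore_diags = ignore_diags)
  cis <- exp_prof$cis
  agg_n <- tapply(cis$n_valid * !is.na(cis$avg_raw), cis$dist, sum)
  agg_s <- tapply(ifelse(is.na(cis$avg_raw), 0, cis$sum_bal), cis$dist, sum)
  d <- as.numeric(names(agg_n))
  P <- ifelse(agg_n > 0, as.numeric(agg_s) / as.numeric(agg_n), NA_real_)
  keep <- d >= ignore_diags & d > 0 & !is.na(P) & P > 0
  d <- d[keep]; P <- as.numeric(P[keep]); nv <- as.numeric(agg_n[keep])
  ssum <- as.numeric(agg_s[keep])
  if (length(d) < 3) stop("fewer than 3 distance points")
  if (smooth) {
    # geometric distance bins: contact sums and valid-pair counts pooled
    grp <- floor(log(d / d[1]) / log(log_bin_ratio))
    bn <- tapply(nv, grp, sum)
    bs <- tapply(ssum, grp, sum)
    bd <- exp(tapply(log(d) * nv, grp, sum) / tapply(nv, grp, sum))
    ok <- bn > 0 & bs > 0
    d <- as.numeric(bd[ok]); P <- as.numeric(bs[ok] / bn[ok])
    if (length(d) < 3) stop("fewer than 3 distance points")
  }
  x <- log(d * m$resolution)
  y <- log(P)
  slope <- gradient_nonuniform(x, y)
  shoulder_bp <- NA_real_
  if (length(slope) >= 5) {
    interior <- 2:(length(slope) - 1)
    pk <- find_peaks_1d(slope[interior], prominence = shoulder_prominence)
    if (nrow(pk)) {
      best <- pk$index[which.max(pk$prominence)]
      shoulder_bp <- d[interior][best] * m$resolution
    }
  }
  structure(list(dist_bp = d * m$resolution, P = P, slope = slope,
                 shoulder_bp = shoulder_bp),
            class = "scaling_curve")
}

# numpy.gradient-style second-order differences on a non-uniform grid
gradient_nonuniform <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  if (n < 2) return(rep(NA_real_, n))
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    h1 <- x[i + 1] - x[i]
    h2 <- x[i] - x[i - 1]
    g[i] <- (h2^2 * y[i + 1] + (h1^2 - h2^2) * y[i] - h1^2 * y[i - 1]) /
      (h1 * h2 * (h1 + h2))
  }
  g
}

#' Write / read expected profiles as TSV
#'
#' Two files: `<prefix>.cis.tsv` with columns (region, dist_bp, n_valid,
#' avg_raw, avg_smoothed) and `<prefix>.trans.tsv` with (region1, region2,
#' n_valid, avg).
#' @param expected an [compute_expected()] result.
#' @param prefix path prefix.
#' @export
write_expected <- function(expected, prefix) {
  cis <- expected$cis
  out <- data.frame(region = cis$region,
                    dist_bp = cis$dist * expected$resolution,
                    n_valid = cis$n_valid, avg_raw = cis$avg_raw,
                    avg_smoothed = cis$avg_smoothed)
  utils::write.table(out, paste0(prefix, ".cis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(expected$trans))
    utils::write.table(expected$trans, paste0(prefix, ".trans.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
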