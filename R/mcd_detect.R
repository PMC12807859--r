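#' Convolution kernel set for enrichment scoring
#'
#' Three footprints swept across the observed/expected map: a centred square
#' M (the candidate piece of a domain-domain interaction block), and two
#' flanking footprints — V, a vertically elongated pair of blocks above and
#' below M (sensitive background for horizontally elongated domains), and H,
#' its transpose. V and H flank M without overlapping it.
#'
#' @param half_width half-width of the square M kernel in bins (M side is
#'   `2*half_width+1`). The default 3 (a 7x7 square, 70 kb at 10 kb) sizes
#'   M to the domains this detector targets (25-125 kb) and averages enough
#'   cells for ratio thresholds to be meaningful on sparse long-range maps.
#' @param flank_extent extent of the V/H flanking blocks beyond M, in bins
#'   (default 7: V spans 21 bins tall by 7 wide in total, reaching 105 kb
#'   beyond the pixel so the flanks clear the largest target domains).
#' @return a `kernel_set`: list of offset data.frames (di, dj) per kernel.
#' @export
kernel_set <- function(half_width = 3, flank_extent = 7) {
  p <- half_width; e <- flank_extent
  sq <- expand.grid(di = -p:p, dj = -p:p)
  vflank <- expand.grid(di = c(-(p + e):-(p + 1), (p + 1):(p + e)), dj = -p:p)
  hflank <- expand.grid(di = -p:p, dj = c(-(p + e):-(p + 1), (p + 1):(p + e)))
  structure(list(M = sq, V = vflank, H = hflank,
                 half_width = p, flank_extent = e),
            class = "kernel_set")
}

# Summed-area table with NA-as-invalid handling; returns closure giving the
# (sum, count) of any rectangle clipped to the matrix.
make_sat <- function(x) {
  valid <- is.finite(x)
  xv <- ifelse(valid, x, 0)
  Sv <- apply(apply(xv, 2, cumsum), 1, cumsum)      # transposed
  Sn <- apply(apply(valid + 0, 2, cumsum), 1, cumsum)
  nr <- nrow(x); nc <- ncol(x)
  function(i1, i2, j1, j2) {
    i1 <- as.vector(pmax(i1, 1L)); j1 <- as.vector(pmax(j1, 1L))
    i2 <- as.vector(pmin(i2, nr)); j2 <- as.vector(pmin(j2, nc))
    bad <- i1 > i2 | j1 > j2
    # SAT indexed [col, row] because of the double-apply transpose;
    # cumulative sums saturate at the far edges, zero below the near ones
    g <- function(S, i, j) {
      zero <- i < 1 | j < 1
      v <- S[cbind(pmin(pmax(j, 1L), nc), pmin(pmax(i, 1L), nr))]
      v[zero] <- 0
      v
    }
    s <- g(Sv, i2, j2) - g(Sv, i1 - 1L, j2) - g(Sv, i2, j1 - 1L) +
      g(Sv, i1 - 1L, j1 - 1L)
    n <- g(Sn, i2, j2) - g(Sn, i1 - 1L, j2) - g(Sn, i2, j1 - 1L) +
      g(Sn, i1 - 1L, j1 - 1L)
    s[bad] <- 0; n[bad] <- 0
    list(sum = s, n = n)
  }
}

# Kernel mean fields over a dense O/E block. Rectangle decomposition:
# M is one box; V and H are each two boxes. Cells outside the matrix count
# as invalid. Returns list(M, V, H, Mfrac) of matrices aligned with `x`.
score_dense_block <- function(x, kernels) {
  p <- kernels$half_width; e <- kernels$flank_extent
  sat <- make_sat(x)
  nr <- nrow(x); nc <- ncol(x)
  ii <- matrix(rep(seq_len(nr), nc), nr, nc)
  jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  box <- function(di1, di2, dj1, dj2) sat(ii + di1, ii + di2, jj + dj1, jj + dj2)
  mb <- box(-p, p, -p, p)
  v1 <- box(-(p + e), -(p + 1), -p, p); v2 <- box(p + 1, p + e, -p, p)
  h1 <- box(-p, p, -(p + e), -(p + 1)); h2 <- box(-p, p, p + 1, p + e)
  msize <- (2 * p + 1)^2
  mk <- function(b) matrix(ifelse(b$n > 0, b$sum / b$n, NA_real_), nr, nc)
  list(M = mk(mb),
       V = matrix(ifelse(v1$n + v2$n > 0, (v1$sum + v2$sum) / (v1$n + v2$n),
                         NA_real_), nr, nc),
       H = matrix(ifelse(h1$n + h2$n > 0, (h1$sum + h2$sum) / (h1$n + h2$n),
                         NA_real_), nr, nc),
       Mfrac = matrix(mb$n / msize, nr, nc))
}

# Dense O/E block of one view region from an oe_map; invalid cells NA,
# stored pixels mirrored, valid unstored cells 0.
oe_dense_region <- function(oe, r) {
  ids <- which(oe$region == r) - 1L          # 0-based bin ids
  lo <- min(ids); hi <- max(ids)
  n <- hi - lo + 1L
  px <- oe$pixels
  sel <- px$bin1_id >= lo & px$bin2_id <= hi
  out <- matrix(0, n, n)
  i <- px$bin1_id[sel] - lo + 1L; j <- px$bin2_id[sel] - lo + 1L
  out[cbind(i, j)] <- px$oe[sel]
  out[cbind(j, i)] <- px$oe[sel]
  bad <- is.na(oe$bins$weight[(lo:hi) + 1L])
  out[bad, ] <- NA; out[, bad] <- NA
  # cells below the ignored diagonals carry no O/E
  if (oe$ignore_diags > 0) for (d in seq_len(oe$ignore_diags) - 1L) if (d < n) {
    idx <- seq_len(n - d)
    out[cbind(idx, idx + d)] <- NA
    out[cbind(idx + d, idx)] <- NA
  }
  attr(out, "lo") <- lo
  out
}

#' Kernel scores of observed/expected pixels
#'
#' Sweeps the M, V and H kernels across the flattened (observed/expected)
#' map within each view region, up to a maximum separation, and reports the
#' mean O/E over each footprint for every scored pixel. Masked bins and
#' cells outside the matrix are ignored in the means; pixels whose M
#' footprint is more than half masked are skipped. Scores are computed at
#' the positions of stored (non-zero) upper-triangle pixels.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @param kernels a [kernel_set()].
#' @param max_dist maximum separation scanned (bp; default 30 Mb).
#' @return data.frame(bin1_id, bin2_id, oe, M, V, H).
#' @export
score_pixels <- function(oe, kernels = kernel_set(), max_dist = 30e6) {
  out <- lapply(sort(unique(oe$region)), function(r)
    score_pixels_region(oe, r, kernels, max_dist))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

score_pixels_region <- function(oe, r, kernels, max_dist) {
  dmax <- floor(max_dist / oe$resolution)
  dense <- oe_dense_region(oe, r)
  lo <- attr(dense, "lo")
  sc <- score_dense_block(dense, kernels)
  px <- oe$pixels
  sel <- which(oe$region[px$bin1_id + 1L] == r & oe$region[px$bin2_id + 1L] == r &
               px$bin2_id - px$bin1_id <= dmax)
  if (!length(sel)) return(NULL)
  i <- px$bin1_id[sel] - lo + 1L
  j <- px$bin2_id[sel] - lo + 1L
  ok <- sc$Mfrac[cbind(i, j)] >= 0.5
  sel <- sel[ok]; i <- i[ok]; j <- j[ok]
  data.frame(bin1_id = px$bin1_id[sel], bin2_id = px$bin2_id[sel],
             oe = px$oe[sel],
             M = sc$M[cbind(i, j)], V = sc$V[cbind(i, j)],
             H = sc$H[cbind(i, j)])
}

#' Threshold and density-cluster enriched pixels
#'
#' Retains pixels whose M kernel mean is at least `ratio` times the V kernel
#' mean and (default) also the H kernel mean, then clusters the retained
#' pixels by density in 2D pixel-coordinate space (OPTICS-style: reachability
#' cut at `max_eps`, Chebyshev metric, core points need `min_samples`
#' neighbours including themselves) and discards singletons and clusters
#' smaller than `min_samples`.
#'
#' @param scored output of [score_pixels()].
#' @param ratio enrichment ratio threshold (default 2, inclusive).
#' @param min_samples minimum neighbourhood size / cluster size (default 5).
#' @param max_eps reachability distance (bp; default 33 kb).
#' @param resolution bin size of the map (bp).
#' @param both require M >= ratio*V AND M >= ratio*H (the stricter reading
#'   of "twice as bright as either", which keeps stripes out); FALSE for
#'   the either-one reading.
#' @param region optional region id per pixel; clustering never joins
#'   pixels across regions.
#' @return the retained pixels with a `cluster` column (integer id).
#' @export
select_and_cluster <- function(scored, ratio = 2, min_samples = 5,
                               max_eps = 33e3, resolution,
                               both = TRUE, region = NULL) {
  keepV <- !is.na(scored$V) & scored$M >= ratio * scored$V
  keepH <- !is.na(scored$H) & scored$M >= ratio * scored$H
  keep <- !is.na(scored$M) & if (both) keepV & keepH else keepV | keepH
  px <- scored[keep, , drop = FALSE]
  if (!nrow(px)) {
    message("no enriched pixels retained")
    px$cluster <- integer(0)
    return(px)
  }
  eps <- floor(max_eps / resolution)
  grp <- if (is.null(region)) rep(1L, nrow(px)) else region[px$bin1_id + 1L]
  cl <- rep(NA_integer_, nrow(px))
  next_id <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    labs <- cluster_pixels_density(px$bin1_id[idx], px$bin2_id[idx],
                                   eps, min_samples)
    pos <- !is.na(labs)
    labs[pos] <- labs[pos] + next_id
    if (any(pos)) next_id <- max(labs[pos])
    cl[idx] <- labs
  }
  px$cluster <- cl
  out <- px[!is.na(cl), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Density clustering of integer 2D points, Chebyshev metric.
# Core point: >= min_samples points (incl. itself) within distance eps.
# Clusters: density-connected components; border points join a core
# neighbour's cluster; clusters below min_samples are dropped (NA label).
cluster_pixels_density <- function(x, y, eps, min_samples) {
  n <- length(x)
  if (n == 0) return(integer(0))
  ord <- order(x, y)
  xo <- x[ord]; yo <- y[ord]
  # neighbour lists via window on sorted x
  nb <- vector("list", n)
  lo_ptr <- 1L
  for (i in seq_len(n)) {
    while (xo[i] - xo[lo_ptr] > eps) lo_ptr <- lo_ptr + 1L
    hi <- i
    while (hi < n && xo[hi + 1L] - xo[i] <= eps) hi <- hi + 1L
    cand <- lo_ptr:hi
    cand <- cand[abs(yo[cand] - yo[i]) <= eps]
    nb[[i]] <- cand
  }
  core <- lengths(nb) >= min_samples
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(lab[i])) next
    cur <- cur + 1L
    queue <- i; lab[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (is.na(lab[q])) {
          lab[q] <- cur
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  sizes <- table(lab)
  small <- as.integer(names(sizes)[sizes < min_samples])
  lab[lab %in% small] <- NA_integer_
  out <- rep(NA_integer_, n)
  out[ord] <- lab
  # renumber consecutively
  u <- sort(unique(out[!is.na(out)]))
  match(out, u)
}

#' Call MCD anchors from clustered enriched pixels
#'
#' Builds the anchor-valency track (per-bin count of clustered enriched
#' pixels incident on the bin, rows and columns of the upper triangle each
#' counted once), finds prominent local maxima as summits, grows each
#' footprint as the contiguous run of bins with valency at least half the
#' summit valency, trims overlapping footprints at the valency minimum
#' between summits, and drops anchors outside the width window.
#'
#' @param clustered output of [select_and_cluster()].
#' @param bins bin table of the map.
#' @param resolution bin size (bp).
#' @param min_width,max_width footprint width bounds (bp; defaults
#'   25 and 125 kb, the size range of the domains this detector targets).
#' @param prominence minimum summit prominence in valency units. The
#'   default 15 (three times `min_samples` of the clustering step) demands
#'   summit support equivalent to several independent partner clusters,
#'   which a single noise cluster cannot supply.
#' @param min_distance minimum summit separation in bins (default 2).
#' @return data.frame(chrom, start, end, summit, summit_bin, valency): one
#'   row per anchor, footprint in bp, `summit` the summit bin's start.
#' @export
call_mcd_anchors <- function(clustered, bins, resolution,
                             min_width = 25e3, max_width = 125e3,
                             prominence = 15, min_distance = 2) {
  n <- nrow(bins)
  val <- numeric(n)
  if (nrow(clustered)) {
    t1 <- tabulate(clustered$bin1_id + 1L, nbins = n)
    t2 <- tabulate(clustered$bin2_id + 1L, nbins = n)
    same <- clustered$bin1_id == clustered$bin2_id
    val <- t1 + t2 - tabulate(clustered$bin1_id[same] + 1L, nbins = n)
  }
  if (all(val == 0))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      summit_bin = integer(0), valency = numeric(0)))
  anchors <- list()
  offs <- chrom_offsets(bins)
  for (ch in names(offs)) {
    ids <- which(bins$chrom == ch)
    v <- val[ids]
    pk <- find_peaks_1d(v, prominence = prominence, min_distance = min_distance)
    if (!nrow(pk)) next
    half <- v[pk$index] / 2
    lo <- hi <- pk$index
    for (k in seq_along(lo)) {
      while (lo[k] > 1 && v[lo[k] - 1] >= half[k]) lo[k] <- lo[k] - 1
      while (hi[k] < length(v) && v[hi[k] + 1] >= half[k]) hi[k] <- hi[k] + 1
    }
    # trim overlapping footprints at the valency minimum between summits
    if (length(lo) > 1) {
      for (k in seq_len(length(lo) - 1)) {
        if (hi[k] >= lo[k + 1]) {
          between <- pk$index[k]:pk$index[k + 1]
          cut <- between[which.min(v[between])]
          hi[k] <- min(hi[k], cut - 1)
          lo[k + 1] <- max(lo[k + 1], cut)
        }
      }
    }
    ok <- hi >= lo
    anchors[[ch]] <- data.frame(
      chrom = ch,
      start = bins$start[ids[lo[ok]]],
      end = bins$end[ids[hi[ok]]],
      summit = bins$start[ids[pk$index[ok]]],
      summit_bin = ids[pk$index[ok]] - 1L,
      valency = pk$value[ok])
  }
  out <- do.call(rbind, anchors)
  if (is.null(out)) out <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), summit = numeric(0),
                                      summit_bin = integer(0), valency = numeric(0))
  w <- out$end - out$start
  out <- out[w >= min_width & w <= max_width, , drop = FALSE]
  out <- out[out$summit >= out$start & out$summit < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call MCD detection
#'
#' Region-wise kernel scoring, thresholding, density clustering and anchor
#' calling with the default parameters of the method.
#'
#' @param m a balanced [contact_matrix()].
#' @param expected its [compute_expected()] profile.
#' @param view the [genome_view()].
#' @inheritParams score_pixels
#' @inheritParams select_and_cluster
#' @inheritParams call_mcd_anchors
#' @return list(anchors, pixels) — the anchor table and the clustered
#'   enriched pixels.
#' @export
detect_mcds <- function(m, expected, view, kernels = kernel_set(),
                        max_dist = 30e6, ratio = 2, min_samples = 5,
                        max_eps = 33e3, both = TRUE,
                        min_width = 25e3, max_width = 125e3,
                        prominence = 15, min_distance = 2) {
  oe <- observed_over_expected(m, expected, view)
  clustered <- list()
  for (r in sort(unique(oe$region))) {
    sc <- score_pixels_region(oe, r, kernels, max_dist)
    if (is.null(sc) || !nrow(sc)) next
    cl <- select_and_cluster(sc, ratio = ratio, min_samples = min_samples,
                             max_eps = max_eps, resolution = m$resolution,
                             both = both)
    if (nrow(cl)) {
      if (length(clustered))
        cl$cluster <- cl$cluster + max(vapply(clustered, function(x)
          max(x$cluster), numeric(1)))
      clustered[[length(clustered) + 1L]] <- cl
    }
  }
  clustered <- if (length(clustered)) do.call(rbind, clustered)
    else data.frame(bin1_id = integer(0), bin2_id = integer(0),
                    oe = numeric(0), M = numeric(0), V = numeric(0),
                    H = numeric(0), cluster = integer(0))
  anchors <- call_mcd_anchors(clustered, m$bins, m$resolution,
                              min_width = min_width, max_width = max_width,
                              prominence = prominence,
                              min_distance = min_distance)
  list(anchors = anchors, pixels = clustered)
}

#' Compare two anchor sets by footprint overlap
#'
#' Partitions two anchor sets into A-specific, shared and B-specific by
#' footprint overlap (at least 1 bp after extending both footprints by a
#' symmetric tolerance).
#'
#' @param a,b anchor data.frames (chrom, start, end).
#' @param tolerance symmetric extension applied to both sets (bp).
#' @return list(a_specific, a_shared, b_shared, b_specific, summary) where
#'   summary counts each category and the shared fraction of each set.
#' @export
compare_anchor_sets <- function(a, b, tolerance = 0) {
  hit_a <- interval_overlaps_any(a$chrom, a$start - tolerance, a$end + tolerance,
                                 b$chrom, b$start - tolerance, b$end + tolerance)
  hit_b <- interval_overlaps_any(b$chrom, b$start - tolerance, b$end + tolerance,
                                 a$chrom, a$start - tolerance, a$end + tolerance)
  list(a_specific = a[!hit_a, , drop = FALSE],
       a_shared = a[hit_a, , drop = FALSE],
       b_shared = b[hit_b, , drop = FALSE],
       b_specific = b[!hit_b, , drop = FALSE],
       summary = data.frame(
         n_a = nrow(a), n_b = nrow(b),
         n_a_shared = sum(hit_a), n_b_shared = sum(hit_b),
         frac_a_shared = if (nrow(a)) sum(hit_a) / nrow(a) else NA_real_,
         frac_b_shared = if (nrow(b)) sum(hit_b) / nrow(b) else NA_real_))
}
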