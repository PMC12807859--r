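#' Genome-wide observed/expected as a sparse symmetric matrix
#'
#' Assembles the flattened map (cis per-region distance decay, per-pair
#' trans levels) into one sparse symmetric matrix over all bins, the input
#' of the genome-wide eigendecomposition. Masked bins have empty rows.
#'
#' @param oe an `oe_map` from [observed_over_expected()].
#' @return a `Matrix::dgCMatrix` (n_bins x n_bins).
#' @export
genomewide_oe_matrix <- function(oe) {
  n <- nrow(oe$bins)
  px <- oe$pixels
  off <- px$bin1_id != px$bin2_id
  Matrix::sparseMatrix(i = c(px$bin1_id, px$bin2_id[off]) + 1L,
                       j = c(px$bin2_id, px$bin1_id[off]) + 1L,
                       x = c(px$oe, px$oe[off]), dims = c(n, n))
}

# The eigensolver sees the map only through this closure.
make_matvec <- function(A) function(x, extra = NULL) as.numeric(A %*% x)

#' Genome-wide sparse spectral clustering
#'
#' The whole-genome variant of compartment analysis: the balanced map is
#' flattened (per-region cis decay, per-pair trans levels), translocation
#' or otherwise untrustworthy regions are masked, the flattened map is
#' itself iteratively corrected so bin coverage cannot drive the leading
#' eigenvectors, and the resulting symmetric matrix is eigendecomposed
#' through a matrix-free ARPACK call (the solver only ever sees a
#' matrix-vector product; the dense matrix is never materialized
#' genome-wide). Eigenvectors are ordered by absolute eigenvalue; E1 is the
#' trivial flat vector (uniform row sums after correction) and is excluded
#' from clustering. E2 onward are unit-normalized, weighted by the square
#' root of the absolute eigenvalue, and k-means-clustered with a fixed
#' seed. The correlation between E2 and the concatenated per-region EV1 is
#' reported as a diagnostic (no pass/fail gate).
#'
#' @param m a balanced [contact_matrix()].
#' @param view a [genome_view()].
#' @param bad_regions optional data.frame (chrom, start, end) masked before
#'   the flattening and correction.
#' @param n_eigs eigenvectors computed (default 9).
#' @param k number of k-means clusters (default 8).
#' @param seed k-means seed.
#' @param nstart k-means restarts (default 10).
#' @return list(labels (per-bin integer, NA masked), values, vectors
#'   (bins x n_eigs), e2_ev1_cor, kmeans).
#' @export
spectral_cluster_genome <- function(m, view, bad_regions = NULL,
                                    n_eigs = 9, k = 8, seed = 0,
                                    nstart = 10) {
  if (!is_balanced(m)) stop("weights required")
  if (!is.null(bad_regions) && nrow(bad_regions)) {
    hit <- interval_overlaps_any(m$bins$chrom, m$bins$start, m$bins$end,
                                 bad_regions$chrom, bad_regions$start,
                                 bad_regions$end)
    m$bins$weight[hit] <- NA_real_
  }
  expected <- compute_expected(m, view)
  oe <- observed_over_expected(m, expected, view)

  # iterative correction of the flattened map itself
  oe_cm <- contact_matrix(m$bins,
                          data.frame(bin1_id = oe$pixels$bin1_id,
                                     bin2_id = oe$pixels$bin2_id,
                                     count = oe$pixels$oe),
                          m$resolution)
  oe_cm$bins$weight <- NA_real_
  oe_bal <- balance_ic(oe_cm, ignore_diags = expected$ignore_diags,
                       madmax_threshold = Inf, tol = 1e-5)
  w2 <- oe_bal$bins$weight
  px <- oe_bal$pixels
  keep <- !is.na(w2[px$bin1_id + 1L]) & !is.na(w2[px$bin2_id + 1L])
  px <- px[keep, , drop = FALSE]
  bal_oe <- oe
  bal_oe$pixels <- data.frame(bin1_id = px$bin1_id, bin2_id = px$bin2_id,
                              oe = px$count * w2[px$bin1_id + 1L] *
                                w2[px$bin2_id + 1L])
  bal_oe$bins$weight <- w2

  A <- genomewide_oe_matrix(bal_oe)
  valid <- which(!is.na(w2))
  Av <- A[valid, valid]
  nv <- length(valid)
  er <- igraph::arpack(make_matvec(Av),
                       options = list(n = nv, nev = n_eigs,
                                      ncv = min(nv, max(40, 4 * n_eigs)),
                                      which = "LM", maxiter = 20000),
                       sym = TRUE)
  ord <- order(abs(er$values), decreasing = TRUE)
  lambda <- er$values[ord]
  V <- matrix(er$vectors, ncol = length(er$values))[, ord, drop = FALSE]

  nb <- nrow(m$bins)
  vectors <- matrix(NA_real_, nb, n_eigs)
  for (e in seq_len(ncol(V))) vectors[valid, e] <- V[, e]

  # features: E2..E(n_eigs), unit norm, sqrt(|eigenvalue|) weights
  feat <- sapply(2:ncol(V), function(e) {
    v <- V[, e] / sqrt(sum(V[, e]^2))
    v * sqrt(abs(lambda[e]))
  })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  km <- stats::kmeans(feat, centers = k, nstart = nstart, iter.max = 200)
  labels <- rep(NA_integer_, nb)
  labels[valid] <- km$cluster

  # diagnostic: per-region EV1 of the same flattened map vs genome-wide E2
  ev1 <- tryCatch({
    er1 <- eigs_cis_phased(bal_oe, n_eigs = 1)
    er1$vectors[, 1]
  }, error = function(e) rep(NA_real_, nb))
  e2 <- vectors[, 2]
  for (r in sort(unique(oe$region))) {
    ids <- which(oe$region == r)
    cc <- suppressWarnings(stats::cor(ev1[ids], e2[ids], use = "complete.obs"))
    if (is.finite(cc) && cc < 0) ev1[ids] <- -ev1[ids]
  }
  e2_ev1_cor <- suppressWarnings(stats::cor(ev1, e2, use = "complete.obs"))

  list(labels = labels, values = lambda, vectors = vectors,
       e2_ev1_cor = e2_ev1_cor, kmeans = km)
}

#' Cluster / MCD bidirectional coverage
#'
#' For each cluster label: the fraction of the cluster covered by MCD
#' footprints and the fraction of MCD footprints covered by the cluster,
#' both by nucleotides and by interval counts, with a flag for clusters
#' meeting a bidirectional threshold (default 60%/60%).
#'
#' @param labels per-bin integer cluster labels (NA allowed).
#' @param bins bin table the labels refer to.
#' @param anchors MCD anchor table (chrom, start, end).
#' @param threshold bidirectional coverage threshold (default 0.6).
#' @return data.frame(cluster, cluster_bp, frac_cluster_in_mcd,
#'   frac_mcd_in_cluster, frac_cluster_ivals_hit, frac_mcd_ivals_hit,
#'   meets_criterion).
#' @export
cluster_mcd_overlap <- function(labels, bins, anchors, threshold = 0.60) {
  mcd_bp_total <- sum(anchors$end - anchors$start)
  out <- list()
  for (cl in sort(unique(labels[!is.na(labels)]))) {
    sel <- which(labels == cl)
    iv <- interval_union(bins$chrom[sel], bins$start[sel], bins$end[sel])
    clus_bp <- sum(iv$end - iv$start)
    in_mcd <- interval_covered_bp(iv$chrom, iv$start, iv$end,
                                  anchors$chrom, anchors$start, anchors$end)
    mcd_in <- interval_covered_bp(anchors$chrom, anchors$start, anchors$end,
                                  iv$chrom, iv$start, iv$end)
    hit_iv <- interval_overlaps_any(iv$chrom, iv$start, iv$end,
                                    anchors$chrom, anchors$start, anchors$end)
    hit_mcd <- interval_overlaps_any(anchors$chrom, anchors$start, anchors$end,
                                     iv$chrom, iv$start, iv$end)
    f1 <- sum(in_mcd) / clus_bp
    f2 <- sum(mcd_in) / mcd_bp_total
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, cluster_bp = clus_bp,
      frac_cluster_in_mcd = f1, frac_mcd_in_cluster = f2,
      frac_cluster_ivals_hit = mean(hit_iv),
      frac_mcd_ivals_hit = mean(hit_mcd),
      meets_criterion = f1 > threshold & f2 > threshold)
  }
  do.call(rbind, out)
}
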