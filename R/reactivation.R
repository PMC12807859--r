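#' Classify genes by post-mitotic reactivation timing
#'
#' Buckets genes by the first time point at which the new-to-total RNA
#' ratio (NTR) reaches a threshold: crossing at t = 0 h -> "prometaphase",
#' t = 1-2 h -> "early", t = 3-5 h -> "late", never -> "none". The
#' threshold test is inclusive (>= 10% by default); set `strict` for a
#' strict inequality.
#'
#' @param ntr data.frame with columns `ntr_0` .. `ntr_5` (NTR in \[0, 1\]
#'   at t = 0..5 h), one row per gene.
#' @param threshold NTR crossing threshold (default 0.10).
#' @param strict use strictly-greater instead of >=.
#' @return character vector of cluster labels; genes with a missing time
#'   point are NA with a warning.
#' @export
classify_reactivation <- function(ntr, threshold = 0.10, strict = FALSE) {
  tcols <- paste0("ntr_", 0:5)
  stopifnot(all(tcols %in% names(ntr)))
  mat <- as.matrix(ntr[, tcols])
  out <- rep(NA_character_, nrow(mat))
  incomplete <- apply(mat, 1, anyNA)
  if (any(incomplete))
    warning(sum(incomplete), " gene(s) with missing time points skipped")
  cross <- if (strict) mat > threshold else mat >= threshold
  first <- apply(cross, 1, function(z) if (any(z)) which(z)[1] - 1L else NA_integer_)
  ok <- !incomplete
  out[ok & !is.na(first) & first == 0] <- "prometaphase"
  out[ok & !is.na(first) & first >= 1 & first <= 2] <- "early"
  out[ok & !is.na(first) & first >= 3] <- "late"
  out[ok & is.na(first)] <- "none"
  out
}

#' Cluster-vs-MCD enrichment: one-sided Fisher tests with BH correction
#'
#' For each reactivation cluster, tests whether its genes are
#' over-represented among MCD-resident genes with a one-sided (greater)
#' Fisher's exact test on the 2x2 table (in cluster x at MCD), reporting
#' the sample cross-product odds ratio and Benjamini-Hochberg adjusted
#' q values across clusters. Tables with a zero margin get OR NA and
#' p = 1.
#'
#' @param clusters character vector of cluster labels (NA ignored).
#' @param mcd logical vector: gene overlaps an MCD.
#' @param background "all" uses every labelled gene as background
#'   (including "none"); "classified" drops "none" genes first.
#' @return data.frame(cluster, n, n_mcd, odds_ratio, p, q).
#' @export
enrichment_fisher_bh <- function(clusters, mcd,
                                 background = c("all", "classified")) {
  background <- match.arg(background)
  keep <- !is.na(clusters) & !is.na(mcd)
  if (background == "classified") keep <- keep & clusters != "none"
  cl <- clusters[keep]; fl <- mcd[keep]
  levs <- setdiff(sort(unique(cl)), character(0))
  if (length(levs) < 2) stop("need at least 2 clusters with genes")
  rows <- lapply(levs, function(L) {
    a <- sum(cl == L & fl);  b <- sum(cl == L & !fl)
    c_ <- sum(cl != L & fl); d <- sum(cl != L & !fl)
    zero_margin <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
    if (zero_margin) {
      or <- NA_real_; p <- 1
    } else {
      or <- (a * d) / (b * c_)
      if (!is.finite(or)) or <- NA_real_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                              alternative = "greater")$p.value
    }
    data.frame(cluster = L, n = a + b, n_mcd = a, odds_ratio = or, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
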