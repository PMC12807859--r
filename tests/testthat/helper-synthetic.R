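# Shared fixtures and independent oracles. Everything is generated in code;
# the heavier simulations are cached per test run.

.fixtures <- new.env(parent = emptyenv())

# The default study-scale simulation (3 x 20 Mb @ 10 kb, 30 MCDs,
# affinity 4, depth 2e7), balanced with expected and O/E. Built once.
default_sim <- function() {
  if (is.null(.fixtures$default)) {
    spec <- synthetic_genome_spec(seed = 1)
    sim <- simulate_contact_map(spec)
    m <- balance_ic(sim$matrix)
    view <- spec_view(spec)
    expected <- compute_expected(m, view)
    oe <- observed_over_expected(m, expected, view)
    .fixtures$default <- list(spec = spec, truth = sim$truth, m = m,
                              view = view, expected = expected, oe = oe)
  }
  .fixtures$default
}

default_detection <- function() {
  if (is.null(.fixtures$det)) {
    fx <- default_sim()
    .fixtures$det <- detect_mcds(fx$m, fx$expected, fx$view)
  }
  .fixtures$det
}

# A small uniform-intensity matrix: every cis pixel at separation >= 1
# carries the same expected count; handy for null-behaviour checks.
toy_uniform_matrix <- function(n = 60, count = 10, chrom = "chrA") {
  bins <- data.frame(chrom = chrom, start = (0:(n - 1)) * 1e4,
                     end = (1:n) * 1e4)
  idx <- t(utils::combn(0:(n - 1), 2))
  m <- contact_matrix(bins,
                      data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                                 count = count), 1e4)
  m$bins$weight <- 1
  m
}

toy_view <- function(m) {
  genome_view(data.frame(chrom = unique(m$bins$chrom),
                         start = 0,
                         end = vapply(unique(m$bins$chrom), function(ch)
                           max(m$bins$end[m$bins$chrom == ch]), numeric(1))))
}

# Oracle: mean O/E over an explicit offset footprint around (i, j) in a
# dense symmetric map (NA-aware); the brute-force counterpart of the
# integral-image kernel scores.
oracle_footprint_mean <- function(dense, i, j, offsets) {
  n <- nrow(dense)
  vals <- mapply(function(di, dj) {
    ii <- i + di; jj <- j + dj
    if (ii < 1 || ii > n || jj < 1 || jj > n) NA_real_ else dense[ii, jj]
  }, offsets$di, offsets$dj)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Oracle: exhaustive per-diagonal mean of balanced values over valid bins.
oracle_diag_means <- function(m, ids0) {
  w <- m$bins$weight
  n <- length(ids0)
  dense <- matrix(0, n, n)
  px <- m$pixels
  sel <- px$bin1_id %in% ids0 & px$bin2_id %in% ids0
  px <- px[sel, ]
  i <- match(px$bin1_id, ids0); j <- match(px$bin2_id, ids0)
  dense[cbind(i, j)] <- px$count * w[px$bin1_id + 1] * w[px$bin2_id + 1]
  dense[cbind(j, i)] <- dense[cbind(i, j)]
  valid <- !is.na(w[ids0 + 1])
  sapply(0:(n - 1), function(d) {
    num <- 0; den <- 0
    for (a in seq_len(n - d)) {
      b <- a + d
      if (valid[a] && valid[b]) { num <- num + dense[a, b]; den <- den + 1 }
    }
    if (den > 0) num / den else NA_real_
  })
}

# Oracle: one-sided (greater) Fisher p by exhaustive enumeration of all
# tables with the observed margins, probabilities from choose().
oracle_fisher_greater <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Oracle: Benjamini-Hochberg from first principles.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Adjusted Rand index (used where mclust is not guaranteed).
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expect <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  (sij - expect) / (maxi - expect)
}

# recall/precision of anchors against planted truth at a bp tolerance
recovery_metrics <- function(anchors, truth, tol) {
  hit_t <- mcdtools:::interval_overlaps_any(truth$chrom, truth$start - tol,
                                            truth$end + tol, anchors$chrom,
                                            anchors$start, anchors$end)
  hit_a <- mcdtools:::interval_overlaps_any(anchors$chrom, anchors$start - tol,
                                            anchors$end + tol, truth$chrom,
                                            truth$start, truth$end)
  list(recall = mean(hit_t), precision = mean(hit_a))
}

# hand-built oe_map from a dense symmetric matrix (upper triangle stored,
# zeros kept as absent pixels)
make_oe_map <- function(dense, resolution = 1e4, chrom = "chrA",
                        ignore_diags = 0, weight = NULL) {
  n <- nrow(dense)
  bins <- data.frame(chrom = chrom, start = (0:(n - 1)) * resolution,
                     end = (1:n) * resolution)
  bins$weight <- if (is.null(weight)) 1 else weight
  idx <- which(upper.tri(dense, diag = TRUE) & dense != 0 &
                 !is.na(dense), arr.ind = TRUE)
  px <- data.frame(bin1_id = idx[, 1] - 1L, bin2_id = idx[, 2] - 1L,
                   oe = dense[idx])
  view <- genome_view(chrom, 0, n * resolution)
  structure(list(pixels = px[order(px$bin1_id, px$bin2_id), ],
                 bins = bins, resolution = resolution, view = view,
                 region = rep(1L, n), ignore_diags = ignore_diags),
            class = "oe_map")
}

# brute-force single-linkage clusters at Chebyshev reach eps
oracle_single_linkage <- function(x, y, eps) {
  n <- length(x)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (max(abs(x[i] - x[j]), abs(y[i] - y[j])) <= eps &&
          lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}
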