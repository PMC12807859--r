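test_that("iterative correction equalizes row sums on a symmetric toy", {
  bins <- data.frame(chrom = "c", start = (0:3) * 1e4, end = (1:4) * 1e4)
  px <- data.frame(bin1_id = c(0, 1, 2, 0), bin2_id = c(1, 2, 3, 3),
                   count = 2)
  m <- balance_ic(contact_matrix(bins, px, 1e4), ignore_diags = 0)
  w <- m$bins$weight
  expect_false(anyNA(w))
  expect_equal(max(w) / min(w), 1, tolerance = 1e-9)  # equal marginals
  A <- matrix(0, 4, 4)
  A[cbind(px$bin1_id + 1, px$bin2_id + 1)] <- px$count
  A <- A + t(A)
  rs <- rowSums(diag(w) %*% A %*% diag(w))
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-9)
})

test_that("balancing a random Poisson matrix gives uniform marginals away from ignored diagonals", {
  set.seed(42)
  n <- 50
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                   count = rpois(nrow(idx), 5))
  m <- balance_ic(contact_matrix(bins, px, 1e4), ignore_diags = 2,
                  madmax_threshold = Inf)
  w <- m$bins$weight
  # direct recomputation of marginals excluding diagonals 0 and 1
  keep <- px$bin2_id - px$bin1_id >= 2
  bal <- px$count[keep] * w[px$bin1_id[keep] + 1] * w[px$bin2_id[keep] + 1]
  marg <- numeric(n)
  for (k in which(keep)) {
    v <- px$count[k] * w[px$bin1_id[k] + 1] * w[px$bin2_id[k] + 1]
    marg[px$bin1_id[k] + 1] <- marg[px$bin1_id[k] + 1] + v
    marg[px$bin2_id[k] + 1] <- marg[px$bin2_id[k] + 1] + v
  }
  ok <- !is.na(w)
  expect_lt(max(abs(marg[ok] / mean(marg[ok]) - 1)), 1e-5)
})

test_that("MAD coverage filter masks a bin with hundredfold marginal", {
  set.seed(7)
  n <- 50
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  cnt <- rpois(nrow(idx), 5)
  hot <- idx[, 1] == 10 | idx[, 2] == 10
  cnt[hot] <- cnt[hot] * 100
  m0 <- contact_matrix(bins, data.frame(bin1_id = idx[, 1],
                                        bin2_id = idx[, 2], count = cnt), 1e4)
  # brute-force MAD of log10 marginals flags the hot bin at threshold 5
  A <- matrix(0, n, n)
  A[cbind(idx[, 1] + 1, idx[, 2] + 1)] <- cnt
  A <- A + t(A)
  lm <- log10(rowSums(A))
  madv <- median(abs(lm - median(lm)))
  expect_gt(abs(lm[11] - median(lm)), 5 * madv)
  m <- balance_ic(m0, ignore_diags = 0, madmax_threshold = 5)
  expect_true(is.na(m$bins$weight[11]))
  expect_false(anyNA(m$bins$weight[-11]))
})

test_that("balancing errors on degenerate input and reports non-convergence budget", {
  bins <- data.frame(chrom = "c", start = (0:3) * 1e4, end = (1:4) * 1e4)
  px <- data.frame(bin1_id = 0, bin2_id = 1, count = 0)
  expect_error(balance_ic(contact_matrix(bins, px, 1e4)), "degenerate")
})

test_that("balancing is idempotent: rebalancing balanced values leaves weights uniform", {
  set.seed(11)
  n <- 40
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                   count = rpois(nrow(idx), 8) *
                     exp(rnorm(n)[idx[, 1] + 1] + rnorm(n)[idx[, 2] + 1]))
  m1 <- balance_ic(contact_matrix(bins, px, 1e4), ignore_diags = 0,
                   madmax_threshold = Inf, tol = 1e-10)
  px2 <- px
  px2$count <- balanced_values(m1)
  m2 <- balance_ic(contact_matrix(bins, px2, 1e4), ignore_diags = 0,
                   madmax_threshold = Inf, tol = 1e-10)
  w2 <- m2$bins$weight
  expect_lt(max(w2) / min(w2) - 1, 1e-6)
})

test_that("expected equals exhaustive per-diagonal means on a hand-set toy", {
  set.seed(3)
  bins <- data.frame(chrom = rep(c("a", "b", "c"), each = 12),
                     start = rep((0:11) * 1e4, 3),
                     end = rep((1:12) * 1e4, 3))
  n <- nrow(bins)
  idx <- t(combn(0:(n - 1), 2))
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                   count = rpois(nrow(idx), 4))
  m <- contact_matrix(bins, px, 1e4)
  m$bins$weight <- 1
  m$bins$weight[5] <- NA   # one masked bin in region a
  view <- toy_view(m)
  ex <- compute_expected(m, view, ignore_diags = 0)
  for (r in 1:3) {
    ids0 <- which(bins$chrom == c("a", "b", "c")[r]) - 1L
    oracle <- oracle_diag_means(m, ids0)
    got <- ex$cis$avg_raw[ex$cis$region == view$name[r]]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # trans scalar equals the constant when the block is constant
  pxc <- px
  cross <- bins$chrom[px$bin1_id + 1] == "a" & bins$chrom[px$bin2_id + 1] == "b"
  pxc$count[cross] <- 7
  mc <- contact_matrix(bins, pxc, 1e4)
  mc$bins$weight <- 1
  exc <- compute_expected(mc, view, ignore_diags = 0)
  ab <- exc$trans[exc$trans$region1 == view$name[1] &
                    exc$trans$region2 == view$name[2], ]
  expect_equal(ab$avg, 7)
  expect_error(compute_expected(contact_matrix(bins, px, 1e4), view),
               "weights required")
})

test_that("a map whose balanced values follow a pure power law yields a power-law expected", {
  n <- 80
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  d <- idx[, 2] - idx[, 1]
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2], count = 3 * d^-1)
  m <- contact_matrix(bins, px, 1e4)
  m$bins$weight <- 1
  ex <- compute_expected(m, toy_view(m), ignore_diags = 1)
  cis <- ex$cis[ex$cis$dist >= 1, ]
  expect_equal(cis$avg_raw, 3 * cis$dist^-1, tolerance = 1e-12)
  # smoothed variant defined wherever raw is
  expect_true(all(is.na(cis$avg_smoothed) == is.na(cis$avg_raw)))
})

test_that("observed/expected self-normalizes every diagonal and drops masked rows", {
  set.seed(9)
  n <- 60
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                   count = rpois(nrow(idx), 6) + 1)
  m <- contact_matrix(bins, px, 1e4)
  m$bins$weight <- runif(n, 0.5, 2)
  m$bins$weight[c(8, 30)] <- NA
  view <- toy_view(m)
  ex <- compute_expected(m, view, ignore_diags = 0)
  oe <- observed_over_expected(m, ex, view)
  d <- oe$pixels$bin2_id - oe$pixels$bin1_id
  sums <- tapply(oe$pixels$oe, d, sum)
  nv <- ex$cis$n_valid[match(as.integer(names(sums)), ex$cis$dist)]
  expect_lt(max(abs(as.numeric(sums) / nv - 1)), 1e-12)
  expect_false(any(oe$pixels$bin1_id %in% c(7, 29) |
                     oe$pixels$bin2_id %in% c(7, 29)))
})

test_that("masking one more bin leaves pixels not touching it unchanged", {
  set.seed(10)
  n <- 40
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2],
                   count = rpois(nrow(idx), 5) + 1)
  m <- contact_matrix(bins, px, 1e4)
  m$bins$weight <- 1
  view <- toy_view(m)
  ex <- compute_expected(m, view, ignore_diags = 0)
  oe1 <- observed_over_expected(m, ex, view)
  m2 <- m
  m2$bins$weight[15] <- NA
  oe2 <- observed_over_expected(m2, ex, view)   # same expected
  k1 <- paste(oe1$pixels$bin1_id, oe1$pixels$bin2_id)
  k2 <- paste(oe2$pixels$bin1_id, oe2$pixels$bin2_id)
  shared <- intersect(k1, k2)
  expect_equal(oe1$pixels$oe[match(shared, k1)],
               oe2$pixels$oe[match(shared, k2)])
  expect_false(any(oe2$pixels$bin1_id == 14 | oe2$pixels$bin2_id == 14))
})

test_that("contact scaling recovers a pure power-law exponent to three decimals", {
  n <- 200
  bins <- data.frame(chrom = "c", start = (0:(n - 1)) * 1e4, end = (1:n) * 1e4)
  idx <- t(combn(0:(n - 1), 2))
  d <- idx[, 2] - idx[, 1]
  px <- data.frame(bin1_id = idx[, 1], bin2_id = idx[, 2], count = 10 * d^-1.2)
  m <- contact_matrix(bins, px, 1e4)
  m$bins$weight <- 1
  sc <- contact_scaling(m, toy_view(m), smooth = FALSE, ignore_diags = 1)
  interior <- 2:(length(sc$slope) - 1)
  expect_lt(max(abs(sc$slope[interior] + 1.2)), 1e-3)

  # aggregating two identical arms reproduces the single-arm curve
  bins2 <- rbind(bins, transform(bins, chrom = "c2"))
  px2 <- rbind(px, transform(px, bin1_id = bin1_id + n, bin2_id = bin2_id + n))
  m2 <- contact_matrix(bins2, px2, 1e4)
  m2$bins$weight <- 1
  sc2 <- contact_scaling(m2, toy_view(m2), smooth = FALSE, ignore_diags = 1)
  expect_equal(sc2$P, sc$P, tolerance = 1e-12)

  expect_error(contact_scaling(contact_matrix(bins[1:3, ],
    data.frame(bin1_id = 0, bin2_id = 1, count = 1), 1e4) |>
      (\(x) { x$bins$weight <- 1; x })(), genome_view("c", 0, 3e4),
    smooth = FALSE, ignore_diags = 0), "fewer than 3")
})

test_that("a planted extruded-loop shoulder is located near its true position", {
  spec <- synthetic_genome_spec(chrom_sizes = c(chr1 = 20e6),
                                loop_shoulder_bp = 100e3, n_mcds = 0,
                                compartment_contrast = 1, depth = 1e7,
                                seed = 7)
  sim <- simulate_contact_map(spec)
  m <- balance_ic(sim$matrix)
  sc <- contact_scaling(m, spec_view(spec))
  expect_true(is.finite(sc$shoulder_bp))
  expect_gte(sc$shoulder_bp, 50e3)
  expect_lte(sc$shoulder_bp, 200e3)
})

test_that("contact matrices and views round-trip through the text formats", {
  fx <- toy_uniform_matrix(10)
  pre <- file.path(tempdir(), "mtest")
  write_contacts(fx, pre)
  back <- read_contacts(pre)
  expect_equal(back$pixels, fx$pixels)
  expect_equal(back$bins$start, fx$bins$start)
  v <- toy_view(fx)
  vp <- file.path(tempdir(), "vtest.tsv")
  write_view(v, vp)
  expect_equal(read_view(vp)$end, v$end)
})
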