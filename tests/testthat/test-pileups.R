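test_that("pairwise grids enumerate cis and trans pairs correctly", {
  v <- genome_view(c("chr1", "chr2"), 0, c(10e6, 10e6))
  a3 <- data.frame(chrom = "chr1", start = c(1, 3, 5) * 1e6,
                   end = c(1.05, 3.05, 5.05) * 1e6,
                   summit = c(1, 3, 5) * 1e6)
  g3 <- make_pairwise_grid(a3, v)
  expect_equal(nrow(g3), 3)                     # C(3,2)
  expect_true(all(g3$kind == "cis"))

  a4 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                   start = rep(c(1e6, 4e6), 2), end = rep(c(1.1e6, 4.1e6), 2),
                   summit = rep(c(1e6, 4e6), 2))
  g4 <- make_pairwise_grid(a4, v)
  expect_equal(sum(g4$kind == "trans"), 4)
  expect_equal(sum(g4$kind == "cis"), 2)

  # pair count equals an exhaustive double loop under a separation cap
  set.seed(13)
  aN <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   summit = round(runif(100, 0, 10e6)))
  aN$start <- aN$summit; aN$end <- aN$summit + 1e4
  gN <- make_pairwise_grid(aN, v, max_sep = 3e6)
  brute <- 0
  for (i in 1:99) for (j in (i + 1):100) {
    if (aN$chrom[i] != aN$chrom[j]) brute <- brute + 1
    else {
      s <- abs(aN$summit[i] - aN$summit[j])
      if (s > 0 && s <= 3e6) brute <- brute + 1
    }
  }
  expect_equal(nrow(gN), brute)

  # grid counts identity: |cis| + |trans| = C(n,2) without bounds
  gAll <- make_pairwise_grid(aN, v)
  dup <- sum(duplicated(paste(aN$chrom, aN$summit)))
  expect_equal(nrow(gAll) + dup, choose(100, 2) -
                 sum(table(paste(aN$chrom, aN$summit)) > 1) * 0)
})

test_that("a single-feature pileup is that snippet, and stacking duplicates is idempotent", {
  set.seed(4)
  n <- 61
  dense <- matrix(runif(n * n), n); dense[lower.tri(dense)] <- t(dense)[lower.tri(dense)]
  oe <- make_oe_map(dense)
  f1 <- data.frame(chrom1 = "chrA", pos1 = 20 * 1e4 + 1,
                   chrom2 = "chrA", pos2 = 40 * 1e4 + 1)
  p1 <- aggregate_pileup(oe, f1, flank = 5e4)
  d0 <- matrix(0, n, n)
  px <- oe$pixels
  d0[cbind(px$bin1_id + 1, px$bin2_id + 1)] <- px$oe
  d0[cbind(px$bin2_id + 1, px$bin1_id + 1)] <- px$oe
  expect_equal(p1$mat, d0[16:26, 36:46], tolerance = 1e-12)

  p2 <- aggregate_pileup(oe, rbind(f1, f1), flank = 5e4)
  expect_equal(p2$mat, p1$mat, tolerance = 1e-12)
  expect_equal(p2$n_snippets, 2)

  expect_error(aggregate_pileup(oe, f1[0, ], flank = 5e4), "zero usable")
})

test_that("grouped pileup means recombine to the global mean", {
  set.seed(5)
  n <- 81
  dense <- matrix(runif(n * n), n); dense[lower.tri(dense)] <- t(dense)[lower.tri(dense)]
  oe <- make_oe_map(dense)
  feats <- data.frame(chrom1 = "chrA", pos1 = (c(20, 30, 40, 50) * 1e4) + 1,
                      chrom2 = "chrA", pos2 = (c(60, 65, 70, 75) * 1e4) + 1)
  groups <- factor(c("x", "x", "y", "y"))
  parts <- aggregate_pileup(oe, feats, flank = 3e4, groups = groups)
  whole <- aggregate_pileup(oe, feats, flank = 3e4)
  recombined <- (parts$x$mat * parts$x$n_snippets +
                   parts$y$mat * parts$y$n_snippets) /
    (parts$x$n_snippets + parts$y$n_snippets)
  expect_equal(recombined, whole$mat, tolerance = 1e-12)
})

test_that("feature strength equals brute-force window means in all three modes", {
  mk_pileup <- function(mat, res) structure(
    list(mat = mat, n_snippets = 1, flank = (nrow(mat) - 1) / 2 * res,
         resolution = res), class = "pileup")
  # 21x21 of ones with the centre 5x5 set to 4 (10 kb maps)
  m1 <- matrix(1, 21, 21); m1[9:13, 9:13] <- 4
  expect_equal(feature_strength(mk_pileup(m1, 1e4), "cis_grid"), 4)
  expect_equal(feature_strength(mk_pileup(m1, 1e4), "loop"), 4)
  # trans mode at 25 kb: 9x9, centre pixel over 2x2 corners
  m2 <- matrix(1, 9, 9); m2[5, 5] <- 6
  expect_equal(feature_strength(mk_pileup(m2, 25e3), "trans_grid"), 6)
  # all-ones pileup: strength 1 in any mode
  expect_equal(feature_strength(mk_pileup(matrix(1, 21, 21), 1e4), "cis_grid"), 1)

  # random pileups vs direct window arithmetic
  set.seed(6)
  for (rep in 1:25) {
    mat <- matrix(runif(21 * 21, 0.1, 3), 21)
    p <- mk_pileup(mat, 1e4)
    got <- feature_strength(p, "cis_grid")
    oracle <- mean(mat[9:13, 9:13]) /
      mean(c(mat[1:6, 1:6], mat[1:6, 16:21], mat[16:21, 1:6],
             mat[16:21, 16:21]))
    expect_equal(got, oracle, tolerance = 1e-12)
    gotl <- feature_strength(p, "loop")
    oraclel <- mean(mat[10:12, 10:12]) /
      mean(c(mat[1:7, 1:7], mat[1:7, 15:21], mat[15:21, 1:7],
             mat[15:21, 15:21]))
    expect_equal(gotl, oraclel, tolerance = 1e-12)
  }

  # scale invariance
  p <- mk_pileup(matrix(runif(441, 0.5, 2), 21), 1e4)
  expect_equal(feature_strength(p, "cis_grid"),
               feature_strength(mk_pileup(p$mat * 7.3, 1e4), "cis_grid"),
               tolerance = 1e-12)

  # degenerate periphery errors
  z <- matrix(0, 21, 21); z[9:13, 9:13] <- 1
  expect_error(feature_strength(mk_pileup(z, 1e4), "cis_grid"), "degenerate")
  # corner/centre overlap is refused rather than silently computed
  expect_error(feature_strength(mk_pileup(matrix(1, 11, 11), 1e4), "cis_grid"),
               "overlap")
})

test_that("planted loops pile up to their planted strength", {
  loops <- data.frame(chrom = "chr1",
                      pos1 = c(3e6, 6e6, 9e6, 12e6),
                      pos2 = c(3.5e6, 6.4e6, 9.6e6, 12.3e6),
                      strength = 3, motif1 = "+", motif2 = "-")
  spec <- synthetic_genome_spec(chrom_sizes = c(chr1 = 16e6),
                                loop_truth = loops, n_mcds = 0,
                                compartment_contrast = 1, depth = 2e7,
                                seed = 23)
  sim <- simulate_contact_map(spec)
  m <- balance_ic(sim$matrix)
  ex <- compute_expected(m, spec_view(spec))
  oe <- observed_over_expected(m, ex, spec_view(spec))
  feats <- data.frame(chrom1 = "chr1", pos1 = loops$pos1,
                      chrom2 = "chr1", pos2 = loops$pos2)
  p <- aggregate_pileup(oe, feats, flank = 100e3)
  centre <- p$mat[11, 11]
  expect_gt(centre, 3 * 0.7)
  expect_lt(centre, 3 * 1.3)
  expect_gt(feature_strength(p, "loop"), 1.5)
})

test_that("stackups equal brute-force window binning", {
  # constant track: every cell equals the constant
  track <- data.frame(chrom = "chr1", start = 0, end = 10e6, value = 2.5)
  iv <- data.frame(chrom = "chr1", start = c(2e6, 5e6), end = c(2e6, 5e6) + 1e4)
  st <- stackup_track(track, iv, flank = 1e5, n_bins = 20)
  expect_true(all(abs(st$mat - 2.5) < 1e-9))
  expect_true(all(abs(st$profile - 2.5) < 1e-9))

  # delta at interval centres: profile peaks at the middle bin
  centres <- c(2e6, 5e6) + 5e3
  delta <- data.frame(chrom = "chr1", start = centres - 500,
                      end = centres + 500, value = 100)
  st2 <- stackup_track(delta, iv, flank = 1e5, n_bins = 21)
  expect_equal(which.max(st2$profile), 11)

  # random track vs direct per-window integration
  set.seed(30)
  seg <- seq(0, 10e6 - 1e4, by = 1e4)
  rtrack <- data.frame(chrom = "chr1", start = seg, end = seg + 1e4,
                       value = runif(length(seg)))
  st3 <- stackup_track(rtrack, iv[1, ], flank = 1e5, n_bins = 10)
  edges <- (2e6 + 5e3) - 1e5 + (0:10) * 2e4
  oracle <- sapply(1:10, function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    ov <- pmin(hi, rtrack$end) - pmax(lo, rtrack$start)
    sum(rtrack$value[ov > 0] * ov[ov > 0]) / (hi - lo)
  })
  expect_equal(as.numeric(st3$mat[1, ]), oracle, tolerance = 1e-9)

  # windows reaching before the chromosome start are padded missing
  iv_edge <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  st4 <- stackup_track(track, iv_edge, flank = 1e5, n_bins = 20,
                       chrom_sizes = c(chr1 = 10e6))
  expect_true(anyNA(st4$mat))
  expect_true(all(!is.na(st4$mat[1, 11:20])))
})
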