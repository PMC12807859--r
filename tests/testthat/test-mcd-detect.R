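test_that("kernel scores are exact footprint means, verified against brute force", {
  set.seed(21)
  n <- 60
  dense <- matrix(runif(n * n, 0.5, 2), n)
  dense[lower.tri(dense)] <- t(dense)[lower.tri(dense)]
  dense[, 12] <- dense[12, ] <- NA       # one masked bin
  oe <- make_oe_map(abs(dense), weight = replace(rep(1, n), 12, NA))
  ks <- kernel_set(1, 3)
  sc <- score_pixels(oe, ks, max_dist = Inf)
  d0 <- matrix(NA_real_, n, n)
  px <- oe$pixels
  d0[cbind(px$bin1_id + 1, px$bin2_id + 1)] <- px$oe
  d0[cbind(px$bin2_id + 1, px$bin1_id + 1)] <- px$oe
  d0[is.na(d0)] <- 0
  d0[, 12] <- d0[12, ] <- NA
  samp <- sc[sample(nrow(sc), 50), ]
  for (k in seq_len(nrow(samp))) {
    i <- samp$bin1_id[k] + 1; j <- samp$bin2_id[k] + 1
    expect_equal(samp$M[k], oracle_footprint_mean(d0, i, j, ks$M),
                 tolerance = 1e-9)
    expect_equal(samp$V[k], oracle_footprint_mean(d0, i, j, ks$V),
                 tolerance = 1e-9)
    expect_equal(samp$H[k], oracle_footprint_mean(d0, i, j, ks$H),
                 tolerance = 1e-9)
  }
})

test_that("kernel scores are flat on a uniform map and localized on a planted block", {
  n <- 50
  dense <- matrix(1, n, n)
  oe <- make_oe_map(dense)
  sc <- score_pixels(oe, kernel_set(1, 3), max_dist = Inf)
  away <- sc$bin2_id - sc$bin1_id > 8   # pixels whose flanks stay in-matrix
  inner <- away & sc$bin1_id >= 8 & sc$bin2_id <= n - 9
  expect_true(all(abs(sc$M[inner] - 1) < 1e-12))
  expect_true(all(abs(sc$V[inner] - 1) < 1e-12))
  expect_true(all(abs(sc$H[inner] - 1) < 1e-12))

  # a 3x3 block fully inside M but clear of the flanks (which start
  # 2 bins out for these kernels)
  dense2 <- matrix(1, n, n)
  dense2[21:23, 36:38] <- 4
  dense2[36:38, 21:23] <- 4
  oe2 <- make_oe_map(dense2)
  sc2 <- score_pixels(oe2, kernel_set(1, 3), max_dist = Inf)
  centre <- sc2[sc2$bin1_id == 21 & sc2$bin2_id == 36, ]
  expect_equal(centre$M, 4, tolerance = 1e-12)
  expect_equal(centre$V, 1, tolerance = 1e-12)
  expect_equal(centre$H, 1, tolerance = 1e-12)
})

test_that("the separation scan limit excludes pixels beyond max_dist", {
  n <- 40
  dense <- matrix(1, n, n)
  oe <- make_oe_map(dense, resolution = 1e6)   # 1 Mb bins
  sc <- score_pixels(oe, kernel_set(1, 3), max_dist = 30e6)
  expect_true(all((sc$bin2_id - sc$bin1_id) * 1e6 <= 30e6))
  expect_false(any(sc$bin2_id - sc$bin1_id == 31))
})

test_that("selection threshold is inclusive and small groups are discarded", {
  scored <- data.frame(bin1_id = 0L, bin2_id = 10L, oe = 2,
                       M = 2.0, V = 1.0, H = 0.9)
  kept <- select_and_cluster(scored, ratio = 2, min_samples = 1,
                             max_eps = 33e3, resolution = 1e4)
  expect_equal(nrow(kept), 1)   # boundary M = 2V retained

  # 4 mutually adjacent retained pixels but min_samples = 5: all dropped
  scored4 <- data.frame(bin1_id = c(0, 0, 1, 1), bin2_id = c(10, 11, 10, 11),
                        oe = 3, M = 3, V = 1, H = 1)
  expect_message(
    kept4 <- select_and_cluster(scored4, ratio = 2, min_samples = 5,
                                max_eps = 33e3, resolution = 1e4),
    NA)
  expect_equal(nrow(kept4), 0)
})

test_that("density clustering matches exhaustive single-linkage at the 33 kb reach", {
  set.seed(8)
  # two blocks of retained pixels 10 bins apart plus sparse bridge pixels
  b1 <- expand.grid(bin1_id = 5:9, bin2_id = 40:44)
  b2 <- expand.grid(bin1_id = 19:23, bin2_id = 40:44)
  px <- rbind(b1, b2)
  scored <- data.frame(px, oe = 5, M = 5, V = 1, H = 1)
  out <- select_and_cluster(scored, ratio = 2, min_samples = 5,
                            max_eps = 33e3, resolution = 1e4)
  expect_equal(length(unique(out$cluster)), 2)
  oracle <- oracle_single_linkage(scored$bin1_id, scored$bin2_id, 3)
  # same partition (every oracle group maps to exactly one cluster id)
  key <- tapply(out$cluster, oracle[match(paste(out$bin1_id, out$bin2_id),
                                          paste(scored$bin1_id, scored$bin2_id))],
                function(z) length(unique(z)))
  expect_true(all(key == 1))
})

test_that("anchor calling turns clustered pixels into summits and footprints", {
  # one isolated cluster, all pixels sharing row bin 7
  cl <- data.frame(bin1_id = 7L, bin2_id = 30:37, oe = 5, M = 5, V = 1,
                   H = 1, cluster = 1L)
  bins <- data.frame(chrom = "chrA", start = (0:59) * 1e4, end = (1:60) * 1e4)
  a <- call_mcd_anchors(cl, bins, 1e4, prominence = 3, min_width = 0,
                        max_width = Inf)
  expect_true(7L %in% a$summit_bin)

  # all-zero valency: empty result
  empty <- cl[0, ]
  expect_equal(nrow(call_mcd_anchors(empty, bins, 1e4)), 0)
})

test_that("detection output is invariant to transposing the pixel list", {
  fx <- default_sim()
  oe <- fx$oe
  sc <- mcdtools:::score_pixels_region(oe, 1, kernel_set(), 30e6)
  cl1 <- select_and_cluster(sc, resolution = 1e4)
  # transpose: swap bin1/bin2 of the scored pixels (and V/H accordingly)
  sc_t <- data.frame(bin1_id = sc$bin2_id, bin2_id = sc$bin1_id,
                     oe = sc$oe, M = sc$M, V = sc$H, H = sc$V)
  cl2 <- select_and_cluster(sc_t, resolution = 1e4)
  a1 <- call_mcd_anchors(cl1, fx$m$bins, 1e4)
  a2 <- call_mcd_anchors(data.frame(bin1_id = cl2$bin2_id,
                                    bin2_id = cl2$bin1_id,
                                    oe = cl2$oe, M = cl2$M, V = cl2$H,
                                    H = cl2$V, cluster = cl2$cluster),
                         fx$m$bins, 1e4)
  expect_equal(a1$summit_bin, a2$summit_bin)
  expect_equal(a1$start, a2$start)
})

test_that("recall is non-decreasing in planted affinity", {
  recalls <- vapply(c(1.5, 4), function(aff) {
    spec <- synthetic_genome_spec(chrom_sizes = c(chr1 = 20e6),
                                  n_mcds = 10, mcd_affinity = aff,
                                  depth = 7e6, seed = 41)
    sim <- simulate_contact_map(spec)
    m <- balance_ic(sim$matrix)
    det <- detect_mcds(m, compute_expected(m, spec_view(spec)),
                       spec_view(spec))
    if (!nrow(det$anchors)) return(0)
    recovery_metrics(det$anchors, sim$truth$mcd_truth, 1e4)$recall
  }, numeric(1))
  expect_true(recalls[2] >= recalls[1])
  expect_gte(recalls[2], 0.7)
})

test_that("anchor set comparison partitions exhaustively and reproduces the printed shared fraction", {
  a <- data.frame(chrom = "chr1", start = c(1e5, 5e5, 9e5),
                  end = c(2e5, 6e5, 10e5))
  cmp_same <- compare_anchor_sets(a, a)
  expect_equal(cmp_same$summary$n_a_shared, 3)
  expect_equal(nrow(cmp_same$a_specific), 0)

  b <- data.frame(chrom = "chr2", start = c(1e5), end = c(2e5))
  cmp_dis <- compare_anchor_sets(a, b)
  expect_equal(cmp_dis$summary$n_a_shared, 0)
  expect_equal(cmp_dis$summary$n_b_shared, 0)
  expect_equal(nrow(cmp_dis$a_specific) + nrow(cmp_dis$b_specific), 4)

  # the printed cytokinesis bookkeeping: 1,218 shared of 1,791 is 68%
  expect_equal(round(100 * 1218 / 1791), 68)
})
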