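#' Specification of a synthetic Hi-C genome
#'
#' Describes a desk-scale genome and the structures planted in its contact
#' map: a power-law distance decay with an optional extruded-loop shoulder,
#' an A/B checkerboard acting in cis and trans, a set of small high-affinity
#' microcompartment domains (MCDs) interacting at all distances and between
#' chromosomes, focal convergent-CTCF loops, and Poisson sequencing noise.
#' The expected intensity of a cis pixel (i, j) at separation s bins is
#' `ps_scale * s^-ps_exponent * C(i,j) * L(i,j) * M(i,j)` and of a trans
#' pixel `trans_base * C(i,j) * M(i,j)`, where `C = contrast^(p_i * p_j)`
#' with p the per-bin compartment profile in \[-1, 1\] (equal to the
#' same-label/opposite-label contrast rule when the profile is hard +/-1),
#' `M = affinity_i * affinity_j` over MCD bins and `L` multiplies loop
#' pixels (1-bin Gaussian halo) by their strength. Intensities are globally
#' scaled so their sum equals `depth`, then Poisson-sampled.
#'
#' Defaults model a 3 x 20 Mb genome at 10 kb (6,000 bins) with compartment
#' blocks of 0.8-1.7 Mb at contrast 1.8, 30 planted MCDs of width 25-125 kb
#' and affinity 4, no loops, ~12% trans contacts and 2e7 total counts.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param resolution bin size (bp).
#' @param ps_exponent power-law decay exponent (positive; slope is its
#'   negative).
#' @param ps_scale decay amplitude (arbitrary units; depth sets the scale).
#' @param loop_shoulder_bp position of the extruded-loop shoulder in P(s)
#'   (a Gaussian bump of the log-log slope centred there), or NULL for a
#'   pure power law.
#' @param shoulder_strength,shoulder_sigma bump height (slope units) and
#'   width (natural-log units).
#' @param compartment_profile optional per-bin profile in \[-1, 1\]; when
#'   NULL, an alternating +/-1 block wave with block lengths uniform in
#'   `compartment_block_bp` is drawn and Gaussian-smoothed with
#'   `profile_edge_bins` (compartment identity at 10 kb changes gradually
#'   over ~100 kb in real maps, never as a step).
#' @param compartment_contrast checkerboard contrast (>= 1).
#' @param compartment_block_bp length-2 range of block lengths (bp).
#' @param profile_edge_bins Gaussian sd (bins) of the block-edge smoothing
#'   applied to the auto-generated profile.
#' @param mcd_truth optional data.frame (chrom, start, end, affinity); when
#'   NULL, `n_mcds` non-overlapping domains with widths uniform in
#'   `mcd_width_range` and affinity `mcd_affinity` are placed; pass a
#'   zero-row data.frame for none.
#' @param n_mcds,mcd_affinity,mcd_width_range automatic MCD placement
#'   parameters.
#' @param loop_truth data.frame (chrom, pos1, pos2, strength, motif1,
#'   motif2) of intra-chromosomal loops (pos1 < pos2, bp).
#' @param trans_base trans intensity per bin pair (same units as ps_scale).
#' @param bias_sd standard deviation (natural-log scale) of the
#'   multiplicative per-bin coverage bias (mappability/GC-style), which the
#'   intensity model applies as `b_i * b_j`. Iterative correction removes
#'   it; 0 disables.
#' @param depth expected total contact count.
#' @param dispersion NULL for Poisson sampling; otherwise the negative
#'   binomial size parameter (overdispersion switch).
#' @param seed integer seed governing both structure placement and sampling.
#' @return a `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(chrom_sizes = c(chr1 = 20e6, chr2 = 20e6, chr3 = 20e6),
                                  resolution = 10e3,
                                  ps_exponent = 1.0, ps_scale = 1.0,
                                  loop_shoulder_bp = NULL,
                                  shoulder_strength = 0.6, shoulder_sigma = 0.5,
                                  compartment_profile = NULL,
                                  compartment_contrast = 1.8,
                                  compartment_block_bp = c(0.8e6, 1.7e6),
                                  profile_edge_bins = 5,
                                  mcd_truth = NULL, n_mcds = 30,
                                  mcd_affinity = 4,
                                  mcd_width_range = c(25e3, 125e3),
                                  loop_truth = NULL,
                                  trans_base = 5e-4, bias_sd = 0.2,
                                  depth = 2e7,
                                  dispersion = NULL, seed = 1) {
  stopifnot(compartment_contrast >= 1, depth > 0, trans_base > 0)
  bins <- make_bins(chrom_sizes, resolution)
  n <- nrow(bins)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)

  if (is.null(compartment_profile)) {
    compartment_profile <- numeric(0)
    for (ch in names(chrom_sizes)) {
      nb <- sum(bins$chrom == ch)
      prof <- numeric(0)
      sign_cur <- 1
      while (length(prof) < nb) {
        len <- round(stats::runif(1, compartment_block_bp[1],
                                  compartment_block_bp[2]) / resolution)
        prof <- c(prof, rep(sign_cur, len))
        sign_cur <- -sign_cur
      }
      prof <- prof[seq_len(nb)]
      if (profile_edge_bins > 0) {
        half <- ceiling(3 * profile_edge_bins)
        kern <- stats::dnorm(-half:half, sd = profile_edge_bins)
        kern <- kern / sum(kern)
        padded <- c(rep(prof[1], half), prof, rep(prof[nb], half))
        prof <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + nb)]
      }
      compartment_profile <- c(compartment_profile, as.numeric(prof))
    }
  }
  stopifnot(length(compartment_profile) == n,
            all(abs(compartment_profile) <= 1 + 1e-9))

  if (is.null(mcd_truth)) {
    mcd_truth <- place_random_mcds(chrom_sizes, n_mcds, mcd_width_range,
                                   mcd_affinity)
  }
  mcd_truth <- as.data.frame(mcd_truth)
  if (nrow(mcd_truth)) {
    stopifnot(all(c("chrom", "start", "end", "affinity") %in% names(mcd_truth)),
              all(mcd_truth$affinity >= 1),
              all(mcd_truth$end <= chrom_sizes[mcd_truth$chrom]),
              all(mcd_truth$start >= 0), all(mcd_truth$end > mcd_truth$start))
  }
  if (is.null(loop_truth))
    loop_truth <- data.frame(chrom = character(0), pos1 = numeric(0),
                             pos2 = numeric(0), strength = numeric(0),
                             motif1 = character(0), motif2 = character(0))
  loop_truth <- as.data.frame(loop_truth)
  if (nrow(loop_truth))
    stopifnot(all(loop_truth$pos1 < loop_truth$pos2),
              all(loop_truth$strength >= 1))

  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 ps_exponent = ps_exponent, ps_scale = ps_scale,
                 loop_shoulder_bp = loop_shoulder_bp,
                 shoulder_strength = shoulder_strength,
                 shoulder_sigma = shoulder_sigma,
                 compartment_profile = compartment_profile,
                 compartment_contrast = compartment_contrast,
                 mcd_truth = mcd_truth, loop_truth = loop_truth,
                 trans_base = trans_base, bias_sd = bias_sd, depth = depth,
                 dispersion = dispersion, seed = seed, bins = bins),
            class = "synthetic_genome_spec")
}

# Non-overlapping random placement, >= 200 kb from chromosome ends and
# >= 200 kb apart; MCD counts split evenly across chromosomes.
place_random_mcds <- function(chrom_sizes, n_mcds, width_range, affinity) {
  if (n_mcds == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), affinity = numeric(0)))
  per <- diff(round(seq(0, n_mcds, length.out = length(chrom_sizes) + 1)))
  out <- list()
  margin <- 2e5; gap <- 2e5
  for (ci in seq_along(chrom_sizes)) {
    k <- per[ci]
    if (k == 0) next
    size <- chrom_sizes[[ci]]
    widths <- stats::runif(k, width_range[1], width_range[2])
    # place with guaranteed gaps: distribute the leftover space uniformly
    slack <- size - 2 * margin - sum(widths) - (k - 1) * gap
    if (slack < 0) stop("could not place MCDs; chromosome too crowded")
    u <- sort(stats::runif(k, 0, slack))
    starts <- margin + u + c(0, cumsum(widths[-k] + gap))
    ends <- starts + widths
    out[[ci]] <- data.frame(chrom = names(chrom_sizes)[ci],
                            start = floor(starts), end = ceiling(ends),
                            affinity = affinity, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# shoulder multiplier on P(s): exp(b*sigma*sqrt(2*pi)*Phi(log(s/s0)/sigma)),
# whose log-log derivative is a Gaussian bump of height b centred at s0.
shoulder_factor <- function(s_bp, s0, b, sigma) {
  if (is.null(s0)) return(rep(1, length(s_bp)))
  exp(b * sigma * sqrt(2 * pi) * stats::pnorm(log(s_bp / s0) / sigma))
}

#' Simulate a contact map with planted structures
#'
#' Draws a [contact_matrix()] of Poisson (or negative binomial) counts from
#' the intensity model described in [synthetic_genome_spec()], and returns
#' the planted ground truth alongside. Identical spec and seed give
#' byte-identical pixel tables. Cis pixels are emitted at separations of at
#' least one bin (the main diagonal carries no information used downstream
#' and the first diagonals are excluded from balancing).
#'
#' @param spec a [synthetic_genome_spec()].
#' @return list(matrix = [contact_matrix()], truth = `synthetic_truth`
#'   carrying the spec echo, per-bin compartment labels and profile, MCD bin
#'   sets and loop pixel coordinates).
#' @export
simulate_contact_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  bins <- spec$bins
  n <- nrow(bins)
  res <- spec$resolution
  p <- spec$compartment_profile
  logc <- log(spec$compartment_contrast)

  # a_i = affinity on MCD bins, 0 elsewhere: pmax(a_i * a_j, 1) is then the
  # MCD-by-MCD factor (affinity_i * affinity_j where both bins lie in MCDs,
  # 1 otherwise; affinities are >= 1). The factor acts between *distinct*
  # MCDs only — the planted feature is the off-diagonal interaction grid,
  # not a self-interaction block.
  aff <- rep(0, n)
  mcd_id <- rep(0L, n)
  mcd_bin_sets <- vector("list", nrow(spec$mcd_truth))
  offs <- chrom_offsets(bins)
  for (k in seq_len(nrow(spec$mcd_truth))) {
    mt <- spec$mcd_truth[k, ]
    lo <- offs[[mt$chrom]] + floor(mt$start / res)
    hi <- offs[[mt$chrom]] + ceiling(mt$end / res) - 1
    ids <- lo:hi
    aff[ids + 1L] <- mt$affinity
    mcd_id[ids + 1L] <- k
    mcd_bin_sets[[k]] <- ids
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed %% .Machine$integer.max)
  bias <- if (spec$bias_sd > 0) exp(stats::rnorm(n, 0, spec$bias_sd)) else rep(1, n)

  chroms <- names(spec$chrom_sizes)
  nb <- vapply(chroms, function(ch) sum(bins$chrom == ch), integer(1))
  lam_list <- list(); idx_list <- list()
  loop_px <- list()

  for (ci in seq_along(chroms)) {
    nn <- nb[ci]; lo <- offs[[chroms[ci]]]
    cnt <- (nn - 1):1
    iv <- rep(0:(nn - 2), cnt)
    dv <- sequence(cnt)
    jv <- iv + dv
    decay <- spec$ps_scale * (1:(nn - 1))^(-spec$ps_exponent) *
      shoulder_factor((1:(nn - 1)) * res, spec$loop_shoulder_bp,
                      spec$shoulder_strength, spec$shoulder_sigma)
    gi <- iv + lo + 1L; gj <- jv + lo + 1L
    mfac <- ifelse(mcd_id[gi] > 0 & mcd_id[gj] > 0 & mcd_id[gi] != mcd_id[gj],
                   aff[gi] * aff[gj], 1)
    lam <- decay[dv] * exp(logc * p[gi] * p[gj]) * mfac *
      bias[gi] * bias[gj]
    lt <- spec$loop_truth[spec$loop_truth$chrom == chroms[ci], , drop = FALSE]
    for (k in seq_len(nrow(lt))) {
      a1 <- floor(lt$pos1[k] / res); a2 <- floor(lt$pos2[k] / res)
      halo <- expand.grid(di = -3:3, dj = -3:3)
      ii <- a1 + halo$di; jj <- a2 + halo$dj
      ok <- ii >= 0 & jj < nn & ii < jj
      f <- 1 + (lt$strength[k] - 1) * exp(-(halo$di^2 + halo$dj^2) / 2)
      ii <- ii[ok]; jj <- jj[ok]; f <- f[ok]
      pos <- ii * (2 * nn - ii - 1) / 2 + (jj - ii)
      lam[pos] <- lam[pos] * f
      loop_px[[length(loop_px) + 1L]] <-
        data.frame(bin1_id = a1 + lo, bin2_id = a2 + lo,
                   strength = lt$strength[k])
    }
    lam_list[[length(lam_list) + 1L]] <- lam
    idx_list[[length(idx_list) + 1L]] <- cbind(iv + lo, jv + lo)
  }

  if (length(chroms) > 1) {
    for (ci in 1:(length(chroms) - 1)) for (cj in (ci + 1):length(chroms)) {
      lo1 <- offs[[chroms[ci]]]; lo2 <- offs[[chroms[cj]]]
      id1 <- lo1 + 0:(nb[ci] - 1); id2 <- lo2 + 0:(nb[cj] - 1)
      lam <- spec$trans_base *
        exp(logc * outer(p[id1 + 1L], p[id2 + 1L])) *
        pmax(outer(aff[id1 + 1L], aff[id2 + 1L]), 1) *
        outer(bias[id1 + 1L], bias[id2 + 1L])
      lam_list[[length(lam_list) + 1L]] <- as.numeric(lam)
      idx_list[[length(idx_list) + 1L]] <-
        cbind(rep(id1, times = nb[cj]), rep(id2, each = nb[ci]))
    }
  }

  tot <- sum(vapply(lam_list, sum, numeric(1)))
  scale <- spec$depth / tot

  px_list <- vector("list", length(lam_list))
  any_pos <- FALSE
  for (b in seq_along(lam_list)) {
    lam <- lam_list[[b]] * scale
    cnt <- if (is.null(spec$dispersion)) stats::rpois(length(lam), lam)
           else stats::rnbinom(length(lam), size = spec$dispersion, mu = lam)
    nz <- which(cnt > 0)
    any_pos <- any_pos || length(nz) > 0
    px_list[[b]] <- data.frame(bin1_id = idx_list[[b]][nz, 1],
                               bin2_id = idx_list[[b]][nz, 2],
                               count = cnt[nz])
  }
  if (!any_pos) warning("depth too low: simulated map has no nonzero pixel")

  mat <- contact_matrix(bins, do.call(rbind, px_list), res)
  truth <- structure(list(
    spec = spec,
    labels = ifelse(p >= 0, "A", "B"),
    profile = p,
    bias = bias,
    mcd_truth = spec$mcd_truth,
    mcd_bins = mcd_bin_sets,
    loop_pixels = if (length(loop_px)) do.call(rbind, loop_px)
                  else data.frame(bin1_id = integer(0), bin2_id = integer(0),
                                  strength = numeric(0))),
    class = "synthetic_truth")
  list(matrix = mat, truth = truth)
}

#' Default view for a synthetic spec (one region per chromosome)
#' @param spec a [synthetic_genome_spec()].
#' @export
spec_view <- function(spec) view_from_sizes(spec$chrom_sizes)
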