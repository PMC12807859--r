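#' Default pipeline configuration
#'
#' Returns the full configuration of a synthetic end-to-end run as a nested
#' list: generator conditions, per-stage parameters and toggles, and an
#' explicit seed for every stochastic stage. The configuration round-trips
#' through YAML unchanged.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @return a named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(chrom_sizes = list(chr1 = 20e6, chr2 = 20e6, chr3 = 20e6),
                  resolution = 10e3, ps_exponent = 1.0,
                  compartment_contrast = 1.8, n_mcds = 30, mcd_affinity = 4,
                  trans_base = 5e-4, bias_sd = 0.2, depth = 2e7),
    balance = list(ignore_diags = 2, madmax_threshold = 5, tol = 1e-6),
    detect = list(enabled = TRUE, kernel_half_width = 3, kernel_flank = 7,
                  max_dist = 30e6, ratio = 2, min_samples = 5,
                  max_eps = 33e3, min_width = 25e3, max_width = 125e3,
                  prominence = 15),
    grid = list(enabled = TRUE, flank = 100e3, long_range_bp = 750e3),
    compartments = list(enabled = TRUE, n_quantiles = 38,
                        trim_fraction = 0.025, top_fraction = 0.2),
    spectral = list(enabled = FALSE, n_eigs = 9, k = 8, nstart = 10),
    annotate = list(enabled = TRUE, bookmark_fraction = 0.9,
                    ccre_per_mcd = 3),
    slam = list(enabled = TRUE, n_genes = 5000, noise_sd = 0.02,
                mcd_or = 3))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates simulate -> balance -> expected -> detect -> grid /
#' pileup / strength -> compartments -> (optional) spectral clustering ->
#' annotate -> reactivation statistics, writing artifacts and a
#' machine-readable JSON summary (anchor counts, pair counts, strengths,
#' recovery metrics against the planted truth, stage seeds and parameters)
#' into a run directory. Stages can be toggled off in the config; a rerun
#' with the same config reproduces the same summary.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir run directory (created).
#' @return the summary list, invisibly; written to `summary.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  logline("mcdtools ", as.character(utils::packageVersion("mcdtools")),
          " seed=", config$seed)
  summary <- list(seed = config$seed)

  g <- config$genome
  spec <- synthetic_genome_spec(
    chrom_sizes = unlist(g$chrom_sizes), resolution = g$resolution,
    ps_exponent = g$ps_exponent,
    compartment_contrast = g$compartment_contrast,
    n_mcds = g$n_mcds, mcd_affinity = g$mcd_affinity,
    trans_base = g$trans_base, bias_sd = g$bias_sd, depth = g$depth,
    seed = config$seed)
  sim <- simulate_contact_map(spec)
  view <- spec_view(spec)
  logline("simulated ", nrow(sim$matrix$pixels), " pixels")

  b <- config$balance
  m <- balance_ic(sim$matrix, ignore_diags = b$ignore_diags,
                  madmax_threshold = b$madmax_threshold, tol = b$tol)
  expected <- compute_expected(m, view, ignore_diags = b$ignore_diags)
  write_expected(expected, file.path(out_dir, "expected"))
  summary$n_bins <- n_bins(m)
  summary$n_masked <- sum(is.na(m$bins$weight))
  oe <- observed_over_expected(m, expected, view)

  anchors <- NULL
  if (isTRUE(config$detect$enabled)) {
    dt <- config$detect
    det <- detect_mcds(m, expected, view,
                       kernels = kernel_set(dt$kernel_half_width,
                                            dt$kernel_flank),
                       max_dist = dt$max_dist, ratio = dt$ratio,
                       min_samples = dt$min_samples, max_eps = dt$max_eps,
                       min_width = dt$min_width, max_width = dt$max_width,
                       prominence = dt$prominence)
    anchors <- det$anchors
    write_bed(anchors, file.path(out_dir, "mcd_anchors.bed"))
    summary$anchors <- list(n = nrow(anchors))
    tr <- sim$truth$mcd_truth
    if (nrow(tr) && nrow(anchors)) {
      tol <- m$resolution
      rec <- mean(interval_overlaps_any(tr$chrom, tr$start - tol,
                                        tr$end + tol, anchors$chrom,
                                        anchors$start, anchors$end))
      prec <- mean(interval_overlaps_any(anchors$chrom, anchors$start - tol,
                                         anchors$end + tol, tr$chrom,
                                         tr$start, tr$end))
      summary$anchors$recall <- rec
      summary$anchors$precision <- prec
    }
    logline("detected ", nrow(anchors), " anchors")
  }

  if (isTRUE(config$grid$enabled) && !is.null(anchors) && nrow(anchors) > 1) {
    gr <- config$grid
    grid <- make_pairwise_grid(anchors, view)
    summary$grid <- list(n_cis = sum(grid$kind == "cis"),
                         n_trans = sum(grid$kind == "trans"))
    cis <- grid[grid$kind == "cis", , drop = FALSE]
    if (nrow(cis)) {
      strata <- ifelse(cis$separation <= gr$long_range_bp,
                       "short", "long")
      pls <- aggregate_pileup(oe, cis, flank = gr$flank, groups = strata)
      summary$grid$strength_cis <- lapply(pls, function(p)
        tryCatch(feature_strength(p, "cis_grid"), error = function(e) NA))
    }
    logline("grid: ", nrow(grid), " pairs")
  }

  if (isTRUE(config$compartments$enabled)) {
    cp <- config$compartments
    tracks <- simulate_annotation_tracks(spec, sim$truth,
                                         seed = config$seed + 1)
    ev <- eigs_cis_phased(oe, phasing_track = tracks$gene_density$value,
                          n_eigs = 1)
    sad <- saddle_strength(oe, ev$vectors[, 1],
                           n_quantiles = cp$n_quantiles,
                           trim_fraction = cp$trim_fraction,
                           top_fraction = cp$top_fraction)
    summary$compartments <- list(
      strength_A = sad$strength_A, strength_B = sad$strength_B,
      ev1_profile_cor = suppressWarnings(
        stats::cor(ev$vectors[, 1], sim$truth$profile, method = "spearman",
                   use = "complete.obs")))
    write_bed(data.frame(chrom = m$bins$chrom, start = m$bins$start,
                         end = m$bins$end, value = ev$vectors[, 1]),
              file.path(out_dir, "ev1.bedgraph"))
    logline("compartments: A=", round(sad$strength_A, 3))
  }

  if (isTRUE(config$spectral$enabled)) {
    sp <- config$spectral
    scl <- spectral_cluster_genome(m, view, n_eigs = sp$n_eigs, k = sp$k,
                                   seed = config$seed + 2,
                                   nstart = sp$nstart)
    summary$spectral <- list(e2_ev1_cor = scl$e2_ev1_cor,
                             n_clusters = length(unique(
                               scl$labels[!is.na(scl$labels)])))
    if (!is.null(anchors) && nrow(anchors)) {
      cov <- cluster_mcd_overlap(scl$labels, m$bins, anchors)
      summary$spectral$best_cluster_coverage <-
        max(pmin(cov$frac_cluster_in_mcd, cov$frac_mcd_in_cluster))
    }
    logline("spectral: e2~EV1 r=", round(scl$e2_ev1_cor, 3))
  }

  if (isTRUE(config$annotate$enabled)) {
    an <- config$annotate
    tracks <- simulate_annotation_tracks(spec, sim$truth,
                                         bookmark_fraction = an$bookmark_fraction,
                                         ccre_per_mcd = an$ccre_per_mcd,
                                         seed = config$seed + 1)
    write_bed(tracks$ccres[, c("chrom", "start", "end", "class")],
              file.path(out_dir, "ccres.bed"))
    if (!is.null(anchors) && nrow(anchors)) {
      bk <- pool_and_bookmark(tracks$peaks_g1, tracks$peaks_g1,
                              tracks$peaks_g1, tracks$peaks_mitosis,
                              tracks$peaks_g1)
      val <- mcd_valency(anchors, tracks$ccres,
                         classes = c("PLS", "pELS", "dELS"))
      frac_book <- mean(interval_overlaps_any(
        anchors$chrom, anchors$start, anchors$end,
        bk$bookmarked$chrom, bk$bookmarked$start, bk$bookmarked$end))
      summary$annotate <- list(frac_anchors_bookmarked = frac_book,
                               frac_valency_ge1 = val$summary$fraction[1])
    }
    logline("annotation done")
  }

  if (isTRUE(config$slam$enabled)) {
    sl <- config$slam
    ntr <- simulate_ntr_table(n_genes = sl$n_genes, noise_sd = sl$noise_sd,
                              mcd_or = sl$mcd_or, seed = config$seed + 3)
    cls <- classify_reactivation(ntr)
    fe <- enrichment_fisher_bh(cls, ntr$mcd)
    utils::write.table(fe, file.path(out_dir, "reactivation_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$slam <- list(
      n_classified = sum(!is.na(cls) & cls != "none"),
      or_early = fe$odds_ratio[fe$cluster == "early"],
      q_early = fe$q[fe$cluster == "early"])
    logline("reactivation stats done")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
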