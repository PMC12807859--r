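#' Companion 1D tracks and annotations for a synthetic genome
#'
#' Emits the annotation side of the synthetic study: a gene-density track
#' positively correlated with the compartment profile; candidate
#' cis-regulatory elements (PLS/pELS/dELS plus background CTCF/open sites)
#' placed inside the planted MCDs with configurable valency; accessibility
#' peak sets for a "G1" and a "mitosis" condition such that a configurable
#' fraction of MCDs carry peaks present in both conditions (mitotically
#' bookmarked); and H3K27ac / H3K4me3 coverage concentrated at the planted
#' elements.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param truth the matching `synthetic_truth` from [simulate_contact_map()].
#' @param bookmark_fraction fraction of MCDs whose peaks are retained in
#'   mitosis (default 0.9).
#' @param ccre_per_mcd elements planted per MCD (default 3; the first is a
#'   PLS, the rest enhancer-like).
#' @param element_width width of planted elements (bp).
#' @param background_rate background (non-MCD) elements per Mb (CTCF/open).
#' @param seed random seed (defaults to `spec$seed + 1`).
#' @return list(gene_density, ccres, peaks_g1, peaks_mitosis, h3k27ac,
#'   h3k4me3, bookmarked_mcd).
#' @export
simulate_annotation_tracks <- function(spec, truth, bookmark_fraction = 0.9,
                                       ccre_per_mcd = 3,
                                       element_width = 300,
                                       background_rate = 5,
                                       seed = spec$seed + 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  bins <- spec$bins
  p <- truth$profile

  gene_density <- data.frame(chrom = bins$chrom, start = bins$start,
                             end = bins$end,
                             value = pmax(0, (p + 1) * 5 +
                                            stats::rnorm(nrow(bins), 0, 0.5)))

  mcds <- truth$mcd_truth
  ccres <- list(); g1 <- list(); mito <- list()
  bookmarked <- if (nrow(mcds)) stats::runif(nrow(mcds)) < bookmark_fraction
                else logical(0)
  enh_classes <- c("pELS", "dELS")
  for (k in seq_len(nrow(mcds))) {
    cls <- c("PLS", sample(enh_classes, max(0, ccre_per_mcd - 1),
                           replace = TRUE))
    pos <- sort(stats::runif(length(cls), mcds$start[k],
                             mcds$end[k] - element_width))
    tssd <- ifelse(cls == "PLS", sample(0:200, length(cls), replace = TRUE),
                   ifelse(cls == "pELS", sample(200:2000, length(cls), TRUE),
                          sample(2000:50000, length(cls), TRUE)))
    ccres[[k]] <- data.frame(chrom = mcds$chrom[k], start = floor(pos),
                             end = floor(pos) + element_width, class = cls,
                             tss_dist = tssd, mcd = k)
    pk <- data.frame(chrom = mcds$chrom[k], start = floor(pos) - 50,
                     end = floor(pos) + element_width + 50)
    g1[[k]] <- pk
    if (bookmarked[k]) mito[[k]] <- pk
  }
  # background elements outside MCDs
  for (ch in names(spec$chrom_sizes)) {
    nb <- round(background_rate * spec$chrom_sizes[[ch]] / 1e6)
    if (nb == 0) next
    pos <- floor(stats::runif(nb, 0, spec$chrom_sizes[[ch]] - element_width))
    cand <- data.frame(chrom = ch, start = pos, end = pos + element_width,
                       class = sample(c("CTCF", "open"), nb, replace = TRUE),
                       tss_dist = sample(2000:50000, nb, TRUE), mcd = 0L)
    inside <- interval_overlaps_any(cand$chrom, cand$start, cand$end,
                                    mcds$chrom, mcds$start, mcds$end)
    ccres[[length(ccres) + 1L]] <- cand[!inside, , drop = FALSE]
  }
  ccres <- do.call(rbind, ccres)
  rownames(ccres) <- NULL
  peaks_g1 <- if (length(g1)) do.call(rbind, g1)
              else data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0))
  peaks_mitosis <- if (length(mito)) do.call(rbind, mito)
                   else data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0))

  cover_at <- function(el, height) {
    if (!nrow(el)) return(data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0), value = numeric(0)))
    data.frame(chrom = el$chrom, start = pmax(0, el$start - 1000),
               end = el$end + 1000, value = height)
  }
  h3k27ac <- cover_at(ccres[ccres$class %in% c("pELS", "dELS"), ], 20)
  h3k4me3 <- cover_at(ccres[ccres$class == "PLS", ], 20)

  list(gene_density = gene_density, ccres = ccres, peaks_g1 = peaks_g1,
       peaks_mitosis = peaks_mitosis, h3k27ac = h3k27ac, h3k4me3 = h3k4me3,
       bookmarked_mcd = bookmarked)
}

#' Simulate a gene NTR time course
#'
#' Generates per-gene new-to-total RNA ratios at t = 0..5 h after mitotic
#' release such that each gene's first crossing of the reactivation
#' threshold falls in its assigned cluster (prometaphase t = 0, early
#' t = 1-2, late t = 3-5, none never), with Gaussian noise truncated to
#' \[0, 1\], and an MCD-membership flag enriched (odds ratio `mcd_or`) in
#' the clusters named by `enrich_clusters`.
#'
#' @param n_genes number of genes.
#' @param cluster_fractions named fractions for prometaphase/early/late
#'   (the remainder is "none"); must sum to <= 1.
#' @param noise_sd NTR noise standard deviation.
#' @param mcd_rate baseline probability that a gene sits in an MCD.
#' @param mcd_or odds-ratio of MCD membership in `enrich_clusters`.
#' @param enrich_clusters clusters receiving the enrichment.
#' @param threshold the reactivation threshold the curves are built
#'   around (default 0.10).
#' @param seed random seed.
#' @return data.frame(gene, ntr_0..ntr_5, reads, mcd, true_cluster).
#' @export
simulate_ntr_table <- function(n_genes = 5000,
                               cluster_fractions = c(prometaphase = 0.15,
                                                     early = 0.25,
                                                     late = 0.30),
                               noise_sd = 0.02, mcd_rate = 0.20,
                               mcd_or = 3,
                               enrich_clusters = c("prometaphase", "early"),
                               threshold = 0.10, seed = 1) {
  stopifnot(sum(cluster_fractions) <= 1 + 1e-9)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)

  counts <- floor(cluster_fractions * n_genes)
  lab <- c(rep(names(counts), counts),
           rep("none", n_genes - sum(counts)))
  lab <- sample(lab)
  t_first <- ifelse(lab == "prometaphase", 0,
                    ifelse(lab == "early", sample(1:2, n_genes, TRUE),
                           ifelse(lab == "late", sample(3:5, n_genes, TRUE),
                                  NA)))
  tt <- 0:5
  mat <- matrix(0, n_genes, 6)
  for (g in seq_len(n_genes)) {
    if (is.na(t_first[g])) {
      mat[g, ] <- threshold * 0.5 * tt / 5         # stays below threshold
    } else {
      pre <- tt < t_first[g]
      ramp <- if (t_first[g] > 0) threshold * 0.6 * tt / t_first[g] else 0
      post <- threshold + (0.75 - threshold) *
        (1 - exp(-(tt - t_first[g] + 1) / 2))
      mat[g, ] <- ifelse(pre, ramp, post)
    }
  }
  if (noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), 0, noise_sd)
  mat <- pmin(pmax(mat, 0), 1)

  base_odds <- mcd_rate / (1 - mcd_rate)
  odds <- ifelse(lab %in% enrich_clusters, base_odds * mcd_or, base_odds)
  mcd <- stats::runif(n_genes) < odds / (1 + odds)

  out <- data.frame(gene = paste0("g", seq_len(n_genes)), mat,
                    reads = 100L + stats::rpois(n_genes, 900),
                    mcd = mcd, true_cluster = lab,
                    stringsAsFactors = FALSE)
  names(out)[2:7] <- paste0("ntr_", 0:5)
  out
}
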