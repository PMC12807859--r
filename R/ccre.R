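#' Hierarchical cCRE class assignment to bins
#'
#' Assigns each genomic bin the highest-priority candidate cis-regulatory
#' element class among the elements overlapping it, in the order
#' PLS > pELS > dELS > H3K4me3 > CTCF > open; bins overlapping nothing are
#' "not_open". A bin containing a pELS element is pELS regardless of any
#' lower-priority elements in it.
#'
#' @param elements data.frame (chrom, start, end, class) with class in
#'   the hierarchy above.
#' @param bins bin table (chrom, start, end).
#' @return character vector of per-bin classes.
#' @export
assign_ccre_hierarchy <- function(elements, bins) {
  hier <- c("PLS", "pELS", "dELS", "H3K4me3", "CTCF", "open")
  bad <- setdiff(unique(elements$class), hier)
  if (length(bad)) stop("unknown cCRE class: ", paste(bad, collapse = ", "))
  out <- rep("not_open", nrow(bins))
  for (cl in rev(hier)) {   # low priority first, higher classes overwrite
    el <- elements[elements$class == cl, , drop = FALSE]
    if (!nrow(el)) next
    hit <- interval_overlaps_any(bins$chrom, bins$start, bins$end,
                                 el$chrom, el$start, el$end)
    out[hit] <- cl
  }
  out
}

#' Per-class overlap enrichment in target regions
#'
#' ChromHMM-style fold enrichment: the fraction of target bases in a class
#' divided by the genome-wide fraction of that class,
#' `(class bp in targets / target bp) / (class bp genome-wide / genome bp)`,
#' where the genome is the extent of the class track.
#'
#' @param class_track data.frame (chrom, start, end, class) tiling the
#'   genome (e.g. bins with [assign_ccre_hierarchy()] labels).
#' @param targets data.frame (chrom, start, end).
#' @return data.frame(class, bp_genome, bp_targets, enrichment); classes
#'   absent genome-wide get NA enrichment.
#' @export
overlap_enrichment <- function(class_track, targets) {
  genome_bp <- sum(class_track$end - class_track$start)
  target_bp <- sum(interval_covered_bp(targets$chrom, targets$start,
                                       targets$end, class_track$chrom,
                                       class_track$start, class_track$end))
  out <- list()
  for (cl in sort(unique(class_track$class))) {
    seg <- class_track[class_track$class == cl, , drop = FALSE]
    cl_bp <- sum(seg$end - seg$start)
    cl_in_t <- sum(interval_covered_bp(targets$chrom, targets$start,
                                       targets$end, seg$chrom, seg$start,
                                       seg$end))
    enr <- if (cl_bp > 0) (cl_in_t / target_bp) / (cl_bp / genome_bp)
           else NA_real_
    out[[length(out) + 1L]] <- data.frame(class = cl, bp_genome = cl_bp,
                                          bp_targets = cl_in_t,
                                          enrichment = enr)
  }
  do.call(rbind, out)
}

#' Replicate-supported pooled peaks and mitotic bookmarking
#'
#' A peak called in a pooled dataset is "true" only when at least 50% of
#' its length is covered by a peak in each of the two constituent
#' replicates. Bookmarked peaks are the control-G1 peaks that overlap (by
#' at least 1 bp) any peak called in the prometaphase sample — regulatory
#' sites whose accessibility is retained through mitosis.
#'
#' @param peaks_pooled,peaks_repA,peaks_repB peak tables
#'   (chrom, start, end) for the pooled set and the two replicates.
#' @param peaks_mitosis,peaks_g1 peak tables for the prometaphase and G1
#'   samples (used for bookmarking).
#' @return list(pooled_true, bookmarked).
#' @export
pool_and_bookmark <- function(peaks_pooled, peaks_repA, peaks_repB,
                              peaks_mitosis, peaks_g1) {
  w <- peaks_pooled$end - peaks_pooled$start
  ovA <- interval_covered_bp(peaks_pooled$chrom, peaks_pooled$start,
                             peaks_pooled$end, peaks_repA$chrom,
                             peaks_repA$start, peaks_repA$end)
  ovB <- interval_covered_bp(peaks_pooled$chrom, peaks_pooled$start,
                             peaks_pooled$end, peaks_repB$chrom,
                             peaks_repB$start, peaks_repB$end)
  pooled_true <- peaks_pooled[ovA >= 0.5 * w & ovB >= 0.5 * w, , drop = FALSE]
  book <- interval_overlaps_any(peaks_g1$chrom, peaks_g1$start, peaks_g1$end,
                                peaks_mitosis$chrom, peaks_mitosis$start,
                                peaks_mitosis$end)
  rownames(pooled_true) <- NULL
  list(pooled_true = pooled_true,
       bookmarked = peaks_g1[book, , drop = FALSE])
}

#' Element valency of MCD anchors
#'
#' Counts, per anchor, the overlapping elements of the requested classes,
#' and summarizes the fraction of anchors reaching each valency level.
#'
#' @param anchors anchor table (chrom, start, end).
#' @param elements element table (chrom, start, end, class).
#' @param classes classes counted (default all present).
#' @param max_level highest ">= k" level summarized.
#' @return list(valency = per-anchor integer, summary =
#'   data.frame(min_valency, fraction)).
#' @export
mcd_valency <- function(anchors, elements,
                        classes = unique(elements$class), max_level = 3) {
  el <- elements[elements$class %in% classes, , drop = FALSE]
  v <- interval_count_overlaps(anchors$chrom, anchors$start, anchors$end,
                               el$chrom, el$start, el$end)
  lv <- seq_len(max_level)
  list(valency = v,
       summary = data.frame(min_valency = lv,
                            fraction = vapply(lv, function(k) mean(v >= k),
                                              numeric(1))))
}
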