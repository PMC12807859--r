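#' Filter loops for convergent CTCF motif orientation
#'
#' Keeps loops whose upstream anchor overlaps a forward-strand CTCF motif
#' and whose downstream anchor overlaps a reverse-strand motif — the
#' orientation compatible with a cohesin loop halted at convergent CTCF
#' sites.
#'
#' @param loops data.frame (chrom, start1, end1, start2, end2, ...),
#'   anchor1 upstream of anchor2.
#' @param motifs data.frame (chrom, start, end, strand) with strand
#'   "+"/"-".
#' @return the convergent subset of `loops`.
#' @export
filter_convergent_loops <- function(loops, motifs) {
  fwd <- motifs[motifs$strand == "+", , drop = FALSE]
  rev <- motifs[motifs$strand == "-", , drop = FALSE]
  ok1 <- interval_overlaps_any(loops$chrom, loops$start1, loops$end1,
                               fwd$chrom, fwd$start, fwd$end)
  ok2 <- interval_overlaps_any(loops$chrom, loops$start2, loops$end2,
                               rev$chrom, rev$start, rev$end)
  out <- loops[ok1 & ok2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive extrusion (looping) domains from a loop list
#'
#' A domain is the interval spanned by the outermost loop of a group of
#' nested loops: loops are clustered by overlap of their upstream anchors
#' (same extrusion line), each cluster yields the candidate interval from
#' its most upstream anchor-1 start to its most downstream anchor-2 end,
#' and candidates are then merged to a fixpoint whenever one nests inside
#' another or the overlap exceeds `overlap_merge_fraction` of either
#' interval (read as: of the shorter — the permissive reading; set
#' `rule = "both"` for the conjunctive one).
#'
#' @param loops data.frame (chrom, start1, end1, start2, end2).
#' @param overlap_merge_fraction merge threshold (default 0.70, strict
#'   inequality).
#' @param rule "either" (overlap > fraction of the shorter interval
#'   merges) or "both" (required of both intervals).
#' @return data.frame(chrom, start, end) of domains, sorted.
#' @export
derive_extrusion_domains <- function(loops, overlap_merge_fraction = 0.70,
                                     rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (!nrow(loops))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  cands <- list()
  for (ch in sort(unique(loops$chrom))) {
    sub <- loops[loops$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start1, sub$end1), , drop = FALSE]
    # anchor-1 overlap clusters: sweep over sorted anchor1 intervals
    grp <- integer(nrow(sub))
    cur <- 1L; grp[1] <- 1L
    if (nrow(sub) > 1) {
      reach <- sub$end1[1]
      for (i in 2:nrow(sub)) {
        if (sub$start1[i] < reach) grp[i] <- cur
        else { cur <- cur + 1L; grp[i] <- cur }
        reach <- max(reach, sub$end1[i])
      }
    }
    for (g in unique(grp)) {
      s <- sub[grp == g, , drop = FALSE]
      cands[[length(cands) + 1L]] <-
        data.frame(chrom = ch, start = min(s$start1), end = max(s$end2))
    }
  }
  doms <- do.call(rbind, cands)
  merge_pass <- function(df) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    out <- df[0, ]
    for (i in seq_len(nrow(df))) {
      row <- df[i, ]
      if (nrow(out)) {
        last <- out[nrow(out), ]
        if (last$chrom == row$chrom) {
          ov <- min(last$end, row$end) - max(last$start, row$start)
          w1 <- last$end - last$start; w2 <- row$end - row$start
          nested <- (row$start >= last$start & row$end <= last$end) |
            (last$start >= row$start & last$end <= row$end)
          fr <- c(ov / w1, ov / w2)
          merge_it <- nested || (ov > 0 &&
            if (rule == "either") max(fr) > overlap_merge_fraction
            else min(fr) > overlap_merge_fraction)
          if (merge_it) {
            out[nrow(out), "start"] <- min(last$start, row$start)
            out[nrow(out), "end"] <- max(last$end, row$end)
            next
          }
        }
      }
      out <- rbind(out, row)
    }
    out
  }
  repeat {
    merged <- merge_pass(doms)
    if (nrow(merged) == nrow(doms)) break
    doms <- merged
  }
  rownames(doms) <- NULL
  doms
}

#' Classify MCD anchors and anchor pairs by extrusion context
#'
#' Tags each anchor as `anchored` (its footprint, expanded to whole bins at
#' the working resolution, overlaps a loop anchor) or extrusion-free; each
#' cis pair as intra-domain (both summits inside one extrusion domain) or
#' inter-domain; pairs as `anchored_pair` when either member is anchored;
#' and flags `pair_is_loop` when the two footprints overlap the two anchors
#' of a single loop.
#'
#' @param grid a [make_pairwise_grid()] table.
#' @param loops loop table (chrom, start1, end1, start2, end2).
#' @param domains extrusion domain table (chrom, start, end), e.g. from
#'   [derive_extrusion_domains()].
#' @param anchors the MCD anchor table the grid was built from.
#' @param resolution bin size used to discretize overlap tests (default
#'   10 kb).
#' @return list(anchors = anchors + `anchored` flag, grid = grid +
#'   `anchored_pair`, `domain_context` ("intra"/"inter"/NA), `pair_is_loop`).
#' @export
classify_pairs_by_extrusion <- function(grid, loops, domains, anchors,
                                        resolution = 10e3) {
  snap <- function(s, e) list(start = floor(s / resolution) * resolution,
                              end = ceiling(e / resolution) * resolution)
  af <- snap(anchors$start, anchors$end)
  la <- snap(c(loops$start1, loops$start2), c(loops$end1, loops$end2))
  lchrom <- c(loops$chrom, loops$chrom)
  anchored <- interval_overlaps_any(anchors$chrom, af$start, af$end,
                                    lchrom, la$start, la$end)
  anchors$anchored <- anchored

  # intra-domain: some single domain contains both summits (domains may
  # partially overlap, so membership is not unique)
  domain_context <- rep(NA_character_, nrow(grid))
  for (p in which(grid$kind == "cis")) {
    di <- which(domains$chrom == grid$chrom1[p])
    intra <- any(domains$start[di] <= grid$pos1[p] &
                   grid$pos1[p] < domains$end[di] &
                   domains$start[di] <= grid$pos2[p] &
                   grid$pos2[p] < domains$end[di])
    domain_context[p] <- if (intra) "intra" else "inter"
  }

  anchored_pair <- anchored[grid$a1] | anchored[grid$a2]

  pair_is_loop <- logical(nrow(grid))
  if (nrow(loops)) {
    l1 <- snap(loops$start1, loops$end1)
    l2 <- snap(loops$start2, loops$end2)
    for (p in which(grid$kind == "cis")) {
      i <- grid$a1[p]; j <- grid$a2[p]
      cand <- which(loops$chrom == anchors$chrom[i])
      if (!length(cand)) next
      hit <- (af$start[i] < l1$end[cand] & af$end[i] > l1$start[cand] &
                af$start[j] < l2$end[cand] & af$end[j] > l2$start[cand])
      pair_is_loop[p] <- any(hit)
    }
  }
  grid$anchored_pair <- anchored_pair
  grid$domain_context <- domain_context
  grid$pair_is_loop <- pair_is_loop
  list(anchors = anchors, grid = grid)
}
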