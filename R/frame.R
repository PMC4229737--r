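#' Pool block boundaries across samples into a shared VB frame
#'
#' All dVB/sVB boundaries from all samples are pooled per chromosome,
#' clustered greedily left-to-right with cluster span at most `tolerance`,
#' and each cluster replaced by its (rounded) median: these are the
#' recombination sites. The sites split each chromosome into variation
#' blocks (VBs) with sequential ids, the shared comparison frame for the
#' whole sample set.
#'
#' @param maps List of `sample_block_map`, all on the same layout.
#' @param layout `genome_layout`.
#' @param tolerance Maximum bp span of a boundary cluster (default one bin,
#'   10,000 bp).
#' @return List with `sites` (named per-chromosome numeric vectors of
#'   deduplicated recombination sites) and `frame`, a data frame of class
#'   `vb_frame` with columns `vb_id`, `chrom`, `start`, `end`.
#' @export
build_vb_frame <- function(maps, layout, tolerance = 10000) {
  .assert(length(maps) >= 1L, "need at least one sample block map")
  for (m in maps) {
    .assert(setequal(unique(m$blocks$chrom), layout$chrom),
            "map '", m$sample_id,
            "' does not cover the layout's chromosome set")
  }
  lens <- .chrom_lengths(layout)
  sites <- stats::setNames(vector("list", nrow(layout)), layout$chrom)
  rows <- list()
  next_id <- 1L
  for (ch in layout$chrom) {
    pooled <- sort(unlist(lapply(maps, function(m)
      block_boundaries(m)[[ch]]), use.names = FALSE))
    ded <- numeric(0)
    if (length(pooled) > 0L) {
      cl_start <- 1L
      for (i in seq_along(pooled)) {
        if (pooled[i] - pooled[cl_start] > tolerance) {
          ded <- c(ded, round(stats::median(pooled[cl_start:(i - 1L)])))
          cl_start <- i
        }
      }
      ded <- c(ded, round(stats::median(pooled[cl_start:length(pooled)])))
      ded <- unique(ded[ded > 0 & ded < lens[[ch]]])
    }
    sites[[ch]] <- ded
    edges <- c(0, ded, lens[[ch]])
    n <- length(edges) - 1L
    rows[[ch]] <- data.frame(
      vb_id = sprintf("VB%04d", next_id:(next_id + n - 1L)),
      chrom = ch, start = edges[-length(edges)], end = edges[-1L],
      stringsAsFactors = FALSE)
    next_id <- next_id + n
  }
  frame <- do.call(rbind, rows)
  rownames(frame) <- NULL
  class(frame) <- c("vb_frame", "data.frame")
  list(sites = sites, frame = frame)
}

#' Per-sample VB instances within a shared frame
#'
#' For every VB interval of the frame, extracts the sample's SNVs inside
#' the interval and assigns a dense/sparse label from the sample block
#' covering the majority of the interval (an exact tie takes the label of
#' the block containing the interval start).
#'
#' @param frame `vb_frame` data frame (the `$frame` element of
#'   [build_vb_frame()]).
#' @param map The sample's `sample_block_map`; its boundaries should have
#'   contributed to the frame.
#' @param snvs The sample's homozygous-SNV `variant_set`.
#' @return Data frame of class `vb_instances`: one row per VB with columns
#'   `vb_id`, `sample_id`, `chrom`, `start`, `end`, `density`
#'   (`"dense"`/`"sparse"`), `n_snv`, and a list column `snv` of
#'   per-instance data frames with `pos` (1-based) and `alt`.
#' @export
annotate_instances <- function(frame, map, snvs) {
  v <- snvs$variants
  out <- frame[, c("vb_id", "chrom", "start", "end")]
  out$sample_id <- map$sample_id
  dens <- character(nrow(out))
  snv_list <- vector("list", nrow(out))
  n_snv <- integer(nrow(out))
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    fb <- out[idx, , drop = FALSE]
    mb <- map$blocks[map$blocks$chrom == ch, , drop = FALSE]
    mb <- mb[order(mb$start), , drop = FALSE]
    vi <- v[v$chrom == ch, , drop = FALSE]
    # bucket SNVs into VB intervals (frame tiles the chromosome)
    if (nrow(vi) > 0L) {
      bucket <- findInterval(vi$pos - 1, fb$start)
    } else bucket <- integer(0)
    dmb <- mb[mb$label == "dVB", , drop = FALSE]
    for (k in seq_along(idx)) {
      s <- fb$start[k]; e <- fb$end[k]
      ov <- 0
      if (nrow(dmb) > 0L)
        ov <- sum(pmax(0, pmin(dmb$end, e) - pmax(dmb$start, s)))
      half <- (e - s) / 2
      if (ov > half) {
        dens[idx[k]] <- "dense"
      } else if (ov < half) {
        dens[idx[k]] <- "sparse"
      } else {
        cover <- mb$label[findInterval(s, mb$start)]
        dens[idx[k]] <- if (cover == "dVB") "dense" else "sparse"
      }
      sel <- which(bucket == k)
      snv_list[[idx[k]]] <- data.frame(pos = vi$pos[sel], alt = vi$alt[sel],
                                       stringsAsFactors = FALSE)
      n_snv[idx[k]] <- length(sel)
    }
  }
  out$density <- dens
  out$n_snv <- n_snv
  out$snv <- I(snv_list)
  out <- out[, c("vb_id", "sample_id", "chrom", "start", "end", "density",
                 "n_snv", "snv")]
  class(out) <- c("vb_instances", "data.frame")
  out
}
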