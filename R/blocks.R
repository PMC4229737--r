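#' Count homozygous SNVs in consecutive genome bins
#'
#' An SNV at 1-based position p falls in 0-based bin index
#' `floor((p - 1) / bin_size)`. Every chromosome of the layout gets a count
#' vector (all-zero when the sample has no SNVs there); the last bin may be
#' shorter than `bin_size` and keeps its raw count.
#'
#' @param snvs `variant_set` restricted to homozygous SNVs (see
#'   [prepare_homozygous_snvs()]).
#' @param layout `genome_layout`.
#' @param bin_size Bin width in bp (default 10,000).
#' @return Object of class `bin_profile`: list with `bin_size` and `counts`,
#'   a named list of per-chromosome integer vectors.
#' @export
compute_bin_profile <- function(snvs, layout, bin_size = 10000) {
  v <- snvs$variants
  counts <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    nbin <- ceiling(layout$length[i] / bin_size)
    p <- v$pos[v$chrom == ch]
    if (length(p) == 0L) return(integer(nbin))
    tabulate(floor((p - 1) / bin_size) + 1L, nbins = nbin)
  })
  names(counts) <- layout$chrom
  structure(list(bin_size = bin_size, counts = counts),
            class = "bin_profile")
}

#' Classify bins as dense (dRB) or sparse (sRB)
#'
#' A bin is a different-to-standard recombination block (dRB) iff its
#' homozygous SNV count is at least `threshold`; otherwise it is
#' similar-to-standard (sRB).
#'
#' @param profile A `bin_profile`.
#' @param threshold Minimum SNV count for a dRB (default 4).
#' @return Object of class `bin_labels`: list with `bin_size` and `labels`,
#'   a named list of per-chromosome character vectors in `{"sRB","dRB"}`.
#' @export
classify_bins <- function(profile, threshold = 4) {
  .assert(threshold >= 1, "threshold must be >= 1")
  labels <- lapply(profile$counts, function(cnt)
    ifelse(cnt >= threshold, "dRB", "sRB"))
  structure(list(bin_size = profile$bin_size, labels = labels),
            class = "bin_labels")
}

#' Construct and validate a per-sample block map
#'
#' @param sample_id Sample name.
#' @param blocks Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `label` in `{"dVB","sVB"}`.
#' @param layout `genome_layout`; intervals must tile each chromosome
#'   exactly with alternating labels.
#' @return Object of class `sample_block_map`.
#' @export
sample_block_map <- function(sample_id, blocks, layout) {
  b <- blocks
  b$chrom <- as.character(b$chrom)
  b$label <- as.character(b$label)
  .assert(all(b$label %in% c("dVB", "sVB")), "labels must be dVB or sVB")
  b <- b[order(match(b$chrom, layout$chrom), b$start), , drop = FALSE]
  rownames(b) <- NULL
  lens <- .chrom_lengths(layout)
  .assert(setequal(unique(b$chrom), layout$chrom),
          "block map must cover every chromosome of the layout")
  for (ch in layout$chrom) {
    bi <- b[b$chrom == ch, , drop = FALSE]
    .assert(bi$start[1L] == 0 && bi$end[nrow(bi)] == lens[[ch]] &&
              all(bi$start > -1) && all(bi$end > bi$start) &&
              (nrow(bi) == 1L || all(bi$start[-1L] == bi$end[-nrow(bi)])),
            "blocks must tile chromosome ", ch, " exactly")
    .assert(nrow(bi) == 1L ||
              all(bi$label[-1L] != bi$label[-nrow(bi)]),
            "adjacent blocks on ", ch, " must alternate labels")
  }
  structure(list(sample_id = sample_id,
                 blocks = b[, c("chrom", "start", "end", "label")]),
            class = "sample_block_map")
}

#' @exportS3Method
print.sample_block_map <- function(x, ...) {
  b <- x$blocks
  dv <- b$label == "dVB"
  cat(sprintf(
    "Block map '%s': %d blocks (%d dVB covering %.1f Mb, %.1f%% of genome)\n",
    x$sample_id, nrow(b), sum(dv), sum(b$end[dv] - b$start[dv]) / 1e6,
    100 * sum(b$end[dv] - b$start[dv]) / sum(b$end - b$start)))
  invisible(x)
}

#' Merge bin labels into dense/sparse variation blocks
#'
#' Two-pass smoothing per chromosome. Pass 1 joins maximal runs of dRB bins
#' into one dense block (dVB) whenever the sparse gap between them is
#' shorter than `dvb_gap_merge`, absorbing the intervening sRB bins. Pass 2
#' dissolves any dense block shorter than `svb_gap_merge` into the
#' surrounding sparse run (a dense block spanning an entire chromosome is
#' exempt). The remaining genome is sparse (sVB).
#'
#' @param bin_labels A `bin_labels` object.
#' @param layout `genome_layout`.
#' @param params `vb_params`.
#' @param sample_id Sample name attached to the result.
#' @return A `sample_block_map`.
#' @export
merge_blocks <- function(bin_labels, layout, params = vb_params(),
                         sample_id = "sample") {
  bs <- bin_labels$bin_size
  lens <- .chrom_lengths(layout)
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    lab <- bin_labels$labels[[ch]]
    clen <- lens[[ch]]
    .assert(!is.null(lab) && length(lab) == ceiling(clen / bs),
            "bin labels must cover every bin of chromosome ", ch)
    r <- rle(lab)
    run_end_bin <- cumsum(r$lengths)
    run_start_bin <- run_end_bin - r$lengths
    # run coordinates in bp (0-based half-open; last bin may be partial)
    rs <- run_start_bin * bs
    re <- pmin(run_end_bin * bs, clen)
    dense <- which(r$values == "dRB")
    merged <- NULL
    if (length(dense) > 0L) {
      cur_s <- rs[dense[1L]]
      cur_e <- re[dense[1L]]
      acc <- list()
      for (j in dense[-1L]) {
        if (rs[j] - cur_e < params$dvb_gap_merge) {
          cur_e <- re[j]                       # absorb the sparse gap
        } else {
          acc[[length(acc) + 1L]] <- c(cur_s, cur_e)
          cur_s <- rs[j]; cur_e <- re[j]
        }
      }
      acc[[length(acc) + 1L]] <- c(cur_s, cur_e)
      m <- do.call(rbind, acc)
      keep <- (m[, 2L] - m[, 1L]) >= params$svb_gap_merge |
        (m[, 1L] == 0 & m[, 2L] == clen)
      merged <- m[keep, , drop = FALSE]
    }
    if (is.null(merged) || nrow(merged) == 0L) {
      blk <- data.frame(chrom = ch, start = 0, end = clen, label = "sVB")
    } else {
      edges <- c(0, as.vector(t(merged)), clen)
      starts <- edges[-length(edges)]
      ends <- edges[-1L]
      labels <- rep(c("sVB", "dVB"), length.out = 2L * nrow(merged) + 1L)
      keep <- ends > starts                    # drop zero-width flanks
      blk <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                        label = labels[keep])
    }
    out[[i]] <- blk
  }
  sample_block_map(sample_id, do.call(rbind, out), layout)
}

#' Interior block boundaries of a sample block map
#'
#' @param map A `sample_block_map`.
#' @return Named list (per chromosome) of strictly increasing boundary
#'   coordinates in bp, excluding 0 and the chromosome end.
#' @export
block_boundaries <- function(map) {
  b <- map$blocks
  out <- lapply(split(b, b$chrom), function(bi) {
    bi <- bi[order(bi$start), , drop = FALSE]
    if (nrow(bi) <= 1L) numeric(0) else bi$start[-1L]
  })
  out[order(names(out))]
}

#' One-call block detection for a single sample
#'
#' Convenience wrapper: homozygous-SNV filtering (with optional noise
#' mask), density binning, bin classification and two-pass merging.
#'
#' @inheritParams prepare_homozygous_snvs
#' @inheritParams merge_blocks
#' @return A `sample_block_map`.
#' @export
detect_blocks <- function(vs, layout, params = vb_params(),
                          noise_mask = NULL) {
  snvs <- prepare_homozygous_snvs(vs, noise_mask)
  prof <- compute_bin_profile(snvs, layout, params$bin_size)
  lab <- classify_bins(prof, params$dense_snv_threshold)
  merge_blocks(lab, layout, params, sample_id = vs$sample_id)
}
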