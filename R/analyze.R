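#' End-to-end variation-block analysis of a sample panel
#'
#' Runs the full pipeline over a set of per-sample variant sets: noise
#' masking and homozygous-SNV filtering, density binning and two-pass
#' block merging per sample, pooling of block boundaries into a shared VB
#' frame, per-sample instance annotation, block typing, and the diversity
#' curve in input order.
#'
#' @param variant_sets List of `variant_set` objects (one per sample).
#' @param layout `genome_layout`.
#' @param params `vb_params`.
#' @param noise_mask Optional `variant_set` of mask positions (e.g. calls
#'   from resequencing the reference individual).
#' @return Object of class `vb_analysis` with elements `maps` (per-sample
#'   `sample_block_map`s), `sites`, `frame`, `instances`, `types`,
#'   `diversity`, `samples`, `params`, `layout`.
#' @export
#' @examples
#' \donttest{
#' lay <- genome_layout("chr1", 2e6)
#' sim <- simulate_founders(lay, segment_model(seg_len_range = c(1e5, 5e5)),
#'                          n_founders = 3, seed = 7)
#' fit <- vb_analyze(sim$variant_sets, lay)
#' print(fit)
#' }
vb_analyze <- function(variant_sets, layout, params = vb_params(),
                       noise_mask = NULL) {
  .assert(length(variant_sets) >= 1L, "need at least one variant set")
  samples <- unname(vapply(variant_sets, `[[`, "", "sample_id"))
  .assert(!anyDuplicated(samples), "sample ids must be unique")
  prepared <- lapply(variant_sets, prepare_homozygous_snvs, noise_mask)
  maps <- lapply(prepared, function(p) detect_blocks(p, layout, params))
  names(maps) <- samples
  fr <- build_vb_frame(maps, layout, params$boundary_dedup_tolerance)
  inst <- do.call(rbind, lapply(seq_along(samples), function(i)
    annotate_instances(fr$frame, maps[[i]], prepared[[i]])))
  types <- assign_types(inst, params)
  structure(list(maps = maps, sites = fr$sites, frame = fr$frame,
                 instances = inst, types = types,
                 diversity = diversity_curve(types, samples),
                 samples = samples, params = params, layout = layout),
            class = "vb_analysis")
}

#' @exportS3Method
print.vb_analysis <- function(x, ...) {
  n_sites <- sum(lengths(x$sites))
  cat(sprintf("Variation-block analysis of %d sample(s)\n",
              length(x$samples)))
  cat(sprintf("  %d recombination sites, %d VBs across %d chromosome(s)\n",
              n_sites, nrow(x$frame), nrow(x$layout)))
  cat(sprintf("  diversity score (all samples): %.3f types per VB site\n",
              x$diversity$score[nrow(x$diversity)]))
  invisible(x)
}

#' @exportS3Method
summary.vb_analysis <- function(object, ...) {
  dv <- vapply(object$maps, function(m) {
    b <- m$blocks
    sum(b$end[b$label == "dVB"] - b$start[b$label == "dVB"]) /
      sum(b$end - b$start)
  }, numeric(1))
  k <- object$types$k[!duplicated(object$types$vb_id)]
  out <- list(samples = object$samples,
              dvb_fraction = dv,
              n_sites = sum(lengths(object$sites)),
              n_vb = nrow(object$frame),
              types_per_site = table(k),
              diversity = object$diversity)
  class(out) <- "summary.vb_analysis"
  out
}

#' @exportS3Method
print.summary.vb_analysis <- function(x, ...) {
  cat("Per-sample dVB genome fraction:\n")
  print(round(x$dvb_fraction, 3))
  cat(sprintf("\n%d recombination sites, %d VBs\n", x$n_sites, x$n_vb))
  cat("VB sites by number of types (k):\n")
  print(x$types_per_site)
  cat("\n")
  print(x$diversity)
  invisible(x)
}

#' Plot per-sample block maps
#'
#' One horizontal lane per sample and chromosome; dense blocks are drawn
#' dark, sparse blocks light, with pooled recombination sites as ticks.
#'
#' @param x A `vb_analysis`.
#' @param chrom Chromosome to draw (default: the first of the layout).
#' @param ... Unused.
#' @exportS3Method
plot.vb_analysis <- function(x, chrom = x$layout$chrom[1], ...) {
  n <- length(x$samples)
  len <- x$layout$length[x$layout$chrom == chrom]
  graphics::plot(NULL, xlim = c(0, len / 1e6), ylim = c(0.5, n + 0.5),
                 xlab = sprintf("%s position (Mb)", chrom), ylab = "",
                 yaxt = "n", bty = "n")
  graphics::axis(2, at = seq_len(n), labels = rev(x$samples), las = 1)
  for (i in seq_len(n)) {
    b <- x$maps[[x$samples[i]]]$blocks
    b <- b[b$chrom == chrom, , drop = FALSE]
    graphics::rect(b$start / 1e6, n - i + 0.7, b$end / 1e6, n - i + 1.3,
                   col = ifelse(b$label == "dVB", "grey20", "grey85"),
                   border = NA)
  }
  graphics::axis(1)
  s <- x$sites[[chrom]]
  if (length(s))
    graphics::segments(s / 1e6, 0.5, s / 1e6, 0.6, col = "red")
  invisible(x)
}
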