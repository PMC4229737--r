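# Scoring detected blocks and variants against a reference standard or
# simulator truth, and the depth-robustness experiment.

.dense_intervals <- function(x) {
  if (inherits(x, "sample_block_map")) x <- x$blocks
  lab <- if ("label" %in% names(x)) x$label else
    stop("intervals need a 'label' column", call. = FALSE)
  x[lab %in% c("dVB", "dense"), c("chrom", "start", "end"), drop = FALSE]
}

#' Base-level sensitivity and precision of dense-block detection
#'
#' Overlap of the dense (dVB) regions of a detected block map with a set of
#' reference dense intervals (simulator truth or a full-depth standard):
#' sensitivity is the fraction of reference dense bases recovered,
#' precision the fraction of detected dense bases that are real.
#'
#' @param detected `sample_block_map` (or interval data frame with a
#'   `label` column; labels `dVB`/`dense` count as dense).
#' @param truth Reference intervals in the same formats.
#' @return List with `sensitivity` and `precision` (NA when the respective
#'   denominator is empty).
#' @export
interval_metrics <- function(detected, truth) {
  d <- .dense_intervals(detected)
  t <- .dense_intervals(truth)
  ov <- .overlap_bp(d, t)
  tb <- .interval_bp(t)
  db <- .interval_bp(d)
  list(sensitivity = if (tb > 0) ov / tb else NA_real_,
       precision = if (db > 0) ov / db else NA_real_)
}

#' Sensitivity and precision of SNV recovery
#'
#' Variants match on (chromosome, position, alt allele).
#'
#' @param called,truth `variant_set`s.
#' @return List with `sensitivity` (NA for empty truth) and `precision`.
#' @export
snv_metrics <- function(called, truth) {
  kc <- .keyv(called$variants$chrom, ":", called$variants$pos, ":",
              called$variants$alt)
  kt <- .keyv(truth$variants$chrom, ":", truth$variants$pos, ":",
              truth$variants$alt)
  hit <- length(intersect(kc, kt))
  list(sensitivity = if (length(kt) > 0) hit / length(kt) else NA_real_,
       precision = if (length(kc) > 0) hit / length(kc) else NA_real_)
}

#' Depth-robustness performance curve
#'
#' Reproduces the depth experiment on one genome: block detection on the
#' full homozygous-SNV set is the standard; for each depth of the model the
#' SNV set is Bernoulli-thinned at that depth's retention, detection is
#' rerun, and SNV and dense-block (base-level) sensitivity/precision are
#' scored against the full-depth standard, averaged over seeds.
#'
#' @param full `variant_set` of homozygous SNVs at full depth.
#' @param dm `depth_model`.
#' @param layout `genome_layout`.
#' @param params `vb_params`.
#' @param seeds Integer vector of thinning seeds.
#' @return Data frame of class `performance_table` with one row per depth:
#'   `depth`, `retention`, `snv_sensitivity`, `snv_precision`,
#'   `vb_sensitivity`, `vb_precision`.
#' @export
depth_performance_curve <- function(full, dm, layout, params = vb_params(),
                                    seeds = 1:5) {
  .assert(nrow(dm) >= 1L, "depth model is empty")
  standard <- detect_blocks(full, layout, params)
  rows <- lapply(seq_len(nrow(dm)), function(i) {
    m <- vapply(seeds, function(s) {
      thin <- thin_by_depth(full, dm$retention[i], seed = s)
      det <- detect_blocks(thin, layout, params)
      im <- interval_metrics(det, standard)
      sm <- snv_metrics(thin, full)
      c(sm$sensitivity, sm$precision, im$sensitivity, im$precision)
    }, numeric(4))
    data.frame(depth = dm$depth[i], retention = dm$retention[i],
               snv_sensitivity = mean(m[1, ]), snv_precision = mean(m[2, ]),
               vb_sensitivity = mean(m[3, ]), vb_precision = mean(m[4, ]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Fold ratio of two recombination rates
#'
#' Events per unit length in region class 1 over events per unit length in
#' region class 2 — e.g. the sparse-block versus dense-block recombination
#' contrast measured from RIL crossover counts.
#'
#' @param events_1,events_2 Event counts in the two region classes.
#' @param span_1,span_2 Total lengths of the two classes (any common unit).
#' @return The fold ratio (rate 1 / rate 2).
#' @export
#' @examples
#' recombination_rate_ratio(113, 1190, 9, 630)  # ~6.65
recombination_rate_ratio <- function(events_1, span_1, events_2, span_2) {
  .assert(span_1 > 0 && span_2 > 0, "spans must be positive")
  .assert(events_2 > 0, "events_2 must be > 0 for a finite ratio")
  (events_1 / span_1) / (events_2 / span_2)
}
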