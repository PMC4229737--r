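#' Method parameters for variation-block analysis
#'
#' Bundles every tunable threshold of the variation-block (VB) pipeline.
#' Defaults are the published operating point of the method on resequenced
#' soybean cultivars and transfer unchanged to other inbreeding crops with
#' a reference genome of comparable SNV density.
#'
#' @param bin_size Width in bp of the genome bins over which homozygous-SNV
#'   density is counted. Default 10,000 bp.
#' @param dense_snv_threshold Minimum homozygous SNV count for a bin to be
#'   labelled dense (dRB); bins with fewer SNVs are similar-to-standard
#'   (sRB). Default 4.
#' @param dvb_gap_merge Sparse gaps shorter than this (bp) lying between two
#'   dense runs are absorbed when dense runs are joined into one dVB.
#'   Default 90,000 bp.
#' @param svb_gap_merge Dense blocks shorter than this (bp) are dissolved
#'   into the surrounding sparse block (equivalently, sparse runs closer
#'   than this merge). Default 30,000 bp.
#' @param identity_threshold Minimum variant-level sequence identity for two
#'   VB instances to be of the same type. Default 0.998.
#' @param concordance_threshold Minimum SNV-set concordance (Jaccard index
#'   of position/allele pairs) for two VB instances to be of the same type.
#'   Default 0.80.
#' @param boundary_dedup_tolerance Maximum span in bp of a cluster of
#'   near-identical block boundaries pooled across samples; each cluster is
#'   replaced by its median. Default one bin (10,000 bp), the resolution
#'   limit of the binning itself.
#' @param min_marker_indel_length Minimum indel length in bp for an indel to
#'   qualify as a VB-discriminating marker ("longer than four base pairs"),
#'   i.e. 5.
#' @return An object of class `vb_params`.
#' @seealso [read_vb_params()] to load/override from a YAML config file.
#' @export
#' @examples
#' p <- vb_params()
#' p$dense_snv_threshold
vb_params <- function(bin_size = 10000,
                      dense_snv_threshold = 4,
                      dvb_gap_merge = 90000,
                      svb_gap_merge = 30000,
                      identity_threshold = 0.998,
                      concordance_threshold = 0.80,
                      boundary_dedup_tolerance = 10000,
                      min_marker_indel_length = 5) {
  p <- list(bin_size = bin_size,
            dense_snv_threshold = dense_snv_threshold,
            dvb_gap_merge = dvb_gap_merge,
            svb_gap_merge = svb_gap_merge,
            identity_threshold = identity_threshold,
            concordance_threshold = concordance_threshold,
            boundary_dedup_tolerance = boundary_dedup_tolerance,
            min_marker_indel_length = min_marker_indel_length)
  for (nm in names(p)) {
    .assert(is.numeric(p[[nm]]) && length(p[[nm]]) == 1L && p[[nm]] > 0,
            "parameter '", nm, "' must be a single positive number")
  }
  .assert(identity_threshold <= 1, "identity_threshold must be in (0, 1]")
  .assert(concordance_threshold <= 1, "concordance_threshold must be in (0, 1]")
  .assert(dense_snv_threshold >= 1, "dense_snv_threshold must be >= 1")
  structure(p, class = "vb_params")
}

#' Read method parameters from a YAML config file
#'
#' Fields present in the file override the corresponding defaults; unknown
#' fields are an error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose top-level keys are `vb_params()`
#'   argument names.
#' @param base Parameter set supplying values for fields absent from the
#'   file; defaults to `vb_params()`.
#' @return An object of class `vb_params`.
#' @export
read_vb_params <- function(path, base = vb_params()) {
  cfg <- yaml::read_yaml(path)
  .assert(is.list(cfg), "config file must contain a YAML mapping")
  unknown <- setdiff(names(cfg), names(base))
  .assert(length(unknown) == 0L,
          "unknown parameter field(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(unclass(base), cfg)
  do.call(vb_params, merged)
}

#' @exportS3Method
print.vb_params <- function(x, ...) {
  cat("Variation-block method parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
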