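#' VB diversity curve over successively added genomes
#'
#' The diversity score of a genome panel is the number of distinct VB
#' types observed across all VB sites divided by the number of VB sites.
#' The curve reports the score for every prefix of `sample_order`: a
#' single genome scores exactly 1.0, identical genomes add nothing, and
#' each novel haplotype block raises the score.
#'
#' @param assignment A `vb_types` assignment covering every sample of
#'   `sample_order` at every site.
#' @param sample_order Character vector: the order in which genomes are
#'   added.
#' @return Data frame of class `diversity_curve` with columns `k`,
#'   `sample_added` and `score`.
#' @export
diversity_curve <- function(assignment, sample_order) {
  .assert(all(sample_order %in% assignment$sample_id),
          "sample(s) missing from assignment: ",
          paste(setdiff(sample_order, assignment$sample_id), collapse = ", "))
  vbs <- unique(assignment$vb_id)
  tmat <- vapply(sample_order, function(s) {
    tl <- .type_lookup(assignment, s)
    .assert(all(vbs %in% names(tl)),
            "sample '", s, "' is not typed at every VB site")
    tl[vbs]
  }, numeric(length(vbs)))
  tmat <- matrix(tmat, nrow = length(vbs))
  score <- vapply(seq_along(sample_order), function(k) {
    sum(apply(tmat[, seq_len(k), drop = FALSE], 1L,
              function(z) length(unique(z)))) / length(vbs)
  }, numeric(1))
  out <- data.frame(k = seq_along(sample_order), sample_added = sample_order,
                    score = score, stringsAsFactors = FALSE)
  class(out) <- c("diversity_curve", "data.frame")
  out
}

#' Order-averaged VB diversity curve
#'
#' The diversity curve depends on the order in which genomes are added
#' (except for its endpoint). This averages [diversity_curve()] over
#' random permutations.
#'
#' @param assignment A `vb_types` assignment.
#' @param samples Samples to permute.
#' @param n_orders Number of random permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @return Data frame with columns `k`, `mean_score` and `sd_score`
#'   (`sd_score` is 0 when `n_orders` is 1).
#' @export
diversity_curve_randomized <- function(assignment, samples, n_orders = 100,
                                       seed = 1) {
  .assert(n_orders >= 1, "n_orders must be >= 1")
  set.seed(seed)
  scores <- vapply(seq_len(n_orders), function(i) {
    diversity_curve(assignment, sample(samples))$score
  }, numeric(length(samples)))
  scores <- matrix(scores, nrow = length(samples))
  sds <- apply(scores, 1L, stats::sd)
  data.frame(k = seq_along(samples),
             mean_score = rowMeans(scores),
             sd_score = ifelse(is.na(sds), 0, sds))
}

#' @exportS3Method
print.diversity_curve <- function(x, ...) {
  cat(sprintf(
    "VB diversity curve over %d genome(s); final score %.3f unique types per site\n",
    nrow(x), x$score[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}
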