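# Indel-marker selection and the hierarchical single-marker trait screen.

#' Select VB-discriminating indel markers between two samples
#'
#' Homozygous indels of length at least `min_marker_indel_length` ("longer
#' than four base pairs") that are present in exactly one of the two
#' samples, restricted to VB sites where the two samples carry different
#' types — the only sites a marker can discriminate.
#'
#' @param vs_a,vs_b `variant_set`s of the two parents.
#' @param frame `vb_frame` data frame.
#' @param assignment `vb_types` assignment covering both samples.
#' @param params `vb_params`.
#' @return Data frame of class `indel_markers` with columns `marker_id`,
#'   `chrom`, `pos`, `indel_length`, `carrier`, `vb_id`.
#' @export
select_indel_markers <- function(vs_a, vs_b, frame, assignment,
                                 params = vb_params()) {
  pick <- function(vs) {
    v <- vs$variants
    v <- v[v$kind == "indel" & v$zygosity == "hom" &
             v$indel_length >= params$min_marker_indel_length, ,
           drop = FALSE]
    v$key <- .keyv(v$chrom, ":", v$pos, ":", v$ref, ":", v$alt)
    v
  }
  a <- pick(vs_a); b <- pick(vs_b)
  a$carrier <- vs_a$sample_id
  b$carrier <- vs_b$sample_id
  private <- rbind(a[!(a$key %in% b$key), , drop = FALSE],
                   b[!(b$key %in% a$key), , drop = FALSE])
  ta <- .type_lookup(assignment, vs_a$sample_id)
  tb <- .type_lookup(assignment, vs_b$sample_id)
  discordant <- names(ta)[!is.na(tb[names(ta)]) & ta != tb[names(ta)]]
  out <- list()
  for (ch in unique(private$chrom)) {
    fb <- frame[frame$chrom == ch, , drop = FALSE]
    pv <- private[private$chrom == ch, , drop = FALSE]
    if (nrow(fb) == 0L || nrow(pv) == 0L) next
    vb <- fb$vb_id[findInterval(pv$pos - 1, fb$start)]
    keep <- vb %in% discordant
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = pv$chrom[keep], pos = pv$pos[keep],
                            indel_length = pv$indel_length[keep],
                            carrier = pv$carrier[keep], vb_id = vb[keep],
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(),
               indel_length = numeric(), carrier = character(),
               vb_id = character(), stringsAsFactors = FALSE)
  res <- res[order(match(res$chrom, unique(frame$chrom)), res$pos), ,
             drop = FALSE]
  rownames(res) <- NULL
  res <- cbind(marker_id = sprintf("M%05d", seq_len(nrow(res))), res)
  res$marker_id <- as.character(res$marker_id)
  class(res) <- c("indel_markers", "data.frame")
  res
}

#' One representative marker per VB
#'
#' Because recombination within dense blocks is rare, one marker suffices
#' to represent a block. Per VB the marker closest to the block midpoint is
#' chosen; ties break to the lower coordinate. VBs without candidates are
#' absent from the panel and reported via `message()`.
#'
#' @param markers `indel_markers` data frame.
#' @param frame `vb_frame` data frame.
#' @return `indel_markers` subset of class `marker_panel` with unique
#'   `vb_id`s.
#' @export
representative_markers <- function(markers, frame) {
  if (nrow(markers) == 0L) {
    message("no candidate markers; empty panel")
    res <- markers
    class(res) <- c("marker_panel", class(markers))
    return(res)
  }
  mid <- stats::setNames((frame$start + frame$end) / 2, frame$vb_id)
  keep <- unlist(lapply(split(seq_len(nrow(markers)), markers$vb_id),
                        function(idx) {
    d <- abs(markers$pos[idx] - 1 - mid[[markers$vb_id[idx[1L]]]])
    idx[order(d, markers$pos[idx])][1L]
  }), use.names = FALSE)
  uncovered <- setdiff(frame$vb_id, markers$vb_id)
  if (length(uncovered) > 0L)
    message(length(uncovered), " VB(s) without a candidate marker")
  res <- markers[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_panel", "indel_markers", "data.frame")
  res
}

#' Single-marker association of genotypes with a binary phenotype
#'
#' Per marker, the Pearson correlation r between the 0/1 genotype codes and
#' the 0/1 phenotype over RILs with non-missing data, plus the single-
#' marker LOD approximation `n/2 * log10(1 / (1 - r^2))` (infinite for a
#' perfectly cosegregating marker). Markers are ranked by |r|; a marker
#' with fewer than 2 informative RILs or zero variance is reported as NA.
#'
#' @param genotypes Matrix or data frame, RILs in rows, markers in columns,
#'   entries 0/1/NA (heterozygous calls should be coded NA upstream).
#' @param phenotype 0/1 vector, one entry per RIL.
#' @return Data frame of class `assoc_result` with columns `marker`, `n`,
#'   `r`, `lod`, sorted by decreasing |r|.
#' @export
marker_trait_association <- function(genotypes, phenotype) {
  g <- as.matrix(genotypes)
  .assert(nrow(g) == length(phenotype),
          "phenotype length must equal the number of RIL rows")
  res <- lapply(colnames(g), function(m) {
    ok <- !is.na(g[, m]) & !is.na(phenotype)
    n <- sum(ok)
    if (n < 2L || stats::sd(g[ok, m]) == 0 || stats::sd(phenotype[ok]) == 0)
      return(data.frame(marker = m, n = n, r = NA_real_, lod = NA_real_))
    r <- stats::cor(g[ok, m], phenotype[ok])
    if (1 - r^2 < 1e-12) r <- sign(r)     # exact cosegregation up to fp error
    lod <- n / 2 * log10(1 / (1 - r^2))
    data.frame(marker = m, n = n, r = r, lod = lod)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$r), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Three-pass hierarchical screen for a trait locus
#'
#' Pass 1 associates the genome-wide one-marker-per-VB panel and picks the
#' top VB by |r|. Pass 2 re-associates one representative marker per VB
#' within a window around that VB. Pass 3 associates every marker inside
#' the best pass-2 VB and brackets the locus by the closest flanking
#' markers that show recombinants with the trait (block edges when none
#' exist on a side).
#'
#' @param markers Full `indel_markers` table.
#' @param panel Genome-wide `marker_panel` (one marker per VB).
#' @param frame `vb_frame` data frame.
#' @param genotypes Genotype matrix over at least all panel and candidate
#'   markers (columns named by `marker_id`).
#' @param phenotype 0/1 phenotype vector.
#' @param window Half-width in bp of the pass-2 region around the pass-1
#'   VB midpoint (default 1 Mb, i.e. a 2 Mb target region).
#' @param r_floor |r| below which the result is flagged `"low"` confidence
#'   (default 0.5).
#' @return List of class `vb_screen`: `interval` (chrom/start/end data
#'   frame), `vb_id`, `best_marker`, `r`, `confidence`, and the per-pass
#'   association tables in `passes`.
#' @export
hierarchical_screen <- function(markers, panel, frame, genotypes, phenotype,
                                window = 1e6, r_floor = 0.5) {
  .assert(nrow(panel) > 0L, "empty genome-wide marker panel")
  assoc1 <- marker_trait_association(
    genotypes[, intersect(colnames(genotypes), panel$marker_id),
              drop = FALSE], phenotype)
  .assert(any(!is.na(assoc1$r)), "no informative marker in pass 1")
  top1 <- assoc1$marker[which.max(abs(assoc1$r))]
  vb1 <- panel$vb_id[panel$marker_id == top1]
  f1 <- frame[frame$vb_id == vb1, , drop = FALSE]
  mid1 <- (f1$start + f1$end) / 2

  cand2 <- markers[markers$chrom == f1$chrom &
                     markers$pos - 1 >= mid1 - window &
                     markers$pos - 1 <= mid1 + window, , drop = FALSE]
  if (nrow(cand2) == 0L) cand2 <- markers[markers$vb_id == vb1, , drop = FALSE]
  panel2 <- representative_markers(cand2, frame)
  assoc2 <- marker_trait_association(
    genotypes[, intersect(colnames(genotypes), panel2$marker_id),
              drop = FALSE], phenotype)
  top2 <- assoc2$marker[which.max(abs(assoc2$r))]
  vb2 <- panel2$vb_id[panel2$marker_id == top2]
  f2 <- frame[frame$vb_id == vb2, , drop = FALSE]

  cand3 <- markers[markers$vb_id == vb2, , drop = FALSE]
  assoc3 <- marker_trait_association(
    genotypes[, intersect(colnames(genotypes), cand3$marker_id),
              drop = FALSE], phenotype)
  best <- assoc3$marker[which.max(abs(assoc3$r))]
  best_pos <- cand3$pos[cand3$marker_id == best]
  best_r <- assoc3$r[assoc3$marker == best]

  # recombinants relative to coupling phase: mismatches under whichever
  # coding of the marker is the better fit
  n_rec <- vapply(cand3$marker_id, function(m) {
    ok <- !is.na(genotypes[, m]) & !is.na(phenotype)
    mm <- sum(genotypes[ok, m] != phenotype[ok])
    min(mm, sum(ok) - mm)
  }, numeric(1))
  rec_pos <- cand3$pos[n_rec >= 1]
  left <- rec_pos[rec_pos < best_pos]
  right <- rec_pos[rec_pos > best_pos]
  interval <- data.frame(
    chrom = f2$chrom,
    start = if (length(left)) max(left) - 1 else f2$start,
    end = if (length(right)) min(right) else f2$end)

  structure(list(interval = interval, vb_id = vb2, best_marker = best,
                 r = best_r,
                 confidence = if (abs(best_r) < r_floor) "low" else "high",
                 passes = list(assoc1, assoc2, assoc3)),
            class = "vb_screen")
}

#' @exportS3Method
print.vb_screen <- function(x, ...) {
  cat(sprintf(
    "Hierarchical VB screen: locus at %s:%.0f-%.0f (block %s)\n",
    x$interval$chrom, x$interval$start, x$interval$end, x$vb_id))
  cat(sprintf("  best marker %s, r = %.3f, confidence: %s\n",
              x$best_marker, x$r, x$confidence))
  invisible(x)
}

#' Kosambi map distance from a recombination fraction
#'
#' `25 * ln((1 + 2r) / (1 - 2r))` centimorgans, the mapping function that
#' allows for crossover interference; defined for `0 <= r < 0.5`.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Genetic distance(s) in cM.
#' @export
#' @examples
#' kosambi_cm(0.25)  # 27.47 cM
kosambi_cm <- function(r) {
  .assert(all(r >= 0 & r < 0.5), "recombination fractions must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}
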