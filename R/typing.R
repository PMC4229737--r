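# VB typing: decide when two block instances descend from the same
# parental haplotype, and derive per-site type assignments.

.inst_check_pair <- function(a, b) {
  .assert(inherits(a, "vb_instances") && inherits(b, "vb_instances") &&
            nrow(a) == 1L && nrow(b) == 1L,
          "a and b must be single-row vb_instances")
  .assert(a$vb_id == b$vb_id,
          "instances are from different VB sites (",
          a$vb_id, " vs ", b$vb_id, ")")
}

.keys <- function(snv) paste0(snv$pos, ":", snv$alt)

.concordance_sets <- function(ka, kb) {
  if (length(ka) == 0L && length(kb) == 0L) return(1.0)
  m <- length(intersect(ka, kb))
  m / length(union(ka, kb))
}

.identity_sets <- function(ka, kb, pa, pb, L) {
  m <- length(intersect(ka, kb))        # positions with the same alt
  d <- length(union(pa, pb)) - m        # discordant positions, counted once
  1 - d / L
}

#' SNV concordance between two VB instances
#'
#' Jaccard index of the two (position, alt allele) sets: the fraction of
#' all SNVs present in either instance that are shared. Two empty sets are
#' fully concordant (1.0).
#'
#' @param a,b Single-row `vb_instances` at the same VB site.
#' @return A fraction in \[0, 1\].
#' @export
snv_concordance <- function(a, b) {
  .inst_check_pair(a, b)
  .concordance_sets(.keys(a$snv[[1L]]), .keys(b$snv[[1L]]))
}

#' Variant-level sequence identity between two VB instances
#'
#' `1 - D/L`, where `L` is the VB interval length and `D` counts each
#' position at which the two instances differ once: positions carried by
#' only one instance, plus positions where both carry different alternate
#' alleles. A proxy for per-base alignment identity computed from the
#' variant calls alone.
#'
#' @param a,b Single-row `vb_instances` at the same VB site, with interval
#'   length > 0.
#' @return A fraction in \[0, 1\].
#' @export
variant_identity <- function(a, b) {
  .inst_check_pair(a, b)
  L <- a$end - a$start
  .assert(L > 0, "VB interval length must be > 0")
  .identity_sets(.keys(a$snv[[1L]]), .keys(b$snv[[1L]]),
                 a$snv[[1L]]$pos, b$snv[[1L]]$pos, L)
}

#' Same-type decision for two VB instances
#'
#' Two instances are of the same type — descend from a common parental
#' haplotype — iff variant identity meets `identity_threshold` (default
#' 0.998) and SNV concordance meets `concordance_threshold` (default 0.80).
#'
#' @inheritParams snv_concordance
#' @param params `vb_params`.
#' @return Logical.
#' @export
same_type <- function(a, b, params = vb_params()) {
  variant_identity(a, b) >= params$identity_threshold &&
    snv_concordance(a, b) >= params$concordance_threshold
}

#' Group VB instances into types at every VB site
#'
#' At each VB site, samples are grouped by single-linkage connected
#' components of the pairwise same-type relation; component indices are
#' ordered by the smallest sample index (order of first appearance in
#' `instances`) they contain, so typing is deterministic.
#'
#' @param instances `vb_instances` for all samples over a shared frame
#'   (rows for several samples, e.g. `rbind` of [annotate_instances()]
#'   results).
#' @param params `vb_params`.
#' @return Data frame of class `vb_types` with columns `vb_id`,
#'   `sample_id`, `type` (1..k within the site) and `k` (number of distinct
#'   types at the site).
#' @export
assign_types <- function(instances, params = vb_params()) {
  samples <- unique(instances$sample_id)
  res <- vector("list", 0L)
  for (vb in unique(instances$vb_id)) {
    inst <- instances[instances$vb_id == vb, , drop = FALSE]
    inst <- inst[match(intersect(samples, inst$sample_id), inst$sample_id), ,
                 drop = FALSE]
    n <- nrow(inst)
    L <- inst$end[1L] - inst$start[1L]
    keys <- lapply(inst$snv, .keys)
    poss <- lapply(inst$snv, `[[`, "pos")
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        idv <- .identity_sets(keys[[i]], keys[[j]], poss[[i]], poss[[j]], L)
        if (idv < params$identity_threshold) next
        if (.concordance_sets(keys[[i]], keys[[j]]) <
              params$concordance_threshold) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    type <- match(roots, unique(roots))   # ordered by smallest member index
    res[[length(res) + 1L]] <- data.frame(
      vb_id = vb, sample_id = inst$sample_id, type = type,
      k = length(unique(type)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("vb_types", "data.frame")
  out
}

.type_lookup <- function(assignment, sample) {
  .assert(sample %in% assignment$sample_id, "unknown sample: ", sample)
  a <- assignment[assignment$sample_id == sample, , drop = FALSE]
  stats::setNames(a$type, a$vb_id)
}

#' Parental origin of each VB site of a descendant
#'
#' A site is assigned to a parent when the descendant shares a type with
#' exactly that parent, to `both` when it shares with both, and is
#' `unassigned` when it matches neither — the signature of a block not
#' inherited intact (or absent from the parents).
#'
#' @param assignment A `vb_types` assignment covering all three samples.
#' @param descendant,parent_a,parent_b Sample ids.
#' @return Data frame of class `origin_track` with columns `vb_id` and
#'   `origin` in `{"parentA","parentB","both","unassigned"}`.
#' @export
parental_origin <- function(assignment, descendant, parent_a, parent_b) {
  td <- .type_lookup(assignment, descendant)
  ta <- .type_lookup(assignment, parent_a)
  tb <- .type_lookup(assignment, parent_b)
  vbs <- names(td)
  ma <- !is.na(ta[vbs]) & td == ta[vbs]
  mb <- !is.na(tb[vbs]) & td == tb[vbs]
  origin <- ifelse(ma & mb, "both",
                   ifelse(ma, "parentA",
                          ifelse(mb, "parentB", "unassigned")))
  out <- data.frame(vb_id = vbs, origin = unname(origin),
                    stringsAsFactors = FALSE)
  class(out) <- c("origin_track", "data.frame")
  out
}

#' Fraction of VB sites whose type recurs in another sample group
#'
#' For each sample of group A, the fraction of its VB sites whose type is
#' carried by at least one sample of group B — e.g. how much of a cultivar
#' genome is present among wild accessions at block level.
#'
#' @param assignment A `vb_types` assignment.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids.
#' @return Named numeric vector, one fraction per sample of `group_a`.
#' @export
shared_vb_fraction <- function(assignment, group_a, group_b) {
  .assert(length(group_a) > 0L && length(group_b) > 0L,
          "both groups must be non-empty")
  .assert(length(intersect(group_a, group_b)) == 0L,
          "groups must be disjoint")
  blook <- lapply(group_b, .type_lookup, assignment = assignment)
  vapply(group_a, function(s) {
    ta <- .type_lookup(assignment, s)
    vbs <- names(ta)
    hit <- Reduce(`|`, lapply(blook, function(tb)
      !is.na(tb[vbs]) & ta == tb[vbs]))
    mean(hit)
  }, numeric(1))
}
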