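# Breeding-genome simulator: founder haplotype mosaics, crossover-biased
# crosses, RIL populations and depth-dependent SNV dropout, all with
# truth tracks, so every stage of the block pipeline can be scored
# against known ground truth.

#' Segment model for simulated founder genomes
#'
#' Founder genomes are mosaics of ancestral segments. Each segment offers a
#' shared reference-like haplotype (sparse: the genome matches the
#' reference standard there, SNV density `lambda_sparse`) plus a pool of
#' `n_haplotypes` divergent haplotypes (dense, density `lambda_dense`);
#' founders drawing the same haplotype for a segment are identical there.
#' Indels are placed alongside SNVs at `indel_rate` indels per SNV with
#' lengths uniform over `indel_len_range`.
#'
#' @param lambda_dense Homozygous SNVs per kb in dense segments
#'   (default 3.8).
#' @param lambda_sparse SNVs per kb in sparse (reference-like) segments
#'   (default 0.05).
#' @param seg_len_range Segment length range in bp (default 0.1-3 Mb).
#' @param dense_fraction Expected fraction of a founder genome in dense
#'   segments (default 0.4).
#' @param n_haplotypes Size of the dense ancestral haplotype pool per
#'   segment (default 3, reflecting the narrow pedigree of a breeding
#'   pool).
#' @param indel_rate Indels per SNV (default 0.2).
#' @param indel_len_range Integer range of indel lengths in bp.
#' @return Object of class `segment_model`.
#' @export
segment_model <- function(lambda_dense = 3.8, lambda_sparse = 0.05,
                          seg_len_range = c(1e5, 3e6), dense_fraction = 0.4,
                          n_haplotypes = 3, indel_rate = 0.2,
                          indel_len_range = c(1, 15)) {
  .assert(lambda_dense > lambda_sparse && lambda_sparse >= 0,
          "need lambda_dense > lambda_sparse >= 0")
  .assert(dense_fraction >= 0 && dense_fraction <= 1,
          "dense_fraction must be in [0, 1]")
  .assert(length(seg_len_range) == 2L && seg_len_range[1] > 0 &&
            seg_len_range[1] <= seg_len_range[2],
          "invalid segment length range")
  .assert(n_haplotypes >= 1, "need at least one dense haplotype")
  structure(list(lambda_dense = lambda_dense, lambda_sparse = lambda_sparse,
                 seg_len_range = seg_len_range,
                 dense_fraction = dense_fraction,
                 n_haplotypes = n_haplotypes, indel_rate = indel_rate,
                 indel_len_range = indel_len_range),
            class = "segment_model")
}

.rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one ancestral haplotype for a segment: fixed SNV/indel set
.make_haplotype <- function(chrom, start, end, lambda, indel_rate,
                            indel_len_range) {
  len <- end - start
  n_snv <- stats::rpois(1L, lambda * len / 1000)
  n_ind <- stats::rpois(1L, indel_rate * lambda * len / 1000)
  n <- min(n_snv + n_ind, len)
  if (n == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      zygosity = character(), stringsAsFactors = FALSE))
  pos <- start + sample.int(len, n)          # 1-based, inside (start, end]
  n_snv <- min(n_snv, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- ref
  if (n_snv > 0L) {
    for (i in seq_len(n_snv))
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
  }
  if (n > n_snv) {
    for (i in (n_snv + 1L):n) {
      l <- sample(indel_len_range[1]:indel_len_range[2], 1L)
      if (stats::runif(1) < 0.5) {
        alt[i] <- paste0(ref[i], .rand_bases(l))   # insertion
      } else {
        ref[i] <- paste0(ref[i], .rand_bases(l))   # deletion
      }
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             zygosity = "hom", stringsAsFactors = FALSE)
}

#' Simulate founder genomes as ancestral haplotype mosaics
#'
#' A common segment grid is drawn per chromosome (lengths uniform over the
#' model's range); each segment gets a fixed haplotype pool; each founder
#' picks per segment either the shared reference-like sparse haplotype
#' (probability `1 - dense_fraction`) or one of the dense pool haplotypes.
#' Founders sharing a haplotype are exactly identical over that segment.
#'
#' @param layout `genome_layout`.
#' @param model `segment_model`.
#' @param n_founders Number of founder genomes (>= 1).
#' @param seed Integer seed; all draws are deterministic given it.
#' @return Object of class `founder_sim`: `variant_sets` (named list of
#'   `variant_set`), `truth` (named list of per-founder data frames with
#'   `chrom`, `start`, `end`, `label` in dense/sparse and `hap_id`),
#'   `layout`, `model`.
#' @export
simulate_founders <- function(layout, model = segment_model(), n_founders,
                              seed) {
  .assert(n_founders >= 1, "n_founders must be >= 1")
  set.seed(as.integer(seed))
  segs <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; clen <- layout$length[i]
    pos <- 0
    while (pos < clen) {
      len <- min(round(stats::runif(1, model$seg_len_range[1],
                                    model$seg_len_range[2])), clen - pos)
      segs[[length(segs) + 1L]] <- list(chrom = ch, start = pos,
                                        end = pos + len)
      pos <- pos + len
    }
  }
  # fixed haplotype pool per segment: "ref" (sparse) + dense haplotypes
  pools <- lapply(segs, function(sg) {
    haps <- list(ref = .make_haplotype(sg$chrom, sg$start, sg$end,
                                       model$lambda_sparse,
                                       model$indel_rate,
                                       model$indel_len_range))
    for (h in seq_len(model$n_haplotypes)) {
      haps[[paste0("hap", h)]] <- .make_haplotype(
        sg$chrom, sg$start, sg$end, model$lambda_dense,
        model$indel_rate, model$indel_len_range)
    }
    haps
  })
  founders <- paste0("F", seq_len(n_founders))
  variant_sets <- list()
  truth <- list()
  for (f in founders) {
    picks <- vapply(seq_along(segs), function(j) {
      if (stats::runif(1) >= model$dense_fraction) "ref" else
        paste0("hap", sample.int(model$n_haplotypes, 1L))
    }, character(1))
    vars <- do.call(rbind, lapply(seq_along(segs), function(j)
      pools[[j]][[picks[j]]]))
    variant_sets[[f]] <- variant_set(f, vars, layout)
    truth[[f]] <- data.frame(
      chrom = vapply(segs, `[[`, "", "chrom"),
      start = vapply(segs, `[[`, 0, "start"),
      end = vapply(segs, `[[`, 0, "end"),
      label = ifelse(picks == "ref", "sparse", "dense"),
      hap_id = paste0(vapply(segs, function(s)
        paste0(s$chrom, ":", s$start), ""), "/", picks),
      stringsAsFactors = FALSE)
  }
  structure(list(variant_sets = variant_sets, truth = truth,
                 layout = layout, model = model),
            class = "founder_sim")
}

# overlay two truth tracks: per chromosome, the refinement of both segment
# grids with both haplotype ids
.overlay_truth <- function(ta, tb) {
  out <- list()
  for (ch in unique(ta$chrom)) {
    a <- ta[ta$chrom == ch, , drop = FALSE]
    b <- tb[tb$chrom == ch, , drop = FALSE]
    edges <- sort(unique(c(a$start, a$end, b$start, b$end)))
    s <- edges[-length(edges)]; e <- edges[-1L]
    ia <- findInterval(s, a$start)
    ib <- findInterval(s, b$start)
    out[[ch]] <- data.frame(chrom = ch, start = s, end = e,
                            hap_a = a$hap_id[ia], hap_b = b$hap_id[ib],
                            label_a = a$label[ia], label_b = b$label[ib],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a cross: a descendant crossover mosaic of two parents
#'
#' Crossover positions are sampled with per-bp weight `sparse_bias` in
#' regions where the two parents carry the same ancestral haplotype
#' (recombination concentrates where sequences are identical) and 1
#' elsewhere. The descendant copies parental variants segment-wise.
#'
#' @param parent_a,parent_b Parental `variant_set`s.
#' @param truth_a,truth_b Their truth tracks (as in `founder_sim$truth`).
#' @param layout `genome_layout`.
#' @param n_crossovers Total crossover count across the genome (>= 0).
#' @param sparse_bias Crossover weight of identical regions relative to
#'   differing regions (default 6.6).
#' @param seed Integer seed.
#' @param sample_id Name of the descendant.
#' @return Object of class `cross_sim`: `variant_set`, and `truth` with
#'   `origins` (chrom/start/end/origin in "A"/"B"), `crossovers`
#'   (chrom/pos) and `segments` (inherited haplotype track in the founder
#'   truth format).
#' @export
simulate_cross <- function(parent_a, parent_b, truth_a, truth_b, layout,
                           n_crossovers = 20, sparse_bias = 6.6, seed,
                           sample_id = "cross") {
  .assert(n_crossovers >= 0, "n_crossovers must be >= 0")
  set.seed(as.integer(seed))
  ov <- .overlay_truth(truth_a, truth_b)
  w <- (ov$end - ov$start) * ifelse(ov$hap_a == ov$hap_b, sparse_bias, 1)
  xo <- data.frame(chrom = character(), pos = numeric())
  if (n_crossovers > 0) {
    reg <- sample.int(nrow(ov), n_crossovers, replace = TRUE, prob = w)
    pos <- floor(ov$start[reg] +
                   stats::runif(n_crossovers) * (ov$end[reg] - ov$start[reg]))
    xo <- unique(data.frame(chrom = ov$chrom[reg], pos = pos,
                            stringsAsFactors = FALSE))
    while (nrow(xo) < n_crossovers) {     # replace colliding duplicates
      reg2 <- sample.int(nrow(ov), n_crossovers - nrow(xo), replace = TRUE,
                         prob = w)
      pos2 <- floor(ov$start[reg2] +
                      stats::runif(length(reg2)) * (ov$end[reg2] - ov$start[reg2]))
      xo <- unique(rbind(xo, data.frame(chrom = ov$chrom[reg2], pos = pos2,
                                        stringsAsFactors = FALSE)))
    }
  }
  lens <- .chrom_lengths(layout)
  origins <- list()
  for (ch in layout$chrom) {
    px <- sort(xo$pos[xo$chrom == ch])
    cur <- sample(c("A", "B"), 1L)
    edges <- c(0, px, lens[[ch]])
    lab <- rep(c(cur, setdiff(c("A", "B"), cur)),
               length.out = length(edges) - 1L)
    origins[[ch]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                                end = edges[-1L], origin = lab,
                                stringsAsFactors = FALSE)
  }
  origins <- do.call(rbind, origins)
  origins <- origins[origins$end > origins$start, , drop = FALSE]
  rownames(origins) <- NULL

  pv <- list(A = parent_a$variants, B = parent_b$variants)
  tr <- list(A = truth_a, B = truth_b)
  vars <- list(); seg <- list()
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    v <- pv[[o$origin]]
    sel <- v$chrom == o$chrom & v$pos - 1 >= o$start & v$pos - 1 < o$end
    vars[[i]] <- v[sel, , drop = FALSE]
    t <- tr[[o$origin]]
    ts <- t[t$chrom == o$chrom & t$end > o$start & t$start < o$end, ,
            drop = FALSE]
    if (nrow(ts) > 0L) {
      ts$start <- pmax(ts$start, o$start)
      ts$end <- pmin(ts$end, o$end)
      seg[[length(seg) + 1L]] <- ts
    }
  }
  vs <- variant_set(sample_id, do.call(rbind, vars), layout)
  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL
  structure(list(variant_set = vs,
                 truth = list(origins = origins, crossovers = xo,
                              segments = segments)),
            class = "cross_sim")
}

#' Simulate a recombinant inbred line population
#'
#' Each RIL is modelled as an independent near-homozygous mosaic of the two
#' parental origins: per chromosome and meiosis, a Poisson number of
#' crossovers (default mean 1) at uniform positions, accumulated over
#' `generations` meioses, toggling parental origin. Marker genotypes are
#' read off the true origin at each marker position (0 = parent A,
#' 1 = parent B); the phenotype is the indicator of carrying the `carrier`
#' parent's origin at the causal VB midpoint (full penetrance).
#'
#' @param layout `genome_layout`.
#' @param markers Data frame with `marker_id`, `chrom`, `pos` (1-based),
#'   e.g. an `indel_markers` table.
#' @param causal_vb Single-row data frame (or list) with `chrom`, `start`,
#'   `end`: the block carrying the causal locus.
#' @param n_rils Number of RILs.
#' @param generations Number of meioses accumulated (>= 2 for an inbred
#'   line population; F4-like default 4).
#' @param xo_per_meiosis Mean crossovers per chromosome per meiosis
#'   (default 1).
#' @param carrier `"A"` or `"B"`: the parent whose allele at the causal
#'   block gives phenotype 1.
#' @param seed Integer seed.
#' @return Object of class `ril_sim`: `genotypes` (n_rils x markers 0/1
#'   matrix), `phenotype` (0/1 vector), `truth` (per-RIL list with chrom
#'   start origins and crossover positions), `causal_vb`.
#' @export
simulate_ril_population <- function(layout, markers, causal_vb, n_rils,
                                    generations = 4, xo_per_meiosis = 1,
                                    carrier = "A", seed) {
  .assert(generations >= 2, "generations must be >= 2")
  .assert(carrier %in% c("A", "B"), "carrier must be 'A' or 'B'")
  causal_vb <- as.list(causal_vb)
  .assert(all(c("chrom", "start", "end") %in% names(causal_vb)),
          "causal_vb needs chrom, start, end")
  .assert(causal_vb$chrom %in% layout$chrom,
          "causal_vb chromosome not in layout")
  set.seed(as.integer(seed))
  lens <- .chrom_lengths(layout)
  cmid <- (causal_vb$start + causal_vb$end) / 2
  geno <- matrix(NA_integer_, nrow = n_rils, ncol = nrow(markers),
                 dimnames = list(NULL, markers$marker_id))
  pheno <- integer(n_rils)
  truth <- vector("list", n_rils)
  origin_at <- function(x, start_o, xos) {
    n_below <- sum(xos < x)
    if (n_below %% 2L == 0L) start_o else setdiff(c("A", "B"), start_o)
  }
  for (r in seq_len(n_rils)) {
    starts <- stats::setNames(sample(c("A", "B"), nrow(layout),
                                     replace = TRUE), layout$chrom)
    xos <- lapply(layout$chrom, function(ch) {
      n <- stats::rpois(1L, generations * xo_per_meiosis)
      sort(stats::runif(n, 0, lens[[ch]]))
    })
    names(xos) <- layout$chrom
    for (j in seq_len(nrow(markers))) {
      ch <- markers$chrom[j]
      geno[r, j] <- as.integer(
        origin_at(markers$pos[j] - 0.5, starts[[ch]], xos[[ch]]) == "B")
    }
    pheno[r] <- as.integer(
      origin_at(cmid, starts[[causal_vb$chrom]],
                xos[[causal_vb$chrom]]) == carrier)
    truth[[r]] <- list(start_origin = starts, crossovers = xos)
  }
  structure(list(genotypes = geno, phenotype = pheno, truth = truth,
                 causal_vb = causal_vb),
            class = "ril_sim")
}

#' Depth-dependent SNV dropout model
#'
#' Maps sequencing depth (fold coverage) to the per-SNV retention
#' probability of the calling pipeline; the defaults are the published SNV
#' sensitivities (1.00 at >= 10-fold, 0.79 at 6-fold, 0.73 at 5-fold).
#'
#' @param depth Fold-coverage values.
#' @param retention Retention probability per SNV at each depth; must be
#'   non-decreasing in depth.
#' @return Data frame of class `depth_model` with columns `depth` and
#'   `retention`.
#' @export
depth_model <- function(depth = c(10, 6, 5),
                        retention = c(1.00, 0.79, 0.73)) {
  .assert(length(depth) == length(retention) && length(depth) >= 1L,
          "depth and retention must be equal-length, non-empty")
  .assert(all(retention >= 0 & retention <= 1),
          "retention probabilities must be in [0, 1]")
  ord <- order(depth)
  .assert(!is.unsorted(retention[ord]),
          "retention must be non-decreasing in depth")
  out <- data.frame(depth = depth, retention = retention)
  class(out) <- c("depth_model", "data.frame")
  out
}

#' Thin a variant set by per-SNV Bernoulli retention
#'
#' Emulates the SNV dropout of calling at reduced sequencing depth: each
#' variant is kept independently with probability `retention`.
#'
#' @param vs `variant_set`.
#' @param retention Retention probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A thinned `variant_set`.
#' @export
thin_by_depth <- function(vs, retention, seed) {
  .assert(retention >= 0 && retention <= 1,
          "retention must be in [0, 1]")
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(vs$variants)) < retention
  structure(list(sample_id = vs$sample_id,
                 variants = vs$variants[keep, , drop = FALSE]),
            class = "variant_set")
}
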