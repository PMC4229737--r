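# Independent oracles and fixture builders used across the suite.

# Brute-force merge oracle: operates by per-bin relabeling on the label
# vector (the package implementation works on run intervals instead).
# Pass 1 relabels every internal sparse run shorter than the dense gap
# threshold; pass 2 relabels every dense run shorter than the dissolve
# threshold (a whole-chromosome dense run is exempt). Returns the block
# intervals implied by the final labels.
oracle_merge <- function(labels, chrom_len, bin_size, params = vb_params()) {
  run_bp <- function(from, to) {
    min(to * bin_size, chrom_len) - (from - 1) * bin_size
  }
  lab <- labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "sRB" && i > 1L && i < length(r$values) &&
        run_bp(starts[i], ends[i]) < params$dvb_gap_merge) {
      lab[starts[i]:ends[i]] <- "dRB"
    }
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "dRB" && run_bp(starts[i], ends[i]) <
          params$svb_gap_merge && r$lengths[i] < length(lab)) {
      lab[starts[i]:ends[i]] <- "sRB"
    }
  }
  r <- rle(lab)
  ends <- pmin(cumsum(r$lengths) * bin_size, chrom_len)
  starts <- c(0, ends[-length(ends)])
  data.frame(start = starts, end = ends,
             label = ifelse(r$values == "dRB", "dVB", "sVB"),
             stringsAsFactors = FALSE)
}

# wrap a label vector as the bin_labels object merge_blocks expects
as_bin_labels <- function(labels, chrom = "chr1", bin_size = 10000) {
  structure(list(bin_size = bin_size,
                 labels = stats::setNames(list(labels), chrom)),
            class = "bin_labels")
}

# single-row vb_instances fixture for the typing operations
inst_row <- function(vb_id, sample_id, pos = numeric(0),
                     alt = character(0), start = 0, end = 1e5,
                     chrom = "chr1", density = "dense") {
  out <- data.frame(vb_id = vb_id, sample_id = sample_id, chrom = chrom,
                    start = start, end = end, density = density,
                    n_snv = length(pos), stringsAsFactors = FALSE)
  out$snv <- I(list(data.frame(pos = pos, alt = alt,
                               stringsAsFactors = FALSE)))
  class(out) <- c("vb_instances", "data.frame")
  out
}

# hand-built vb_types assignment from a site x sample matrix of type ids
types_from_matrix <- function(m, samples = colnames(m),
                              vbs = rownames(m)) {
  out <- do.call(rbind, lapply(seq_along(vbs), function(i)
    data.frame(vb_id = vbs[i], sample_id = samples, type = m[i, ],
               k = length(unique(m[i, ])), stringsAsFactors = FALSE)))
  class(out) <- c("vb_types", "data.frame")
  out
}

# quick variant_set builder
vs_build <- function(sample_id, chrom, pos, ref = "A", alt = "T",
                     zygosity = "hom", layout = NULL) {
  n <- length(pos)
  variant_set(sample_id,
              data.frame(chrom = rep_len(chrom, n), pos = pos,
                         ref = rep_len(ref, n), alt = rep_len(alt, n),
                         zygosity = rep_len(zygosity, n),
                         stringsAsFactors = FALSE),
              layout)
}

# toy single-sample VCF writer for io tests
write_test_vcf <- function(path, records,
                           contigs = c(chr1 = 50000, chr2 = 30000),
                           sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
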