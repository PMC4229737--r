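# Internal helpers. All genomic intervals inside the package are 0-based
# half-open data frames with columns chrom/start/end; VCF positions are
# converted on read and BED is written natively.

.assert <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
}

.chrom_lengths <- function(layout) {
  stats::setNames(layout$length, layout$chrom)
}

# total overlap in bp between two 0-based half-open interval sets,
# computed per chromosome with IRanges
.overlap_bp <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  total <- 0
  for (ch in chroms) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(ai) == 0L || nrow(bi) == 0L) next
    ra <- IRanges::reduce(IRanges::IRanges(ai$start + 1, ai$end))
    rb <- IRanges::reduce(IRanges::IRanges(bi$start + 1, bi$end))
    total <- total + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  total
}

.interval_bp <- function(a) {
  if (nrow(a) == 0L) return(0)
  total <- 0
  for (ch in unique(a$chrom)) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    total <- total +
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ai$start + 1, ai$end))))
  }
  total
}

# paste0 treats zero-length args as ""; key builders must stay empty
.keyv <- function(...) {
  if (length(..1) == 0L) return(character(0))
  paste0(...)
}

# deterministic sub-seed derivation: keeps derived seeds well below 2^31
.sub_seed <- function(seed, salt, i = 0L) {
  (as.integer(seed) %% 100000L) * 10000L + (salt %% 100L) * 100L + (i %% 100L)
}
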