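#' Reference genome layout
#'
#' An ordered table of chromosome names and lengths defining the coordinate
#' frame every other object in the package refers to.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer lengths in bp, one per chromosome.
#' @return A data frame of class `genome_layout` with columns `chrom` and
#'   `length`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 3e6))
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  .assert(base::length(chrom) == base::length(length) && base::length(chrom) >= 1L,
          "chrom and length must be equal-length, non-empty vectors")
  .assert(!anyDuplicated(chrom), "chromosome names must be unique")
  .assert(all(is.finite(length)) && all(length >= 1),
          "chromosome lengths must be >= 1")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a genome layout from a chromosome-length file
#'
#' Accepts a 2-column name/length TSV or a FASTA index (`.fai`), of which
#' only the first two columns are used.
#'
#' @param path Path to the tab-separated file.
#' @return A `genome_layout`.
#' @export
read_genome_layout <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  .assert(ncol(tab) >= 2L, "layout file must have at least two columns")
  genome_layout(tab[[1]], tab[[2]])
}

#' @exportS3Method
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d chromosome(s), %.1f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}
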