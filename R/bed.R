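#' Write a block map or VB frame as BED
#'
#' Four-column BED, written 0-based half-open, which is also the package's
#' internal convention, so coordinates pass through unchanged. The name
#' field holds the block label (`dVB`/`sVB`) for a sample block map and the
#' VB id for a frame. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param x A `sample_block_map` or a `vb_frame` data frame.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_block_map <- function(x, path) {
  if (inherits(x, "sample_block_map")) {
    df <- x$blocks
    nm <- df$label
  } else if (inherits(x, "vb_frame")) {
    df <- x
    nm <- df$vb_id
  } else stop("x must be a sample_block_map or vb_frame", call. = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                     as.integer(df$end), nm), path)
  invisible(path)
}

#' Read a block map or VB frame from BED
#'
#' The file is pre-validated line by line (so malformed lines error with
#' their line number), then parsed with `rtracklayer`. Files whose name
#' field is entirely `dVB`/`sVB` are returned as a `sample_block_map`
#' (requiring `sample_id` and `layout`); names entirely `dense`/`sparse`
#' (a simulator truth track, which need not tile the genome) come back as
#' a labelled interval data frame; anything else is a `vb_frame`.
#'
#' @param path BED file path.
#' @param layout `genome_layout`, required to validate a sample block map.
#' @param sample_id Sample name to attach when reading a block map.
#' @return A `sample_block_map`, a labelled interval data frame, or a
#'   `vb_frame`.
#' @export
read_block_map <- function(path, layout = NULL, sample_id = "sample") {
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop("malformed BED line ", i, ": expected at least 4 fields",
           call. = FALSE)
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || e <= s)
      stop("malformed BED line ", i, ": need numeric start < end",
           call. = FALSE)
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  df <- data.frame(chrom = as.character(gr$seqnames),
                   start = as.numeric(gr$start) - 1,
                   end = as.numeric(gr$end),
                   name = gr$name, stringsAsFactors = FALSE)
  if (nrow(df) > 0L && all(df$name %in% c("dVB", "sVB"))) {
    .assert(!is.null(layout),
            "layout is required to read a sample block map")
    names(df)[names(df) == "name"] <- "label"
    sample_block_map(sample_id, df, layout)
  } else if (nrow(df) > 0L && all(df$name %in% c("dense", "sparse"))) {
    # truth-style interval track: labelled but not necessarily a tiling
    names(df)[names(df) == "name"] <- "label"
    df
  } else {
    names(df)[names(df) == "name"] <- "vb_id"
    df <- df[, c("vb_id", "chrom", "start", "end")]
    class(df) <- c("vb_frame", "data.frame")
    df
  }
}
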