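#' Construct a per-sample variant set
#'
#' Holds one sample's variant calls against the reference: SNVs and small
#' indels with zygosity. Records are sorted by (chromosome, position) in
#' layout order and there is at most one record per position.
#'
#' @param sample_id Sample name.
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `zygosity` (`"hom"`/`"het"`). Columns `kind` (`"SNV"`/`"indel"`)
#'   and `indel_length` are derived from the alleles if absent.
#' @param layout Optional `genome_layout`; if given, chromosome names are
#'   checked and positions validated against chromosome lengths, and rows
#'   are sorted in layout chromosome order.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sample_id, variants, layout = NULL) {
  .assert(is.character(sample_id) && length(sample_id) == 1L,
          "sample_id must be a single string")
  need <- c("chrom", "pos", "ref", "alt", "zygosity")
  .assert(all(need %in% names(variants)),
          "variants must have columns: ", paste(need, collapse = ", "))
  v <- variants
  v$chrom <- as.character(v$chrom)
  v$pos <- as.numeric(v$pos)
  v$ref <- as.character(v$ref)
  v$alt <- as.character(v$alt)
  v$zygosity <- as.character(v$zygosity)
  .assert(all(v$zygosity %in% c("hom", "het")),
          "zygosity must be 'hom' or 'het'")
  .assert(all(nchar(v$ref) > 0L & nchar(v$alt) > 0L), "alleles must be non-empty")
  .assert(all(v$pos >= 1), "positions must be >= 1")
  if (!("kind" %in% names(v)) || !("indel_length" %in% names(v))) {
    d <- abs(nchar(v$alt) - nchar(v$ref))
    v$kind <- ifelse(d > 0L, "indel", "SNV")
    v$indel_length <- d
  }
  if (!is.null(layout)) {
    bad <- !(v$chrom %in% layout$chrom)
    .assert(!any(bad), "unknown chromosome in variant record(s): ",
            paste(utils::head(paste0(v$chrom[bad], ":", v$pos[bad]), 3L),
                  collapse = ", "))
    lens <- .chrom_lengths(layout)
    over <- v$pos > lens[v$chrom]
    .assert(!any(over), "variant position beyond chromosome end: ",
            paste(utils::head(paste0(v$chrom[over], ":", v$pos[over]), 3L),
                  collapse = ", "))
    ord <- order(match(v$chrom, layout$chrom), v$pos)
  } else {
    ord <- order(v$chrom, v$pos)
  }
  v <- v[ord, c("chrom", "pos", "ref", "alt", "zygosity", "kind",
                "indel_length"), drop = FALSE]
  rownames(v) <- NULL
  .assert(!anyDuplicated(.keyv(v$chrom, ":", v$pos)),
          "at most one variant record per (chromosome, position) allowed")
  structure(list(sample_id = sample_id, variants = v),
            class = "variant_set")
}

#' @exportS3Method
print.variant_set <- function(x, ...) {
  v <- x$variants
  cat(sprintf("Variant set '%s': %d variants (%d SNV, %d indel; %d hom)\n",
              x$sample_id, nrow(v), sum(v$kind == "SNV"),
              sum(v$kind == "indel"), sum(v$zygosity == "hom")))
  invisible(x)
}

#' Read one sample's variants from a VCF file
#'
#' Parses a VCF 4.x file with `vcfR` and extracts the records of one named
#' sample: PASS/unfiltered records only, zygosity taken from the GT field,
#' reference-homozygous and fully missing genotypes dropped. For
#' multi-allelic genotypes the first called alternate allele is kept; a
#' same-position collision keeps the first record and is reported via
#' `message()`.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param sample_id Name of the sample column to read.
#' @param layout `genome_layout`; records on chromosomes absent from the
#'   layout are an error naming the offending record.
#' @return A `variant_set`.
#' @export
read_variants <- function(path, sample_id, layout) {
  .assert(file.exists(path), "cannot read VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  empty <- variant_set(sample_id,
                       data.frame(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character(),
                                  zygosity = character()), layout)
  if (is.null(n) || n == 0L) return(empty)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))                  # single-record files come back bare
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  .assert(sample_id %in% colnames(vcf@gt),
          "sample '", sample_id, "' not present in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, sample_id]

  filt <- fix[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".", "")
  rec <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt_field = fix[, "ALT"],
                    gt = gt, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(rec) == 0L) return(empty)

  parse_one <- function(alt_field, g) {
    if (is.na(g)) return(NULL)
    al <- strsplit(g, "[/|]")[[1]]
    al <- al[al != "."]
    if (length(al) == 0L) return(NULL)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai) || all(ai == 0L)) return(NULL)
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    called <- ai[ai > 0L][1L]
    if (called > length(alts)) return(NULL)
    zyg <- if (length(ai) >= 2L && length(unique(ai)) == 1L) "hom" else
      if (length(ai) == 1L) "hom" else "het"
    list(alt = alts[called], zygosity = zyg)
  }
  parsed <- Map(parse_one, rec$alt_field, rec$gt)
  ok <- !vapply(parsed, is.null, logical(1))
  rec <- rec[ok, , drop = FALSE]
  parsed <- parsed[ok]
  if (nrow(rec) == 0L) return(empty)
  out <- data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                    alt = vapply(parsed, `[[`, "", "alt"),
                    zygosity = vapply(parsed, `[[`, "", "zygosity"),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste0(out$chrom, ":", out$pos))
  if (any(dup)) {
    message(sum(dup), " same-position collision(s) in '", path,
            "'; first record kept at e.g. ",
            paste0(out$chrom[dup][1L], ":", out$pos[dup][1L]))
    out <- out[!dup, , drop = FALSE]
  }
  variant_set(sample_id, out, layout)
}

#' Write a variant set as a minimal single-sample VCF
#'
#' Emits a plain-text VCF 4.2 with contig lines from the layout and a GT
#' FORMAT field ("1/1" for homozygous, "0/1" for heterozygous). The output
#' round-trips through [read_variants()].
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @param layout `genome_layout` supplying the contig header lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path, layout) {
  v <- vs$variants
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                   as.integer(layout$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$sample_id), collapse = "\t"))
  gt <- ifelse(v$zygosity == "hom", "1/1", "0/1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  v$chrom, as.integer(v$pos), v$ref, v$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Retain homozygous SNVs and remove masked noise positions
#'
#' The density binning of the method runs on homozygous SNVs only; indels
#' and heterozygous calls are removed. An optional noise mask (e.g. the
#' variant calls of a resequenced reference individual, which can only be
#' base-calling artefacts) removes any variant at a masked (chromosome,
#' position), regardless of allele.
#'
#' @param vs A `variant_set`.
#' @param noise_mask A `variant_set` of mask positions, or `NULL`.
#' @return A `variant_set` containing a subset of `vs`.
#' @export
prepare_homozygous_snvs <- function(vs, noise_mask = NULL) {
  v <- vs$variants
  v <- v[v$zygosity == "hom" & v$kind == "SNV", , drop = FALSE]
  if (!is.null(noise_mask)) {
    mk <- .keyv(noise_mask$variants$chrom, ":", noise_mask$variants$pos)
    v <- v[!(.keyv(v$chrom, ":", v$pos) %in% mk), , drop = FALSE]
  }
  rownames(v) <- NULL
  structure(list(sample_id = vs$sample_id, variants = v),
            class = "variant_set")
}
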