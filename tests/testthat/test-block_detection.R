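test_that("bin counts follow the floor((p-1)/bin_size) convention", {
  lay <- genome_layout("chr1", 25000)
  vs <- vs_build("S", "chr1", c(1, 10000))
  expect_equal(compute_bin_profile(vs, lay, 10000)$counts$chr1, c(2, 0, 0))
  vs2 <- vs_build("S", "chr1", 10001)
  expect_equal(compute_bin_profile(vs2, lay, 10000)$counts$chr1, c(0, 1, 0))
  empty <- vs_build("S", character(0), numeric(0))
  prof <- compute_bin_profile(empty, lay, 10000)
  expect_equal(prof$counts$chr1, integer(3))
})

test_that("bin counts sum to the per-chromosome SNV count", {
  lay <- genome_layout(c("chr1", "chr2"), c(123456, 45000))
  set.seed(9)
  vs <- variant_set("S", data.frame(
    chrom = c(rep("chr1", 40), rep("chr2", 15)),
    pos = c(sample.int(123456, 40), sample.int(45000, 15)),
    ref = "A", alt = "T", zygosity = "hom", stringsAsFactors = FALSE), lay)
  prof <- compute_bin_profile(vs, lay, 10000)
  expect_equal(sum(prof$counts$chr1), 40)
  expect_equal(sum(prof$counts$chr2), 15)
  expect_equal(lengths(prof$counts), c(chr1 = 13L, chr2 = 5L))
})

test_that("bins classify as dRB at exactly the SNV threshold", {
  prof <- structure(list(bin_size = 10000,
                         counts = list(chr1 = c(3, 4, 0, 5, 2, 7))),
                    class = "bin_profile")
  lab <- classify_bins(prof, 4)
  expect_equal(lab$labels$chr1, c("sRB", "dRB", "sRB", "dRB", "sRB", "dRB"))
})

test_that("classification is monotone: adding SNVs never flips dRB to sRB", {
  set.seed(4)
  cnt <- rpois(50, 3)
  prof <- function(x) structure(list(bin_size = 1e4, counts = list(c1 = x)),
                                class = "bin_profile")
  a <- classify_bins(prof(cnt), 4)$labels$c1
  b <- classify_bins(prof(cnt + rpois(50, 1)), 4)$labels$c1
  expect_false(any(a == "dRB" & b == "sRB"))
})

test_that("dense runs separated by sub-threshold gaps merge into one dVB", {
  lay <- genome_layout("chr1", 200000)
  lab <- rep("sRB", 20)
  lab[c(1, 3)] <- "dRB"                       # bins [0,10k) and [20k,30k)
  map <- merge_blocks(as_bin_labels(lab), lay, sample_id = "S")
  expect_equal(map$blocks$start, c(0, 30000))
  expect_equal(map$blocks$end, c(30000, 200000))
  expect_equal(map$blocks$label, c("dVB", "sVB"))
})

test_that("dense runs beyond the gap threshold stay separate", {
  lay <- genome_layout("chr1", 300000)
  lab <- c(rep("dRB", 10), rep("sRB", 10), rep("dRB", 10))
  map <- merge_blocks(as_bin_labels(lab), lay, sample_id = "S")
  expect_equal(map$blocks$label, c("dVB", "sVB", "dVB"))
  expect_equal(map$blocks$start, c(0, 100000, 200000))
})

test_that("an isolated short dense bin dissolves into the sparse block", {
  lay <- genome_layout("chr1", 200000)
  lab <- rep("sRB", 20); lab[8] <- "dRB"
  map <- merge_blocks(as_bin_labels(lab), lay, sample_id = "S")
  expect_equal(map$blocks$label, "sVB")
  expect_equal(nrow(map$blocks), 1L)
})

test_that("an all-sparse chromosome is one sVB with no boundaries", {
  lay <- genome_layout("chr1", 200000)
  map <- merge_blocks(as_bin_labels(rep("sRB", 20)), lay, sample_id = "S")
  expect_equal(map$blocks, data.frame(chrom = "chr1", start = 0,
                                      end = 200000, label = "sVB"))
  expect_length(block_boundaries(map)$chr1, 0L)
})

test_that("a fully dense chromosome stays one dVB even when short", {
  lay <- genome_layout("chr1", 20000)
  map <- merge_blocks(as_bin_labels(rep("dRB", 2)), lay, sample_id = "S")
  expect_equal(map$blocks$label, "dVB")
})

test_that("merging matches the brute-force per-bin oracle on random instances", {
  set.seed(123)
  params <- vb_params()
  for (i in 1:200) {
    n <- sample(1:50, 1)
    clen <- n * 10000 - sample(c(0, 4000), 1)   # sometimes a partial last bin
    lab <- sample(c("sRB", "dRB"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
    lay <- genome_layout("chr1", clen)
    got <- merge_blocks(as_bin_labels(lab), lay, params, sample_id = "S")
    want <- oracle_merge(lab, clen, 10000, params)
    expect_equal(got$blocks$start, want$start, info = paste("case", i))
    expect_equal(got$blocks$end, want$end, info = paste("case", i))
    expect_equal(got$blocks$label, want$label, info = paste("case", i))
  }
})

test_that("merged maps tile the chromosome and satisfy minimum-length rules", {
  set.seed(77)
  params <- vb_params()
  for (i in 1:50) {
    n <- sample(5:50, 1)
    clen <- n * 10000
    lab <- sample(c("sRB", "dRB"), n, replace = TRUE)
    lay <- genome_layout("chr1", clen)
    b <- merge_blocks(as_bin_labels(lab), lay, params, sample_id = "S")$blocks
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], clen)
    if (nrow(b) > 1) {
      expect_equal(b$start[-1], b$end[-nrow(b)])
      expect_false(any(b$label[-1] == b$label[-nrow(b)]))
    }
    w <- b$end - b$start
    dv <- b$label == "dVB"
    whole <- b$start == 0 & b$end == clen
    expect_true(all(w[dv & !whole] >= params$svb_gap_merge))
    internal_sv <- !dv & b$start > 0 & b$end < clen
    expect_true(all(w[internal_sv] >= params$dvb_gap_merge))
  }
})

test_that("identical inputs give byte-identical BED output", {
  lay <- genome_layout("chr1", 300000)
  lab <- c(rep("dRB", 10), rep("sRB", 10), rep("dRB", 10))
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_block_map(merge_blocks(as_bin_labels(lab), lay, sample_id = "S"), p1)
  write_block_map(merge_blocks(as_bin_labels(lab), lay, sample_id = "S"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a single boundary induces sites + 1 VB intervals", {
  lay <- genome_layout("chr1", 200000)
  map <- sample_block_map("S", data.frame(
    chrom = "chr1", start = c(0, 30000), end = c(30000, 200000),
    label = c("dVB", "sVB")), lay)
  fr <- build_vb_frame(list(map), lay, 10000)
  expect_equal(fr$sites$chr1, 30000)
  expect_equal(nrow(fr$frame), 2L)
  expect_equal(fr$frame$start, c(0, 30000))
  expect_equal(fr$frame$vb_id, c("VB0001", "VB0002"))
})

test_that("nearby boundaries from different samples collapse to their median", {
  lay <- genome_layout("chr1", 500000)
  m1 <- sample_block_map("A", data.frame(
    chrom = "chr1", start = c(0, 100000), end = c(100000, 500000),
    label = c("dVB", "sVB")), lay)
  m2 <- sample_block_map("B", data.frame(
    chrom = "chr1", start = c(0, 105000), end = c(105000, 500000),
    label = c("dVB", "sVB")), lay)
  fr <- build_vb_frame(list(m1, m2), lay, 10000)
  expect_equal(fr$sites$chr1, 102500)
  expect_equal(nrow(fr$frame), 2L)
})

test_that("pooling identical maps reproduces a single sample's boundaries", {
  lay <- genome_layout("chr1", 300000)
  lab <- c(rep("dRB", 10), rep("sRB", 10), rep("dRB", 10))
  map <- merge_blocks(as_bin_labels(lab), lay, sample_id = "S")
  fr1 <- build_vb_frame(list(map), lay, 10000)
  frN <- build_vb_frame(list(map, map, map), lay, 10000)
  expect_equal(frN$sites, fr1$sites)
  expect_equal(frN$sites$chr1, block_boundaries(map)$chr1)
})

test_that("frame construction rejects inconsistent chromosome sets", {
  lay <- genome_layout("chr1", 200000)
  lay2 <- genome_layout(c("chr1", "chr2"), c(200000, 100000))
  map <- merge_blocks(as_bin_labels(rep("sRB", 20)), lay, sample_id = "S")
  expect_error(build_vb_frame(list(map), lay2, 10000), "chromosome set")
})

test_that("instances carry in-interval SNVs and the majority density label", {
  lay <- genome_layout("chr1", 200000)
  map <- sample_block_map("S", data.frame(
    chrom = "chr1", start = c(0, 60000), end = c(60000, 200000),
    label = c("dVB", "sVB")), lay)
  # frame with a VB straddling the sample boundary 60/40
  frame <- data.frame(vb_id = c("VB0001", "VB0002"), chrom = "chr1",
                      start = c(0, 100000), end = c(100000, 200000),
                      stringsAsFactors = FALSE)
  class(frame) <- c("vb_frame", "data.frame")
  snvs <- vs_build("S", "chr1", c(50, 59999, 150000))
  inst <- annotate_instances(frame, map, snvs)
  expect_equal(inst$density, c("dense", "sparse"))   # 60% dense, 0% dense
  expect_equal(inst$snv[[1]]$pos, c(50, 59999))
  expect_equal(inst$snv[[2]]$pos, 150000)
  expect_equal(inst$n_snv, c(2L, 1L))

  # zero-SNV sample: every instance sparse on an all-sparse map
  map0 <- sample_block_map("T", data.frame(
    chrom = "chr1", start = 0, end = 200000, label = "sVB"), lay)
  inst0 <- annotate_instances(frame, map0, vs_build("T", character(0),
                                                    numeric(0)))
  expect_equal(inst0$density, c("sparse", "sparse"))
  expect_equal(inst0$n_snv, c(0L, 0L))
})
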