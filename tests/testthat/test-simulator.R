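test_that("an all-sparse founder with zero sparse density carries no SNVs", {
  lay <- genome_layout("chr1", 1e6)
  mod <- segment_model(lambda_sparse = 0, dense_fraction = 0,
                       seg_len_range = c(2e5, 5e5), indel_rate = 0)
  sim <- simulate_founders(lay, mod, n_founders = 1, seed = 3)
  expect_equal(nrow(sim$variant_sets$F1$variants), 0L)
  expect_true(all(sim$truth$F1$label == "sparse"))
})

test_that("dense-segment SNV counts follow the Poisson rate", {
  lay <- genome_layout("chr1", 1e6)
  mod <- segment_model(dense_fraction = 1, n_haplotypes = 1,
                       seg_len_range = c(1e6, 1e6), indel_rate = 0)
  lambda <- mod$lambda_dense * 1000            # 3,800 per Mb
  for (s in 1:10) {
    sim <- simulate_founders(lay, mod, n_founders = 1, seed = s)
    n <- sum(sim$variant_sets$F1$variants$kind == "SNV")
    expect_true(abs(n - lambda) < 4 * sqrt(lambda),
                info = paste("seed", s))
  }
})

test_that("founders drawing the same ancestral haplotype are identical there", {
  lay <- genome_layout("chr1", 2e6)
  mod <- segment_model(dense_fraction = 1, n_haplotypes = 1,
                       seg_len_range = c(5e5, 1e6))
  sim <- simulate_founders(lay, mod, n_founders = 2, seed = 17)
  expect_equal(sim$truth$F1$hap_id, sim$truth$F2$hap_id)
  expect_equal(sim$variant_sets$F1$variants, sim$variant_sets$F2$variants)
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  lay <- genome_layout("chr1", 1e6)
  a <- simulate_founders(lay, segment_model(), 2, seed = 5)
  b <- simulate_founders(lay, segment_model(), 2, seed = 5)
  c <- simulate_founders(lay, segment_model(), 2, seed = 6)
  expect_identical(a$variant_sets$F1$variants, b$variant_sets$F1$variants)
  expect_false(identical(a$variant_sets$F1$variants,
                         c$variant_sets$F1$variants))
})

test_that("crosses honour crossover counts and degenerate cases", {
  lay <- genome_layout("chr1", 2e6)
  sim <- simulate_founders(lay, segment_model(seg_len_range = c(3e5, 6e5)),
                           2, seed = 21)
  cr0 <- simulate_cross(sim$variant_sets$F1, sim$variant_sets$F2,
                        sim$truth$F1, sim$truth$F2, lay, n_crossovers = 0,
                        seed = 1, sample_id = "D")
  expect_equal(nrow(cr0$truth$crossovers), 0L)
  expect_true(identical(cr0$variant_set$variants,
                        sim$variant_sets$F1$variants) ||
                identical(cr0$variant_set$variants,
                          sim$variant_sets$F2$variants))
  cr <- simulate_cross(sim$variant_sets$F1, sim$variant_sets$F2,
                       sim$truth$F1, sim$truth$F2, lay, n_crossovers = 5,
                       seed = 2, sample_id = "D")
  expect_equal(nrow(cr$truth$crossovers), 5L)
  expect_error(simulate_cross(sim$variant_sets$F1, sim$variant_sets$F2,
                              sim$truth$F1, sim$truth$F2, lay,
                              n_crossovers = -1, seed = 1), ">= 0")
})

test_that("crossovers concentrate in identical regions at the sparse bias", {
  lay <- genome_layout("chr1", 2e6)
  # constructed truths: first half identical, second half differing
  ta <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                   label = c("sparse", "dense"),
                   hap_id = c("s1/ref", "s2/hap1"), stringsAsFactors = FALSE)
  tb <- ta; tb$hap_id <- c("s1/ref", "s2/hap2")
  ev <- vs_build("E", character(0), numeric(0), layout = lay)
  cr <- simulate_cross(ev, ev, ta, tb, lay, n_crossovers = 1000,
                       sparse_bias = 6.6, seed = 9, sample_id = "D")
  frac <- mean(cr$truth$crossovers$pos < 1e6)
  expect_true(abs(frac - 6.6 / 7.6) < 0.05)    # multinomial expectation
})

test_that("RIL genotypes and phenotypes are read off the true origins", {
  lay <- genome_layout("chr1", 1e6)
  mk <- data.frame(marker_id = "M1", chrom = "chr1", pos = 500001,
                   stringsAsFactors = FALSE)
  causal <- list(chrom = "chr1", start = 400000, end = 600000)
  # no crossovers: phenotype equals the parental carrier status
  sim <- simulate_ril_population(lay, mk, causal, n_rils = 30,
                                 generations = 2, xo_per_meiosis = 0,
                                 carrier = "A", seed = 13)
  expect_equal(sim$phenotype, as.integer(sim$genotypes[, "M1"] == 0))
  # full penetrance: the causal-VB marker cosegregates perfectly
  res <- marker_trait_association(sim$genotypes, sim$phenotype)
  expect_equal(abs(res$r[1]), 1)
  expect_error(simulate_ril_population(lay, mk,
                                       list(chrom = "chrX", start = 0,
                                            end = 1), 5, seed = 1),
               "not in layout")
})

test_that("RIL recombination fractions match the process closed form", {
  # crossovers form a uniform Poisson process per meiosis, so the expected
  # recombination fraction between two points at distance d after g
  # meioses is the Haldane form (1 - exp(-2 g lambda d)) / 2
  lay <- genome_layout("chr1", 1e7)
  mk <- data.frame(marker_id = c("M1", "M2"), chrom = "chr1",
                   pos = c(2e6, 8e6), stringsAsFactors = FALSE)
  causal <- list(chrom = "chr1", start = 0, end = 1e6)
  g <- 4
  sim <- simulate_ril_population(lay, mk, causal, n_rils = 1000,
                                 generations = g, xo_per_meiosis = 1,
                                 seed = 41)
  robs <- mean(sim$genotypes[, "M1"] != sim$genotypes[, "M2"])
  d <- 6e6 / 1e7                    # fraction of the chromosome
  rexp <- (1 - exp(-2 * g * d)) / 2
  expect_true(abs(robs - rexp) < 4 * sqrt(rexp * (1 - rexp) / 1000))
})

test_that("depth thinning keeps a Bernoulli fraction of variants", {
  lay <- genome_layout("chr1", 1e6)
  vs <- vs_build("S", "chr1", seq(1, 999901, by = 100), layout = lay)
  n <- nrow(vs$variants)
  expect_identical(thin_by_depth(vs, 1.0, seed = 1)$variants, vs$variants)
  expect_equal(nrow(thin_by_depth(vs, 0.0, seed = 1)$variants), 0L)
  kept <- nrow(thin_by_depth(vs, 0.79, seed = 7)$variants)
  expect_true(abs(kept - 0.79 * n) < 4 * sqrt(n * 0.79 * 0.21))
  # thinned output is a subset
  th <- thin_by_depth(vs, 0.5, seed = 3)
  expect_true(all(th$variants$pos %in% vs$variants$pos))
  # default depth model carries the published retention probabilities
  dm <- depth_model()
  expect_equal(dm$retention[dm$depth == 6], 0.79)
  expect_equal(dm$retention[dm$depth == 5], 0.73)
  expect_error(depth_model(c(5, 6), c(0.9, 0.8)), "non-decreasing")
})

test_that("detection on simulated founders recovers true dense segments", {
  lay <- genome_layout(paste0("chr", 1:4), rep(5e6, 4))
  sim <- simulate_founders(lay, segment_model(), n_founders = 1, seed = 29)
  map <- detect_blocks(sim$variant_sets$F1, lay)
  truth <- sim$truth$F1
  m <- interval_metrics(map, truth)
  expect_gt(m$sensitivity, 0.95)
  expect_gt(m$precision, 0.95)
  # every detected boundary lies within one bin of a true label transition
  tr_bounds <- unlist(lapply(split(truth, truth$chrom), function(t) {
    t <- t[order(t$start), ]
    t$start[-1][t$label[-1] != t$label[-nrow(t)]]
  }))
  det <- unlist(block_boundaries(map))
  expect_true(all(vapply(det, function(b)
    min(abs(tr_bounds - b)) <= 10000, logical(1))))
})

test_that("cross origin truth matches typing away from crossover blocks", {
  lay <- genome_layout(paste0("chr", 1:4), rep(5e6, 4))
  sim <- simulate_founders(lay, segment_model(), 2, seed = 55)
  cr <- simulate_cross(sim$variant_sets$F1, sim$variant_sets$F2,
                       sim$truth$F1, sim$truth$F2, lay, n_crossovers = 6,
                       seed = 56, sample_id = "D")
  sets <- lapply(c(sim$variant_sets, list(D = cr$variant_set)),
                 prepare_homozygous_snvs)
  maps <- lapply(sets, detect_blocks, layout = lay)
  fr <- build_vb_frame(maps, lay, 10000)
  inst <- do.call(rbind, lapply(names(sets), function(s)
    annotate_instances(fr$frame, maps[[s]], sets[[s]])))
  ty <- assign_types(inst)
  tr <- parental_origin(ty, "D", "F1", "F2")
  xo <- cr$truth$crossovers
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(fr$frame))) {
    f <- fr$frame[i, ]
    near_xo <- any(xo$chrom == f$chrom & xo$pos >= f$start - 10000 &
                     xo$pos <= f$end + 10000)
    if (near_xo) next
    org <- tr$origin[tr$vb_id == f$vb_id]
    true_org <- cr$truth$origins
    hit <- true_org$chrom == f$chrom & true_org$start <= f$start &
      true_org$end >= f$end
    if (!any(hit)) next
    expected <- paste0("parent", ifelse(true_org$origin[hit][1] == "A",
                                        "A", "B"))
    tot <- tot + 1L
    if (org == expected || org == "both") ok <- ok + 1L
  }
  expect_gt(tot, 5L)
  expect_equal(ok, tot)   # 100% of crossover-free VBs trace to the true parent
})
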