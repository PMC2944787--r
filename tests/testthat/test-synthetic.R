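test_that("background genome realizes its composition targets", {
  g <- gen_background_genome(1e6, seed = 70)
  st <- cpg_stats(g[[1]])
  expect_gt(st$oe, 0.18); expect_lt(st$oe, 0.24)
  gcf <- (st$n_c + st$n_g) / st$length
  expect_equal(gcf, 0.40, tolerance = 0.01)

  # unsuppressed independence limit
  g2 <- gen_background_genome(2e5, gc = 0.5, cpg_oe = 1, seed = 71)
  expect_equal(cpg_stats(g2[[1]])$oe, 1, tolerance = 0.05)

  expect_identical(gen_background_genome(5e4, seed = 9),
                   gen_background_genome(5e4, seed = 9))
  expect_error(gen_background_genome(5e4, gc = 0.5, cpg_oe = 5),
               "infeasible")
})

test_that("planted islands honour class, spacing and composition targets", {
  sim <- small_sim()
  truth <- sim$truth
  expect_length(truth, 16)
  expect_equal(as.character(classify_cgi(truth, sim$genes)),
               as.character(truth$class))
  # pairwise separation respects min_gap
  d <- GenomicRanges::distance(truth[-length(truth)], truth[-1])
  expect_true(all(d >= sim$scenario$min_gap))
  # realized per-island o/e close to its target (1 kb sampling noise)
  ann <- cgi_cpg_annotate(truth, sim$genome)
  expect_true(all(abs(ann$oe - ann$target_oe) < 0.15))

  pl0 <- plant_islands(gen_background_genome(5e4, seed = 72),
                       gen_gene_models(5e4, n = 2, gap = 2000, seed = 73),
                       n = 0)
  expect_length(pl0$truth, 0)
})

test_that("methylation assignment respects class rates and the germline", {
  # synthetic truth: classes only, no genome needed
  n <- 3000
  truth <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, by = 10, length.out = n),
                                                   width = 5))
  S4Vectors::mcols(truth)$class <-
    factor(rep(c("ATSS", "Intragenic", "Intergenic"), length.out = n),
           levels = c("ATSS", "Intragenic", "Intergenic"))
  tr <- assign_methylation(truth, c("sperm", "blood"), seed = 74)
  expect_false(any(tr$meth_sperm))
  rates <- tapply(tr$meth_blood, tr$class, mean)
  for (cl in names(rates)) {
    p <- c(ATSS = 0.03, Intragenic = 0.24, Intergenic = 0.14)[[cl]]
    se <- sqrt(p * (1 - p) / (n / 3))
    expect_lt(abs(rates[[cl]] - p), 3 * se + 1e-9)
  }
  none <- assign_methylation(truth, c("sperm", "blood"),
                             rates = c(ATSS = 0, Intragenic = 0,
                                       Intergenic = 0), seed = 75)
  expect_false(any(none$meth_blood))
  all_m <- assign_methylation(truth, c("sperm", "blood"),
                              rates = c(ATSS = 1, Intragenic = 1,
                                        Intergenic = 1), seed = 76)
  expect_true(all(all_m$meth_blood))
  expect_false(any(all_m$active_blood))   # methylated CGIs are inactive
})

test_that("assay tracks reflect the retention models", {
  sim <- small_sim()
  truth <- sim$truth
  # zero signal and zero background give an all-zero track
  z <- simulate_track(sim$genome, truth,
                      assay_params("CAP", mean_depth = 0,
                                   background_depth = 0), "sperm",
                      seed = 77)
  expect_equal(total_depth(z), 0)

  # MAP: unmethylated islands sit at background, methylated ones high
  map_b <- sim$tracks$MAP$blood
  meth <- truth[truth$meth_blood]
  unmeth <- truth[!truth$meth_blood]
  mean_over <- function(tr, gr) {
    if (length(gr) == 0) return(NA_real_)
    v <- IRanges::Views(tr$depth$chr1,
                        GenomicRanges::start(gr), GenomicRanges::end(gr))
    mean(IRanges::viewMeans(v))
  }
  expect_lt(mean_over(map_b, unmeth), 1)
  if (length(meth) > 0) {
    expect_gt(mean_over(map_b, meth), 3)
    # H3K4me3 responds to density only at unmethylated islands
    k4 <- simulate_track(sim$genome, truth, assay_params("H3K4me3"),
                         "blood", seed = 78)
    expect_gt(mean_over(k4, unmeth), mean_over(k4, meth) + 0.5)
  }

  # RNAPII marks active islands only
  pol <- simulate_track(sim$genome, truth, assay_params("RNAPII"),
                        "blood", seed = 79)
  act <- truth[truth$active_blood]
  inact <- truth[!truth$active_blood]
  expect_gt(mean_over(pol, act), 3)
  expect_lt(mean_over(pol, inact), 1)
})

test_that("coupled stringency pair is pointwise nested", {
  sim <- small_sim()
  pair <- simulate_cap_stringency_pair(sim$genome, sim$truth, "sperm",
                                       seed = 80)
  dh <- track_depth(pair$high, "chr1", "numeric")
  dl <- track_depth(pair$low, "chr1", "numeric")
  expect_true(all(dl >= dh))
  expect_gt(sum(dl), sum(dh))
  expect_error(
    simulate_cap_stringency_pair(
      sim$genome, sim$truth, "sperm",
      params_high = assay_params("CAP", cap_stringency = "low"),
      params_low = assay_params("CAP", cap_stringency = "high")),
    "midpoint")
})

test_that("fixture bundles are complete, readable and reproducible", {
  sc <- scenario_default(genome_length = 6e4, n_genes = 4, n_islands = 5,
                         gene_gap = 3000, gene_length = c(3000, 6000),
                         class_mix = c(ATSS = 0.4, Intragenic = 0.3,
                                       Intergenic = 0.3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(d1, sc, seed = 81, force = TRUE)
  m2 <- write_fixture_bundle(d2, sc, seed = 81, force = TRUE)
  expect_setequal(m1$file, m2$file)
  expect_identical(m1$md5[order(m1$file)], m2$md5[order(m2$file)])

  sim <- simulate_scenario(sc, seed = 81)
  g <- read_fasta(file.path(d1, "genome.fa"))
  expect_identical(g, sim$genome)
  genes <- read_gtf_genes(file.path(d1, "genes.gtf"))
  expect_equal(GenomicRanges::start(genes), GenomicRanges::start(sim$genes))
  w <- read_wig(file.path(d1, "CAP_sperm.wig"),
                seqlengths = c(chr1 = 6e4))
  expect_equal(track_depth(w, "chr1", "numeric"),
               track_depth(sim$tracks$CAP$sperm, "chr1", "numeric"))
  truth_tab <- read.table(file.path(d1, "truth.tsv"), header = TRUE,
                          sep = "\t")
  expect_equal(nrow(truth_tab), 5)
  expect_error(write_fixture_bundle(d1, sc, seed = 81), "not empty")
})
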