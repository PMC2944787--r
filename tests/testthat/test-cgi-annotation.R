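g_iv <- function(s, e, chrom = "chr1", strand = "*", ...)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), strand = strand, ...)

test_that("positional classification follows the TSS/body/neither rule", {
  genes <- g_iv(1501, 5000, strand = "+", gene_id = "g1")
  expect_equal(as.character(classify_cgi(g_iv(901, 1900), genes)), "ATSS")
  expect_equal(as.character(classify_cgi(g_iv(3001, 3800), genes)),
               "Intragenic")
  expect_equal(as.character(classify_cgi(g_iv(10, 500, chrom = "chr9"),
                                         genes)), "Intergenic")
  # minus-strand TSS sits at the interval end
  genes_m <- g_iv(1501, 5000, strand = "-", gene_id = "g1")
  expect_equal(as.character(classify_cgi(g_iv(4950, 5600), genes_m)), "ATSS")
  expect_equal(as.character(classify_cgi(g_iv(1450, 1900), genes_m)),
               "Intragenic")
  # flank closes a 100 bp gap to the TSS but not a 101 bp one
  expect_equal(as.character(classify_cgi(g_iv(1101, 1401), genes)), "ATSS")
  expect_equal(as.character(classify_cgi(g_iv(1100, 1400), genes)),
               "Intergenic")

  expect_error(classify_cgi(g_iv(1, 10), g_iv(1, 100, gene_id = "u")),
               "strand")
})

test_that("classification partitions any CGI set and ignores input order", {
  withr::local_seed(40)
  genes <- gen_gene_models(2e5, n = 8, gap = 2000, seed = 41)
  cgis <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sort(sample.int(195000, 60)), width = 1000))
  cl <- classify_cgi(cgis, genes)
  expect_equal(sum(table(cl)), length(cgis))
  perm <- sample(seq_along(cgis))
  expect_equal(as.character(classify_cgi(cgis[perm], genes)),
               as.character(cl)[perm])
  expect_equal(as.character(classify_cgi(cgis, genes[sample(1:8)])),
               as.character(cl))
  # growing the flank only ever promotes toward ATSS
  for (f in c(0, 100, 500, 2000)) {
    a1 <- classify_cgi(cgis, genes, flank = f) == "ATSS"
    a2 <- classify_cgi(cgis, genes, flank = f + 500) == "ATSS"
    expect_true(all(a2[a1]))
  }
})

test_that("feature intersection uses extended intervals, not abutting ones", {
  cgi <- g_iv(1000, 1999)
  expect_true(intersect_features(cgi, g_iv(500, 3000)))
  expect_false(intersect_features(cgi, GenomicRanges::GRanges()))
  # extended CGI covers 900..2099; feature starting at 2100 abuts and misses
  expect_false(intersect_features(cgi, g_iv(2100, 2500)))
  expect_true(intersect_features(cgi, g_iv(2099, 2500)))
})

test_that("overlap table reports per-class percentages with denominators", {
  cgis <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, by = 2000, length.out = 10),
                             width = 1000))
  S4Vectors::mcols(cgis)$class <-
    factor(rep(c("ATSS", "Intragenic", "Intergenic"), c(5, 5, 0)),
           levels = c("ATSS", "Intragenic", "Intergenic"))
  S4Vectors::mcols(cgis)$k4 <- rep(c(TRUE, FALSE), c(4, 6))
  S4Vectors::mcols(cgis)$pol2 <- rep(c(TRUE, FALSE), 5)
  tab <- overlap_table(cgis, c("k4", "pol2"))
  expect_equal(tab$pct[tab$class == "ATSS" & tab$flag == "k4"], 80)
  expect_true(all(is.na(tab$pct[tab$class == "Intergenic"])))
  for (cl in c("ATSS", "Intragenic")) {
    sub <- tab[tab$class == cl, ]
    expect_gte(sub$pct[sub$flag == "Any"],
               max(sub$pct[sub$flag != "Any"]))
  }
  S4Vectors::mcols(cgis)$k4 <- TRUE
  expect_equal(overlap_table(cgis, "k4")$pct[1:2], c(100, 100))
})

test_that("proximity fraction uses an inclusive distance bound", {
  cgis <- g_iv(1000, 1999)
  inside <- g_iv(1500, 1510)
  at_100 <- g_iv(2100, 2150)    # gap of exactly 100 intervening bases
  at_101 <- g_iv(2101, 2150)
  far <- g_iv(9000, 9050)
  q <- c(inside, at_100, at_101, far)
  expect_equal(proximity_fraction(q, cgis, max_dist = 100), 0.5)
  expect_equal(proximity_fraction(far, cgis, max_dist = 100), 0)
  expect_error(proximity_fraction(q, GenomicRanges::GRanges()), "empty")
})

test_that("reciprocal-overlap matching enforces the fraction on both sides", {
  truth <- g_iv(1001, 2000)
  exact <- g_iv(1001, 2000)
  half <- g_iv(1501, 2000)      # covers 50% of truth, 100% of itself
  sliver <- g_iv(1901, 2000)
  expect_equal(nrow(reciprocal_overlap_match(exact, truth)), 1)
  expect_equal(nrow(reciprocal_overlap_match(half, truth)), 1)
  expect_equal(nrow(reciprocal_overlap_match(sliver, truth)), 0)
  big <- g_iv(1, 4000)          # truth covers only 25% of it
  expect_equal(nrow(reciprocal_overlap_match(big, truth)), 0)
})
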