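iv <- function(s, e, chrom = "chr1")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))

test_that("window means over an interval", {
  p <- dm_params()
  t <- depth_track(list(chr1 = rep(2.5, 1000)))
  expect_equal(window_means(t, iv(101, 400), p), rep(2.5, 11))
  expect_length(window_means(t, iv(1, 300), p), (300 - 100) %/% 20 + 1)
  expect_length(window_means(t, iv(1, 99), p), 0)

  t2 <- depth_track(list(chr1 = c(rep(10, 50), numeric(100))))
  expect_equal(window_means(t2, iv(1, 100), p), 5)
})

test_that("dm_score reproduces the sliding-window rule on hand cases", {
  p <- dm_params()
  same <- rep(1.0, 11)
  expect_equal(dm_score(same, same, p)$score, 0)

  # both window totals below the 4-read floor: every ratio forced to 1
  low <- dm_score(rep(0.03, 11), rep(0.02, 11), p)
  expect_equal(low$score, 0)
  expect_equal(low$log2_ratio, rep(0, 11))

  # 11 windows at ref 1.0 and test 5.0 reads/base:
  # totals 100 vs 500, ratio (500+1)/(100+1) = 4.9604, log2 = 2.3125 > 2
  up <- dm_score(rep(1, 11), rep(5, 11), p)
  expect_equal(up$score, 1)
  expect_equal(up$log2_ratio, rep(log2(501 / 101), 11))
  expect_equal(dm_score(rep(5, 11), rep(1, 11), p)$score, -1)

  # 9 exceedances inside a 10-frame suffice; 8 do not
  base <- rep(1, 12)
  hot9 <- c(rep(5, 9), 1, 1, 1)
  expect_equal(dm_score(base, hot9, p)$score, 1)
  hot8 <- c(rep(5, 8), rep(1, 4))
  expect_equal(dm_score(base, hot8, p)$score, 0)
  # 9 exceedances split across the ends: no single 10-frame holds 9
  scattered <- base; scattered[c(1:5, 9:12)] <- 5
  expect_equal(dm_score(base, scattered, p)$score, 0)
})

test_that("short CGIs are non-evaluable unless the proportional rule is on", {
  p <- dm_params()
  short <- dm_score(rep(1, 5), rep(50, 5), p)
  expect_equal(short$score, 0)
  expect_false(short$evaluable)
  pp <- dm_params(proportional = TRUE)
  prop <- dm_score(rep(1, 5), rep(50, 5), pp)
  expect_equal(prop$score, 1)
  expect_error(dm_score(rep(1, 5), rep(1, 6), p), "mismatch")
})

test_that("dm_score is antisymmetric and scale-consistent", {
  withr::local_seed(50)
  p <- dm_params()
  for (i in 1:30) {
    a <- rpois(15, sample(c(0.2, 1, 5), 1)) + runif(15)
    b <- rpois(15, sample(c(0.2, 1, 5), 1)) + runif(15)
    sa <- dm_score(a, b, p)$score
    sb <- dm_score(b, a, p)$score
    if (sa != 0 || sb != 0) expect_equal(sa, -sb)
    # common rescaling far above the floor leaves the call unchanged
    if (all(a * p$window >= p$read_floor) &&
        all(b * p$window >= p$read_floor))
      expect_equal(dm_score(a * 8, b * 8, p)$score, sa)
  }
})

test_that("dm_matrix scores each CGI per sample like dm_score", {
  ref <- depth_track(list(chr1 = rep(1, 2000)))
  hot <- depth_track(list(chr1 = rep(5, 2000)))
  cold <- depth_track(list(chr1 = numeric(2000)))
  cgis <- iv(c(101, 1101), c(500, 1500))
  S4Vectors::mcols(cgis)$cgi_id <- c("a", "b")
  m <- dm_matrix(cgis, ref, list(up = hot, down = cold))
  expect_equal(m["a", "up"], 1L)
  expect_equal(m["b", "down"], -1L)   # ref totals 100 >= floor, test 0
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(attr(m, "evaluable")))
})

test_that("tumour consensus partitions methylation calls", {
  ids <- paste0("cgi", 1:6)
  tum <- paste0("T", 1:5); nor <- paste0("C", 1:5)
  m <- matrix(0L, 6, 10, dimnames = list(ids, c(tum, nor)))
  m["cgi1", tum[1:3]] <- 1L                      # 3/5 tumours, 0 normals
  m["cgi2", c(tum, nor[1:2])] <- 1L              # 5/5 tumours, 2 normals
  m["cgi3", c(tum, nor)] <- 1L                   # everywhere
  m["cgi4", nor[1:4]] <- 1L                      # normals only
  m["cgi5", tum[1:2]] <- 1L                      # below min_tumour
  cons <- consensus_tumour_calls(m, tum, nor)
  expect_equal(cons$tumour_specific, "cgi1")
  expect_false("cgi2" %in% cons$tumour_specific)
  expect_true("cgi3" %in% cons$shared)
  expect_equal(cons$normal_only, "cgi4")
  expect_length(intersect(cons$tumour_specific, cons$shared), 0)
  all0 <- consensus_tumour_calls(matrix(0L, 2, 10,
                                        dimnames = list(ids[1:2],
                                                        c(tum, nor))),
                                 tum, nor)
  expect_equal(lengths(all0), c(tumour_specific = 0L, normal_only = 0L,
                                shared = 0L))
  expect_error(consensus_tumour_calls(m, c(tum, "T9"), nor), "T9")
})

test_that("conservation percentages per class", {
  pairs <- data.frame(a = paste0("h", 1:10), b = paste0("m", 1:10))
  calls_a <- setNames(rep(1L, 10), pairs$a)
  calls_b <- setNames(c(rep(1L, 5), rep(0L, 5)), pairs$b)
  classes <- setNames(rep(c("ATSS", "Intragenic"), each = 5), pairs$a)
  tab <- conservation_table(pairs, calls_a, calls_b, classes)
  expect_equal(tab$pct[tab$class == "ATSS"], 100)
  expect_equal(tab$pct[tab$class == "Intragenic"], 0)

  calls_b2 <- setNames(rep(c(1L, 0L), 5), pairs$b)
  tab2 <- conservation_table(pairs, calls_a, calls_b2,
                             setNames(rep("ATSS", 10), pairs$a))
  expect_equal(tab2$pct, 50)
  # intergenic excluded by default
  tab3 <- conservation_table(pairs, calls_a, calls_b,
                             setNames(rep("Intergenic", 10), pairs$a))
  expect_equal(nrow(tab3), 0)
  expect_warning(conservation_table(pairs[0, ], calls_a, calls_b, classes),
                 "empty")
  expect_error(conservation_table(data.frame(a = "zz", b = "m1"),
                                  calls_a, calls_b, classes), "zz")
})
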