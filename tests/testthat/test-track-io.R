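test_that("fixedStep WIG records map onto per-base depth", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("track type=wiggle_0",
               "fixedStep chrom=chr1 start=1 step=1",
               "5", "5", "5"), f)
  t <- read_wig(f, seqlengths = c(chr1 = 10))
  expect_equal(track_depth(t, "chr1", "numeric"),
               c(5, 5, 5, rep(0, 7)))
})

test_that("variableStep span expands to covered bases", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr2 span=10", "11 2"), f)
  t <- read_wig(f)
  expect_equal(track_depth(t, "chr2", "numeric"),
               c(rep(0, 10), rep(2, 10)))
})

test_that("degenerate and malformed WIG inputs are handled", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines("track type=wiggle_0", f)
  t <- read_wig(f, seqlengths = c(chr1 = 5))
  expect_equal(track_depth(t, "chr1", "numeric"), rep(0, 5))

  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "5", "oops"), f)
  expect_error(read_wig(f), "line 3")

  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "-2"), f)
  expect_error(read_wig(f), "negative")

  writeLines(c("fixedStep chrom=chr1 start=8 step=1", "1", "1"), f)
  expect_error(read_wig(f, seqlengths = c(chr1 = 8)), "bounds")
})

test_that("WIG round-trip is exact for integer and fractional depth", {
  withr::local_seed(11)
  f <- withr::local_tempfile(fileext = ".wig")
  t <- depth_track(list(chr1 = rpois(1000, 1.5), chr2 = rpois(500, 0.2)))
  write_wig(t, f)
  t2 <- read_wig(f, seqlengths = track_seqlengths(t))
  expect_identical(lapply(t$depth, as.numeric), lapply(t2$depth, as.numeric))

  # post-normalization fractional values round-trip bit-exactly too
  ts <- track_scale(t, 1 / 3)
  write_wig(ts, f)
  ts2 <- read_wig(f, seqlengths = track_seqlengths(ts))
  expect_identical(lapply(ts$depth, as.numeric),
                   lapply(ts2$depth, as.numeric))

  # all-zero track round-trips through an (empty-bodied) file
  z <- depth_track(list(chr1 = numeric(20)))
  write_wig(z, f)
  expect_equal(track_depth(read_wig(f, seqlengths = c(chr1 = 20)),
                           "chr1", "numeric"), numeric(20))
})

test_that("BED round-trips and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(101, 151, 11), c(200, 250, 60)),
    strand = c("+", "-", "+"),
    name = c("cgi1", "cgi2", "cgi3"), score = c(0, 0, 0))
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$name, gr$name)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))

  # BED is 0-based half-open on disk
  writeLines("chr1\t100\t200\tcgi1\t0\t+", f)
  one <- read_bed(f)
  expect_equal(GenomicRanges::start(one), 101)
  expect_equal(GenomicRanges::end(one), 200)

  # overlapping records are preserved, not merged
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), f)
  expect_length(read_bed(f), 2)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "line 1")

  writeLines(paste(c("chr1", 0, 1000, "x", 0, "+", 0, 1000, "0",
                     2, "100,100", "0,900"), collapse = "\t"), f)
  expect_warning(b12 <- read_bed(f), "BED6")
  expect_equal(GenomicRanges::width(b12), 1000)
})

test_that("FASTA reading normalizes case and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt", ">chr2", "NNAA"), f)
  g <- read_fasta(f)
  expect_identical(g, c(chr1 = "ACGT", chr2 = "NNAA"))

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">chr1", "ACRT"), f)
  expect_error(read_fasta(f))

  # round trip
  write_fasta(c(chrA = "ACGTN"), f)
  expect_identical(read_fasta(f), c(chrA = "ACGTN"))
})

test_that("GTF gene models round-trip with gene_id and strand", {
  f <- withr::local_tempfile(fileext = ".gtf")
  genes <- gen_gene_models(1e5, n = 5, seed = 3)
  write_gtf_genes(genes, f)
  back <- read_gtf_genes(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(genes)))
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(GenomicRanges::start(gene_tss(back)),
               ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                      GenomicRanges::start(genes),
                      GenomicRanges::end(genes)))
})

test_that("bin_track means, truncation and mass conservation", {
  t <- depth_track(list(chr1 = rep(3.5, 2500)))
  expect_equal(bin_track(t, 1000)$chr1, c(3.5, 3.5))  # truncated tail

  t2 <- depth_track(list(chr1 = c(rep(10, 500), rep(0, 1000))))
  expect_equal(bin_track(t2, 1000)$chr1, 5.0)

  expect_equal(bin_track(depth_track(list(chr1 = 1:5)), 10)$chr1,
               numeric(0))

  withr::local_seed(4)
  t3 <- depth_track(list(chr1 = rpois(3072, 2)))
  for (w in c(7, 64, 1000)) {
    b <- bin_track(t3, w)$chr1
    expect_length(b, 3072 %/% w)
    expect_lte(sum(b) * w, total_depth(t3) + 1e-9)
  }
  b <- bin_track(t3, 512)$chr1   # divides evenly: mass preserved
  expect_equal(sum(b) * 512, total_depth(t3))
})
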