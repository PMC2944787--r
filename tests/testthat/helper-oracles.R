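# Independent brute-force oracles, deliberately kept free of the package's
# own interval machinery.

# enumerate maximal marked runs, merge across gaps <= G, filter span >= L;
# returns a 2-column matrix of 1-based [start, end] spans
peak_oracle <- function(depth, H, L, G) {
  idx <- which(depth >= H)
  empty <- cbind(start = integer(0), end = integer(0))
  if (length(idx) == 0) return(empty)
  breaks <- which(diff(idx) > 1)
  run_start <- idx[c(1, breaks + 1)]
  run_end <- idx[c(breaks, length(idx))]
  ms <- run_start[1]
  me <- run_end[1]
  out <- NULL
  for (i in seq_along(run_start)[-1]) {
    gap <- run_start[i] - me - 1
    if (gap <= G) {
      me <- run_end[i]
    } else {
      out <- rbind(out, c(ms, me))
      ms <- run_start[i]
      me <- run_end[i]
    }
  }
  out <- rbind(out, c(ms, me))
  out <- out[out[, 2] - out[, 1] + 1 >= L, , drop = FALSE]
  colnames(out) <- c("start", "end")
  out
}

peaks_as_matrix <- function(gr) {
  cbind(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

# overlapping CG dinucleotide count via zero-width lookahead regex
cpg_count_oracle <- function(s) {
  m <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_seq <- function(n, p_n = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# blocky random depth track (runs of enrichment over a zero floor)
random_depth <- function(n, n_blocks = 5, max_height = 10) {
  d <- numeric(n)
  for (b in seq_len(sample.int(n_blocks, 1))) {
    w <- sample.int(max(2, n %/% 4), 1)
    s <- sample.int(n - w + 1, 1)
    d[s:(s + w - 1)] <- d[s:(s + w - 1)] + sample.int(max_height, 1)
  }
  # sprinkle point noise so runs get ragged edges
  pts <- sample.int(n, min(n, 25))
  d[pts] <- d[pts] + sample.int(max_height, length(pts), replace = TRUE)
  d
}

make_track <- function(..., chrom = "chr1") {
  vals <- list(...)
  if (length(vals) == 1 && is.null(names(vals)))
    names(vals) <- chrom
  depth_track(vals)
}
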