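#' CpG composition statistics of a sequence
#'
#' Counts CG dinucleotides with an overlapping scan and reports the
#' observed/expected CpG ratio and the CpG density per 100 bp. The expected
#' count follows the classical Gardiner-Garden convention
#' `n_C * n_G / length`, the convention behind the usual island prediction
#' threshold of o/e >= 0.6, so `oe = n_cpg * length / (n_C * n_G)`.
#' `N` bases are excluded: they reduce the effective length and can form no
#' CpG. When the sequence contains no C or no G the ratio is undefined and
#' reported as `NA`; the density `per100 = 100 * n_cpg / length` is still
#' computed.
#'
#' @param sequence A single A/C/G/T/N string (case-insensitive).
#' @return A `CpgStats` list: `n_cpg`, `n_c`, `n_g`, `length` (non-N
#'   bases), `oe`, `per100`.
#' @examples
#' cpg_stats("CGCGCGCG")$oe   # 2
#' cpg_stats("ACGT")$per100   # 25
#' @export
cpg_stats <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  ch <- seq_chars(sequence)
  cpg_stats_chars(ch)
}

# shared fast path over a character vector of bases
cpg_stats_chars <- function(ch) {
  n <- length(ch)
  eff <- sum(ch != "N")
  n_c <- sum(ch == "C")
  n_g <- sum(ch == "G")
  n_cpg <- if (n >= 2) sum(ch[-n] == "C" & ch[-1] == "G") else 0L
  oe <- if (n_c > 0 && n_g > 0 && eff > 0)
    as.numeric(n_cpg) * eff / (as.numeric(n_c) * n_g) else NA_real_
  per100 <- if (eff > 0) 100 * as.numeric(n_cpg) / eff else NA_real_
  structure(list(n_cpg = as.integer(n_cpg), n_c = as.integer(n_c),
                 n_g = as.integer(n_g), length = as.integer(eff),
                 oe = oe, per100 = per100),
            class = "CpgStats")
}

#' @export
print.CpgStats <- function(x, ...) {
  cat(sprintf(
    "CpgStats: %d CpG over %d bp (%.2f per 100 bp), o/e = %s\n",
    x$n_cpg, x$length, x$per100,
    if (is.na(x$oe)) "undefined" else sprintf("%.3f", x$oe)))
  invisible(x)
}

seq_chars <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-ACGTN character at position ", bad[1])
  ch
}

#' Sliding-window CpG o/e profile
#'
#' Evaluates [cpg_stats()] in windows of `window` bp advanced by `slide`
#' bp (defaults 400/10, the convention used for island-scale o/e
#' profiles; 300/10 is a common variant). Windows are placed at starts
#' 1, 1+slide, ... while they fit; a sequence shorter than `window` yields
#' an empty profile. Windows with more than 20% `N` are reported as
#' missing (`NA`) rather than computed from a sliver of sequence.
#'
#' @param sequence A single A/C/G/T/N string.
#' @param window Window width in bp (>= 2).
#' @param slide Step between window starts in bp (>= 1).
#' @param max_n_frac Missingness threshold on the N fraction per window.
#' @return data.frame with `start`, `midpoint` (profile coordinate),
#'   `n_cpg`, `oe`, `per100`.
#' @export
sliding_cpg_oe <- function(sequence, window = 400, slide = 10,
                           max_n_frac = 0.2) {
  stopifnot(window >= 2, slide >= 1)
  ch <- seq_chars(sequence)
  len <- length(ch)
  if (len < window)
    return(data.frame(start = integer(0), midpoint = numeric(0),
                      n_cpg = integer(0), oe = numeric(0),
                      per100 = numeric(0)))
  starts <- seq(1L, len - window + 1L, by = slide)
  rows <- lapply(starts, function(s) {
    w <- ch[s:(s + window - 1L)]
    st <- cpg_stats_chars(w)
    if (mean(w == "N") > max_n_frac) {
      st$oe <- NA_real_
      st$per100 <- NA_real_
    }
    data.frame(start = s, midpoint = s + window / 2 - 0.5,
               n_cpg = st$n_cpg, oe = st$oe, per100 = st$per100)
  })
  do.call(rbind, rows)
}

#' CpG density bins
#'
#' Maps CpGs-per-100-bp values to the six density categories used for
#' island summaries: `<5`, `5-6`, `6-7`, `7-8`, `8-9`, `>9`. Interior
#' boundaries follow the left-closed right-open convention, so 5.0 falls
#' in `5-6`; the top bin includes 9.0 so the six bins are exhaustive.
#'
#' @param per100 Numeric vector of non-negative densities.
#' @return Factor with the six ordered bin labels.
#' @export
density_bin <- function(per100) {
  stopifnot(is.numeric(per100))
  if (any(per100 < 0, na.rm = TRUE)) stop("negative CpG density")
  cut(per100, breaks = c(0, 5, 6, 7, 8, 9, Inf), right = FALSE,
      include.lowest = TRUE,
      labels = c("<5", "5-6", "6-7", "7-8", "8-9", ">9"))
}

#' Annotate intervals with CpG statistics
#'
#' Convenience wrapper: computes [cpg_stats()] for each interval's genomic
#' sequence and attaches `n_cpg`, `oe`, `per100` and the [density_bin()]
#' label as metadata columns.
#'
#' @param intervals `GRanges` (e.g. a CGI set).
#' @param genome Named character vector of chromosome sequences, as from
#'   [read_fasta()].
#' @return `intervals` with added metadata columns.
#' @export
cgi_cpg_annotate <- function(intervals, genome) {
  stopifnot(is(intervals, "GRanges"), is.character(genome))
  stats <- lapply(seq_along(intervals), function(i) {
    ch <- as.character(seqnames(intervals)[i])
    if (!ch %in% names(genome)) stop("no sequence for chromosome ", ch)
    cpg_stats(substr(genome[[ch]], start(intervals)[i], end(intervals)[i]))
  })
  S4Vectors::mcols(intervals)$n_cpg <-
    vapply(stats, `[[`, integer(1), "n_cpg")
  S4Vectors::mcols(intervals)$oe <- vapply(stats, `[[`, numeric(1), "oe")
  S4Vectors::mcols(intervals)$per100 <-
    vapply(stats, `[[`, numeric(1), "per100")
  S4Vectors::mcols(intervals)$bin <-
    density_bin(S4Vectors::mcols(intervals)$per100)
  intervals
}
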