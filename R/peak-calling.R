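#' Height/length/gap peak-calling parameters
#'
#' The enrichment peak finder has three tuning constants: the minimum
#' per-base read height `H`, the minimum region length `L` in bp, and the
#' gap `G` permitted in the length parameter — short sub-threshold
#' interruptions of at most `G` bp inside an otherwise contiguously
#' enriched region are absorbed into it. A gap can never be the whole
#' region, hence `G < L`.
#'
#' `assay` selects a default profile calibrated on the package's synthetic
#' fixtures; the per-sample constants used for any real dataset are the
#' caller's responsibility.
#'
#' @param H Minimum per-base depth (>= 0).
#' @param L Minimum peak span in bp (>= 1).
#' @param G Maximum sub-threshold gap merged into a peak (>= 0, < L).
#' @param assay Optional profile: `"CAP"`, `"MAP"` or `"CHIP"`.
#' @return An object of class `PeakParams`.
#' @export
peak_params <- function(H = 2.5, L = 300, G = 50, assay = NULL) {
  if (!is.null(assay)) {
    assay <- match.arg(assay, c("CAP", "MAP", "CHIP"))
    def <- switch(assay,
                  CAP = list(H = 2.5, L = 300, G = 50),
                  MAP = list(H = 2.5, L = 300, G = 100),
                  CHIP = list(H = 2.5, L = 300, G = 100))
    H <- def$H; L <- def$L; G <- def$G
  }
  stopifnot(is.numeric(H), H >= 0, is.numeric(L), L >= 1,
            is.numeric(G), G >= 0)
  L <- as.integer(L); G <- as.integer(G)
  if (G >= L) stop("G must be smaller than L: a region cannot be all gap")
  structure(list(H = H, L = L, G = G), class = "PeakParams")
}

#' @export
print.PeakParams <- function(x, ...) {
  cat(sprintf("PeakParams: H = %g, L = %d bp, G = %d bp\n", x$H, x$L, x$G))
  invisible(x)
}

#' Find peaks of enrichment with the H/L/G rule
#'
#' Marks every base with depth >= `H`, merges consecutive marked runs
#' separated by at most `G` unmarked bases into candidate regions spanning
#' first to last marked base (interior gap bases count toward the span,
#' flanking sub-threshold bases never do), and reports candidates whose
#' span is at least `L` bp, sorted by chromosome and start. Reported peaks
#' never overlap. Output is monotone in the parameters: lowering `H` or
#' `L`, or raising `G`, never removes a covered base.
#'
#' @param track A [depth_track()].
#' @param params A [peak_params()].
#' @return `GRanges` of peaks (no scores; downstream statistics are
#'   recomputed from the track).
#' @examples
#' t <- depth_track(list(chr1 = c(rep(5, 150), rep(0, 50), rep(5, 150))))
#' find_peaks(t, peak_params(H = 3, L = 250, G = 60))
#' @export
find_peaks <- function(track, params) {
  stopifnot(is(track, "DepthTrack"), is(params, "PeakParams"))
  res <- lapply(track_chroms(track), function(ch) {
    r <- track$depth[[ch]]
    marked <- IRanges::ranges(IRanges::slice(r, lower = params$H))
    if (length(marked) == 0) return(GRanges())
    merged <- IRanges::reduce(marked, min.gapwidth = params$G + 1L)
    keep <- merged[width(merged) >= params$L]
    if (length(keep) == 0) return(GRanges())
    GRanges(ch, keep)
  })
  out <- suppressWarnings(do.call(c, res))
  sort(out)
}

#' Union of peak sets into one comprehensive interval set
#'
#' Combines regions of enrichment from several samples (e.g. the CAP peak
#' sets of each tissue, or high- and low-stringency CAP sets) into a single
#' non-redundant set: any base covered by any input is covered by exactly
#' one output interval. Abutting intervals merge. Idempotent, commutative
#' and associative.
#'
#' @param interval_sets List of `GRanges` (each internally non-overlapping),
#'   or a single `GRanges`.
#' @return Sorted, non-overlapping `GRanges`.
#' @export
union_peak_sets <- function(interval_sets) {
  if (is(interval_sets, "GRanges")) interval_sets <- list(interval_sets)
  stopifnot(is.list(interval_sets), length(interval_sets) >= 1)
  chrs <- lapply(interval_sets, function(g) unique(as.character(seqnames(g))))
  if (length(interval_sets) > 1 &&
      length(unique(lapply(chrs, sort))) > 1)
    warning("peak sets cover different chromosome universes; ",
            "taking the union over the joint universe")
  all <- suppressWarnings(do.call(c, unname(lapply(interval_sets, granges))))
  sort(IRanges::reduce(all))
}
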