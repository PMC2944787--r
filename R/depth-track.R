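#' Per-base read-depth track
#'
#' A `DepthTrack` holds one non-negative real depth value per base for each
#' named chromosome, run-length encoded. Depth is real-valued because
#' normalization rescales integer read counts. All downstream signal
#' computation (binning, peak calling, window means, profiles) consumes this
#' container.
#'
#' @param values Named list of per-chromosome depth, each element a numeric
#'   vector or an [S4Vectors::Rle], one value per base; alternatively an
#'   `RleList`.
#' @param seqlengths Optional named integer vector of chromosome lengths.
#'   When given, each chromosome's values must match its declared length.
#' @return An object of class `DepthTrack`.
#' @examples
#' t <- depth_track(list(chr1 = c(0, 0, 5, 5, 5, 0)))
#' total_depth(t)
#' @export
depth_track <- function(values, seqlengths = NULL) {
  if (is(values, "RleList")) values <- as.list(values)
  if (!is.list(values) ||
      (length(values) && (is.null(names(values)) || any(names(values) == ""))))
    stop("'values' must be a named list of per-chromosome depth vectors")
  depth <- lapply(values, function(v) {
    r <- if (is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    rv <- S4Vectors::runValue(r)
    if (any(!is.finite(rv))) stop("depth values must be finite")
    if (any(rv < 0)) stop("depth values must be non-negative")
    r
  })
  lens <- vapply(depth, length, integer(1))
  if (!is.null(seqlengths)) {
    seqlengths <- seqlengths[names(depth)]
    if (any(is.na(seqlengths)))
      stop("'seqlengths' must cover every chromosome in 'values'")
    if (any(lens != seqlengths))
      stop("value count per chromosome must equal its declared length")
  }
  structure(list(depth = depth, seqlengths = lens),
            class = "DepthTrack")
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat("DepthTrack with", length(x$depth), "chromosome(s)\n")
  for (ch in names(x$depth)) {
    r <- x$depth[[ch]]
    cat(sprintf("  %s: %d bp, total depth %.6g\n",
                ch, length(r), sum_rle(r)))
  }
  invisible(x)
}

#' @rdname depth_track
#' @param x A `DepthTrack`.
#' @export
track_chroms <- function(x) names(x$depth)

#' @rdname depth_track
#' @export
track_seqlengths <- function(x) x$seqlengths

#' Extract one chromosome's depth
#'
#' @param x A `DepthTrack`.
#' @param chrom Chromosome name.
#' @param as One of `"Rle"` (default) or `"numeric"`.
#' @return Per-base depth for `chrom`.
#' @export
track_depth <- function(x, chrom, as = c("Rle", "numeric")) {
  as <- match.arg(as)
  r <- x$depth[[chrom]]
  if (is.null(r)) stop("unknown chromosome: ", chrom)
  if (as == "numeric") as.numeric(r) else r
}

#' Multiply every depth value by a constant
#'
#' @param x A `DepthTrack`.
#' @param factor Positive scale factor.
#' @return A scaled `DepthTrack`.
#' @export
track_scale <- function(x, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, is.finite(factor),
            factor >= 0)
  depth_track(lapply(x$depth, function(r) r * factor))
}

# exact total of a numeric/integer Rle without decoding
sum_rle <- function(r) {
  sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r))
}

#' Mean depth in non-overlapping windows
#'
#' Tiles each chromosome into contiguous windows `[1,w]`, `[w+1,2w]`, ... and
#' reports the mean depth of each. A trailing window shorter than `width` is
#' dropped rather than padded, so the windowed statistic is not biased by
#' short chromosome tails.
#'
#' @param track A [depth_track()].
#' @param width Window width in bp (>= 1).
#' @return Named list with one numeric vector of window means per
#'   chromosome; a chromosome shorter than `width` yields `numeric(0)`.
#' @examples
#' t <- depth_track(list(chr1 = rep(c(10, 0), each = 500)))
#' bin_track(t, 1000)[["chr1"]]  # 5
#' @export
bin_track <- function(track, width) {
  stopifnot(is(track, "DepthTrack"), is.numeric(width), length(width) == 1,
            width >= 1)
  width <- as.integer(width)
  lapply(track$depth, function(r) {
    n <- length(r) %/% width
    if (n == 0L) return(numeric(0))
    v <- IRanges::Views(r, start = seq(1L, by = width, length.out = n),
                        width = width)
    unname(IRanges::viewMeans(v))
  })
}
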