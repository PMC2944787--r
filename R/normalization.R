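#' Total depth of a track
#'
#' Sum of all per-base depth values across chromosomes; the quantity that
#' like-assay samples are scaled to have in common.
#'
#' @param track A [depth_track()].
#' @return A single non-negative number.
#' @export
total_depth <- function(track) {
  stopifnot(is(track, "DepthTrack"))
  sum(vapply(track$depth, sum_rle, numeric(1)))
}

#' Remove diffuse background from a track
#'
#' Zeroes every base whose depth is at or below `floor`; bases above the
#' floor are unchanged. MAP-seq tracks carry diffuse signal from the
#' partially methylated bulk genome, and such background reads would skew a
#' total-count normalization, so it is removed first. Idempotent, and never
#' increases any base's depth.
#'
#' @param track A [depth_track()].
#' @param floor Non-negative depth threshold (default 2).
#' @return A new `DepthTrack`.
#' @export
remove_background <- function(track, floor = 2) {
  stopifnot(is(track, "DepthTrack"), is.numeric(floor), floor >= 0)
  depth_track(lapply(track$depth, function(r) {
    r[r <= floor] <- 0
    r
  }))
}

#' Scale like-assay samples to a common total
#'
#' Each track is multiplied by `target_total / total_depth(track)`, so all
#' like samples (e.g. all CAP purifications) end up with the same total and
#' become directly comparable despite variable sequencing depth. With
#' `target_total = "auto"` the constant approximates the average read
#' number: the arithmetic mean of the input totals. Any background removal
#' must be applied before calling this function so background does not
#' distort the totals.
#'
#' @param tracks Named list of [depth_track()] objects from the same assay.
#' @param target_total Positive constant, or `"auto"` (mean of the totals).
#' @return A list with `tracks` (scaled, same names) and `factors`, a
#'   data.frame of per-sample raw totals and scale factors.
#' @examples
#' a <- depth_track(list(chr1 = rep(1, 100)))   # total 100
#' b <- depth_track(list(chr1 = rep(2, 100)))   # total 200
#' scale_like_samples(list(a = a, b = b))$factors
#' @export
scale_like_samples <- function(tracks, target_total = "auto") {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (is.null(names(tracks)))
    names(tracks) <- paste0("sample", seq_along(tracks))
  totals <- vapply(tracks, total_depth, numeric(1))
  if (any(totals == 0))
    stop("cannot scale zero-total sample(s): ",
         paste(names(tracks)[totals == 0], collapse = ", "))
  if (identical(target_total, "auto")) {
    target <- mean(totals)
  } else {
    stopifnot(is.numeric(target_total), target_total > 0)
    target <- target_total
  }
  factors <- target / totals
  scaled <- mapply(track_scale, tracks, factors, SIMPLIFY = FALSE)
  list(tracks = scaled,
       factors = data.frame(sample = names(tracks), total = unname(totals),
                            factor = unname(factors),
                            scaled_total = unname(totals * factors)))
}

#' Standard normalization pipeline for one assay
#'
#' For CAP and ChIP-style tracks this is [scale_like_samples()]. MAP
#' tracks additionally carry diffuse background whose between-sample
#' fluctuations would skew the scaling constant, so their scale factors
#' are computed from background-removed copies
#' ([remove_background()], floor `background_floor`) and then applied to
#' the intact tracks — the sliding-window methylation comparison needs
#' the smooth background left in place, since flooring turns it into
#' sparse spikes that destabilize window ratios.
#'
#' @param tracks Named list of [depth_track()]s from one assay.
#' @param assay `"CAP"`, `"MAP"` or `"CHIP"`.
#' @param background_floor Depth floor used for MAP factor computation.
#' @param target_total As in [scale_like_samples()].
#' @return List with `tracks` (scaled) and `factors` (data.frame).
#' @export
normalize_tracks <- function(tracks, assay = c("CAP", "MAP", "CHIP"),
                             background_floor = 2, target_total = "auto") {
  assay <- match.arg(assay)
  if (assay != "MAP")
    return(scale_like_samples(tracks, target_total))
  floored <- lapply(tracks, remove_background, floor = background_floor)
  factors <- scale_like_samples(floored, target_total)$factors
  scaled <- mapply(track_scale, tracks, factors$factor, SIMPLIFY = FALSE)
  list(tracks = scaled, factors = factors)
}
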