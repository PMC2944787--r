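#' Composite-profile parameters
#'
#' Defaults mirror the island-anchored H3K4me3 profile convention:
#' read depth averaged across 500 bp windows with a 100 bp slide spanning
#' 5 kb around each CGI midpoint, with the central 2 kb used for per-bin
#' summary values.
#'
#' @param span Total profile span in bp, centred on interval midpoints.
#' @param window,slide Window width and step in bp.
#' @param central Width of the central summary region in bp.
#' @return An object of class `ProfileParams`.
#' @export
profile_params <- function(span = 5000, window = 500, slide = 100,
                           central = 2000) {
  stopifnot(window <= span, central <= span, slide >= 1,
            (span - window) %% slide == 0)
  structure(list(span = as.integer(span), window = as.integer(window),
                 slide = as.integer(slide), central = as.integer(central)),
            class = "ProfileParams")
}

#' Composite read-depth profile around intervals
#'
#' Window means at fixed offsets relative to each interval's midpoint,
#' aggregated across intervals as per-offset median and quartiles (the
#' tabular equivalent of a box-plot meta-profile). Intervals truncated by
#' chromosome ends contribute only the windows that exist.
#'
#' @param track A [depth_track()].
#' @param intervals Non-empty `GRanges`, anchored at their midpoints.
#' @param params A [profile_params()].
#' @return data.frame with `offset` (window centre relative to interval
#'   midpoint), `median`, `q25`, `q75`, `n` (intervals contributing).
#' @export
composite_profile <- function(track, intervals, params = profile_params()) {
  stopifnot(is(track, "DepthTrack"), is(intervals, "GRanges"),
            length(intervals) >= 1, is(params, "ProfileParams"))
  k <- (params$span - params$window) %/% params$slide + 1L
  rel_starts <- -params$span %/% 2L + params$slide * (0:(k - 1L))
  offsets <- rel_starts + params$window / 2
  mids <- (start(intervals) + end(intervals)) %/% 2L
  vals <- matrix(NA_real_, length(intervals), k)
  for (i in seq_along(intervals)) {
    ch <- as.character(seqnames(intervals)[i])
    r <- track$depth[[ch]]
    if (is.null(r)) next
    starts <- mids[i] + rel_starts
    ok <- starts >= 1L & (starts + params$window - 1L) <= length(r)
    if (!any(ok)) next
    v <- IRanges::Views(r, start = starts[ok], width = params$window)
    vals[i, ok] <- IRanges::viewMeans(v)
  }
  data.frame(
    offset = offsets,
    median = apply(vals, 2, stats::median, na.rm = TRUE),
    q25 = apply(vals, 2, stats::quantile, probs = 0.25, na.rm = TRUE,
                names = FALSE),
    q75 = apply(vals, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
                names = FALSE),
    n = colSums(!is.na(vals)))
}

#' Mean central signal per CpG-density bin
#'
#' Groups CGIs by [density_bin()] of their CpG density and reports, per
#' bin, the mean read depth over each CGI's central region (default 2 kb
#' around the midpoint), averaged across the bin's CGIs. Relates CpG
#' density to chromatin signal (e.g. H3K4me3). Bins with no members are
#' reported as missing, not zero.
#'
#' @param cgis `GRanges` carrying a `per100` metadata column (see
#'   [cgi_cpg_annotate()]).
#' @param track A [depth_track()].
#' @param params A [profile_params()]; only `central` is used.
#' @return data.frame with `bin`, `n`, `mean_central`.
#' @export
density_bin_summary <- function(cgis, track, params = profile_params()) {
  stopifnot(is(cgis, "GRanges"), is(track, "DepthTrack"))
  per100 <- S4Vectors::mcols(cgis)$per100
  if (is.null(per100)) stop("'cgis' must carry a per100 column")
  bins <- density_bin(per100)
  half <- params$central %/% 2L
  mids <- (start(cgis) + end(cgis)) %/% 2L
  central_mean <- vapply(seq_along(cgis), function(i) {
    ch <- as.character(seqnames(cgis)[i])
    r <- track$depth[[ch]]
    if (is.null(r)) return(NA_real_)
    s <- max(1L, mids[i] - half)
    e <- min(length(r), mids[i] + half - 1L)
    if (e < s) return(NA_real_)
    IRanges::viewMeans(IRanges::Views(r, start = s, end = e))
  }, numeric(1))
  out <- data.frame(bin = levels(bins), n = as.integer(table(bins)))
  out$mean_central <- vapply(levels(bins), function(b) {
    v <- central_mean[bins == b]
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Genome-wide Pearson correlation of two tracks
#'
#' Both tracks are reduced to mean depth in every contiguous `width`-bp
#' window (via [bin_track()]) and the Pearson correlation is computed over
#' paired windows. Windows where both tracks are zero are retained — the
#' statistic covers every window, not only covered ones. Symmetric, and
#' invariant to positive affine rescaling of either track.
#'
#' @param track_a,track_b [depth_track()]s on the same chromosomes.
#' @param width Window width in bp (default 1000).
#' @return Pearson r, or `NA` when either binned vector has zero variance
#'   (undefined correlation).
#' @export
pairwise_correlation <- function(track_a, track_b, width = 1000) {
  ba <- bin_track(track_a, width)
  bb <- bin_track(track_b, width)
  common <- intersect(names(ba), names(bb))
  if (!setequal(names(ba), names(bb)))
    warning("tracks cover different chromosomes; correlating the ",
            "common set: ", paste(common, collapse = ", "))
  if (length(common) == 0) stop("no common chromosomes")
  x <- unlist(ba[common], use.names = FALSE)
  y <- unlist(bb[common], use.names = FALSE)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  if (identical(x, y)) return(1)   # self-correlation is 1 by definition
  stats::cor(x, y)
}

#' Welch two-sample t-test
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees of
#' freedom), as used to compare CpG o/e distributions between island sets.
#' Requires at least two observations per sample; two exactly constant
#' samples have no defined statistic and raise an error.
#'
#' @param sample_x,sample_y Numeric vectors (n >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_x, sample_y) {
  if (length(sample_x) < 2 || length(sample_y) < 2)
    stop("welch_t requires n >= 2 in both samples")
  ht <- tryCatch(t.test(sample_x, sample_y, var.equal = FALSE),
                 error = function(e)
                   stop("welch_t: ", conditionMessage(e), call. = FALSE))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Counts and percentages per class and condition
#'
#' Cross-tabulates CGI positional classes against one or more logical
#' conditions (e.g. "methylated in colon", "methylated in tumour only")
#' with explicit numerators and denominators.
#'
#' @param classes Factor/character of positional classes, one per CGI.
#' @param conditions Named list of logical vectors (or a single logical
#'   vector) aligned with `classes`.
#' @return data.frame with `class`, `condition`, `n`, `count`, `pct`; an
#'   `Overall` row per condition gives the whole-set percentage.
#' @export
category_percentage_table <- function(classes, conditions) {
  if (is.logical(conditions)) conditions <- list(condition = conditions)
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  classes <- as.factor(classes)
  if (length(classes) == 0)
    return(data.frame(class = character(0), condition = character(0),
                      n = integer(0), count = integer(0),
                      pct = numeric(0)))
  rows <- list()
  for (cond in names(conditions)) {
    v <- conditions[[cond]]
    stopifnot(length(v) == length(classes))
    for (cl in c(levels(classes), "Overall")) {
      sel <- if (cl == "Overall") rep(TRUE, length(classes))
             else classes == cl
      n <- sum(sel)
      k <- sum(v[sel], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, condition = cond, n = n, count = k,
        pct = if (n > 0) 100 * k / n else NA_real_)
    }
  }
  do.call(rbind, rows)
}
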