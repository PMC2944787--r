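#' Differential-methylation calling parameters
#'
#' The sliding-window differential methylation rule compares a somatic
#' MAP-seq track against the hypomethylated germline (sperm) reference
#' over each CGI: mean depth is computed in `window`-bp windows advanced by
#' `slide` bp; window read totals below `read_floor` on both sides force
#' the ratio to 1 (removing bias from small fluctuations at low depth);
#' and a CGI is called differentially methylated when some frame of `m`
#' contiguous windows contains at least `k` windows whose log2 ratio
#' exceeds `log2_threshold` (scored +1, more methylated than the
#' reference) or falls below its negative (scored -1). Defaults: 100 bp
#' window, 20 bp slide, floor 4 reads, threshold 2, 9 of 10 windows.
#'
#' `pseudocount` regularizes the ratio when only one side is below the
#' floor (a zero reference window would otherwise give an infinite ratio).
#' With `proportional = TRUE`, CGIs with fewer than `m` windows are
#' evaluated with the proportional rule (at least `ceiling(0.9 n)` of all
#' `n` windows) instead of being non-evaluable.
#'
#' @param window,slide Window width and step in bp (`window > slide > 0`).
#' @param read_floor Window read total below which both-low windows get
#'   ratio 1.
#' @param log2_threshold Positive log2-ratio threshold.
#' @param k,m At least `k` of `m` contiguous windows must exceed the
#'   threshold (`k <= m`).
#' @param pseudocount Added to both window totals in the ratio.
#' @param proportional Evaluate short CGIs proportionally instead of
#'   scoring them 0.
#' @return An object of class `DmParams`.
#' @export
dm_params <- function(window = 100, slide = 20, read_floor = 4,
                      log2_threshold = 2, k = 9, m = 10, pseudocount = 1,
                      proportional = FALSE) {
  stopifnot(window > slide, slide > 0, read_floor >= 0, log2_threshold > 0,
            k >= 1, k <= m, pseudocount > 0)
  structure(list(window = as.integer(window), slide = as.integer(slide),
                 read_floor = read_floor, log2_threshold = log2_threshold,
                 k = as.integer(k), m = as.integer(m),
                 pseudocount = pseudocount,
                 proportional = isTRUE(proportional)),
            class = "DmParams")
}

#' @export
print.DmParams <- function(x, ...) {
  cat(sprintf(
    "DmParams: %d bp window / %d bp slide, floor %g reads, |log2| > %g in >= %d of %d windows\n",
    x$window, x$slide, x$read_floor, x$log2_threshold, x$k, x$m))
  invisible(x)
}

#' Sliding-window mean depth over an interval
#'
#' Average depth per base in `window`-bp windows advanced by `slide` bp
#' across one interval; windows are placed while they fit entirely inside
#' the interval, giving `floor((len - window)/slide) + 1` windows. An
#' interval shorter than `window` yields an empty series.
#'
#' @param track A [depth_track()].
#' @param interval A length-1 `GRanges`.
#' @param params A [dm_params()] supplying `window` and `slide`.
#' @return Numeric vector of window means, ordered along the interval.
#' @export
window_means <- function(track, interval, params = dm_params()) {
  stopifnot(is(track, "DepthTrack"), is(interval, "GRanges"),
            length(interval) == 1, is(params, "DmParams"))
  ch <- as.character(seqnames(interval))
  r <- track$depth[[ch]]
  if (is.null(r)) stop("track has no chromosome ", ch)
  len <- width(interval)
  if (len < params$window) return(numeric(0))
  k <- (len - params$window) %/% params$slide + 1L
  starts <- start(interval) + params$slide * (0:(k - 1L))
  v <- IRanges::Views(r, start = starts, width = params$window)
  unname(IRanges::viewMeans(v))
}

#' Differential-methylation score for one CGI
#'
#' Compares matched window-mean series (same interval, same windows) from
#' the reference and test MAP tracks; see [dm_params()] for the rule.
#' Scores: +1 more methylated than the reference, -1 less, 0 unchanged.
#' CGIs with fewer than `m` windows are non-evaluable and scored 0
#' (flagged), unless the proportional rule is enabled.
#'
#' @param ref_series,test_series Equal-length numeric vectors of window
#'   means (reference = hypomethylated germline).
#' @param params A [dm_params()].
#' @return A `DmCall` list: `score` in `-1/0/1`, `n_windows`, `evaluable`,
#'   `n_up`, `n_down`, and the per-window `log2_ratio`.
#' @export
dm_score <- function(ref_series, test_series, params = dm_params()) {
  stopifnot(is(params, "DmParams"))
  if (length(ref_series) != length(test_series))
    stop("window series length mismatch: ", length(ref_series), " vs ",
         length(test_series))
  n <- length(ref_series)
  t_ref <- ref_series * params$window
  t_test <- test_series * params$window
  eps <- params$pseudocount
  ratio <- (t_test + eps) / (t_ref + eps)
  ratio[t_ref < params$read_floor & t_test < params$read_floor] <- 1
  l2 <- log2(ratio)
  up <- l2 > params$log2_threshold
  dn <- l2 < -params$log2_threshold
  evaluable <- n >= params$m
  score <- 0L
  if (evaluable) {
    if (frame_hit(up, params$k, params$m)) score <- 1L
    else if (frame_hit(dn, params$k, params$m)) score <- -1L
  } else if (params$proportional && n > 0) {
    need <- ceiling(params$k / params$m * n)
    if (sum(up) >= need) score <- 1L
    else if (sum(dn) >= need) score <- -1L
    evaluable <- TRUE
  }
  structure(list(score = score, n_windows = n, evaluable = evaluable,
                 n_up = sum(up), n_down = sum(dn), log2_ratio = l2),
            class = "DmCall")
}

# does any frame of m consecutive indicators contain >= k TRUEs?
frame_hit <- function(ind, k, m) {
  n <- length(ind)
  if (n < m) return(FALSE)
  cs <- c(0L, cumsum(ind))
  any(cs[(m + 1L):(n + 1L)] - cs[1:(n - m + 1L)] >= k)
}

#' @export
print.DmCall <- function(x, ...) {
  cat(sprintf("DmCall: score %+d (%d windows, %d up / %d down%s)\n",
              x$score, x$n_windows, x$n_up, x$n_down,
              if (x$evaluable) "" else ", non-evaluable"))
  invisible(x)
}

#' Differential-methylation score matrix
#'
#' Applies [window_means()] + [dm_score()] to every CGI and every test
#' sample against the common reference track. Tracks should be normalized
#' (and MAP background removed) beforehand so window totals are
#' comparable. A CGI whose windows cannot be computed in some sample is
#' reported as `NA` with a logged reason.
#'
#' @param cgis `GRanges` of CGIs; row names are taken from a `cgi_id`
#'   metadata column, then `names(cgis)`, else `chrom:start-end`.
#' @param ref_track Reference [depth_track()] (hypomethylated germline).
#' @param test_tracks Named list of test [depth_track()]s.
#' @param params A [dm_params()].
#' @return Integer matrix of scores (-1/0/1), CGIs x samples, with an
#'   `evaluable` logical attribute of the same shape.
#' @export
dm_matrix <- function(cgis, ref_track, test_tracks, params = dm_params()) {
  stopifnot(is(cgis, "GRanges"), is(ref_track, "DepthTrack"),
            is.list(test_tracks), length(test_tracks) >= 1,
            !is.null(names(test_tracks)))
  ids <- cgi_ids(cgis)
  scores <- matrix(NA_integer_, length(cgis), length(test_tracks),
                   dimnames = list(ids, names(test_tracks)))
  evaluable <- matrix(NA, length(cgis), length(test_tracks),
                      dimnames = dimnames(scores))
  for (i in seq_along(cgis)) {
    ref_series <- tryCatch(window_means(ref_track, cgis[i], params),
                           error = function(e) e)
    if (inherits(ref_series, "error")) {
      message("dm_matrix: skipping ", ids[i], ": ",
              conditionMessage(ref_series))
      next
    }
    for (j in seq_along(test_tracks)) {
      call <- tryCatch({
        ts <- window_means(test_tracks[[j]], cgis[i], params)
        dm_score(ref_series, ts, params)
      }, error = function(e) e)
      if (inherits(call, "error")) {
        message("dm_matrix: ", ids[i], " / ", names(test_tracks)[j], ": ",
                conditionMessage(call))
        next
      }
      scores[i, j] <- call$score
      evaluable[i, j] <- call$evaluable
    }
  }
  attr(scores, "evaluable") <- evaluable
  scores
}

cgi_ids <- function(cgis) {
  ids <- S4Vectors::mcols(cgis)$cgi_id
  if (is.null(ids)) ids <- names(cgis)
  if (is.null(ids))
    ids <- sprintf("%s:%d-%d", as.character(seqnames(cgis)),
                   start(cgis), end(cgis))
  as.character(ids)
}

#' Tumour/normal consensus methylation calls
#'
#' Partitions CGIs by their +1 calls across a matched tumour/normal
#' cohort: `tumour_specific` CGIs are heavily methylated in at least
#' `min_tumour` tumours while methylated in at most `max_normal` normals
#' (defaults: at least 3 of 5 tumours, no normals); `normal_only` applies
#' the mirrored thresholds; `shared` CGIs are methylated in at least
#' `min_shared` samples of each group and belong to neither specific set.
#' The three subsets are disjoint.
#'
#' @param score_table Matrix of -1/0/1 scores, CGIs x samples (as from
#'   [dm_matrix()]).
#' @param tumour_samples,normal_samples Column names of the two groups.
#' @param min_tumour Minimum +1 tumours for a tumour-specific call.
#' @param max_normal Maximum +1 normals tolerated in a specific call.
#' @param min_shared Minimum +1 samples per group for a shared call.
#' @return List of character vectors of CGI ids: `tumour_specific`,
#'   `normal_only`, `shared`.
#' @export
consensus_tumour_calls <- function(score_table, tumour_samples,
                                   normal_samples, min_tumour = 3,
                                   max_normal = 0, min_shared = 1) {
  missing <- setdiff(c(tumour_samples, normal_samples),
                     colnames(score_table))
  if (length(missing))
    stop("sample(s) absent from score table: ",
         paste(missing, collapse = ", "))
  tum <- rowSums(score_table[, tumour_samples, drop = FALSE] == 1,
                 na.rm = TRUE)
  nor <- rowSums(score_table[, normal_samples, drop = FALSE] == 1,
                 na.rm = TRUE)
  ids <- rownames(score_table)
  tumour_specific <- ids[tum >= min_tumour & nor <= max_normal]
  normal_only <- ids[nor >= min_tumour & tum <= max_normal]
  shared <- setdiff(ids[tum >= min_shared & nor >= min_shared],
                    c(tumour_specific, normal_only))
  list(tumour_specific = tumour_specific, normal_only = normal_only,
       shared = shared)
}

#' Cross-species conservation of CGI methylation
#'
#' Among species-A CGIs of each positional class that are methylated
#' (score +1) and have an orthologous CGI, the percentage whose ortholog
#' is also methylated in species B. Intergenic CGIs are excluded by
#' default (orthology calls there are unreliable).
#'
#' @param ortholog_pairs data.frame with columns `a` and `b`: paired CGI
#'   ids in species A and B.
#' @param calls_a,calls_b Named vectors of -1/0/1 scores per CGI id.
#' @param classes_a Named factor/character of positional classes for
#'   species-A CGIs.
#' @param exclude Classes to drop (default `"Intergenic"`).
#' @return data.frame with `class`, `n_methylated` (A-methylated with
#'   ortholog), `n_conserved`, `pct`.
#' @export
conservation_table <- function(ortholog_pairs, calls_a, calls_b, classes_a,
                               exclude = "Intergenic") {
  if (nrow(ortholog_pairs) == 0) {
    warning("empty ortholog pair table")
    return(data.frame(class = character(0), n_methylated = integer(0),
                      n_conserved = integer(0), pct = numeric(0)))
  }
  stopifnot(all(c("a", "b") %in% colnames(ortholog_pairs)))
  unknown <- c(setdiff(ortholog_pairs$a, names(calls_a)),
               setdiff(ortholog_pairs$b, names(calls_b)))
  if (length(unknown))
    stop("ortholog pair references unknown CGI id(s): ",
         paste(unique(unknown), collapse = ", "))
  if (is.null(names(classes_a)))
    stop("'classes_a' must be named by CGI id")
  cls_names <- names(classes_a)
  classes_a <- as.factor(classes_a)
  keep <- setdiff(levels(classes_a), exclude)
  rows <- lapply(keep, function(cl) {
    in_cl <- cls_names[classes_a == cl]
    p <- ortholog_pairs[ortholog_pairs$a %in% in_cl &
                          calls_a[ortholog_pairs$a] == 1, , drop = FALSE]
    n <- nrow(p)
    k <- sum(calls_b[p$b] == 1)
    data.frame(class = cl, n_methylated = n, n_conserved = k,
               pct = if (n > 0) 100 * k / n else NA_real_)
  })
  if (length(rows) == 0)
    return(data.frame(class = character(0), n_methylated = integer(0),
                      n_conserved = integer(0), pct = numeric(0)))
  do.call(rbind, rows)
}
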