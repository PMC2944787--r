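#' Classify CGIs relative to gene models
#'
#' A CGI extended by `flank` bp on each side is promoter-associated
#' (`ATSS`) when it reaches the transcription start site of any annotated
#' gene; otherwise it is `Intragenic` when the extended interval overlaps
#' any gene body, and `Intergenic` when it overlaps none. The three classes
#' partition every CGI set; `ATSS` takes precedence because promoter status
#' is the biologically privileged call, and a CGI spanning the TSSs of two
#' genes (a bidirectional promoter) is still simply `ATSS`. CGIs that are
#' not `ATSS` are the "orphan" CGIs.
#'
#' @param cgis `GRanges` of CGIs.
#' @param genes Stranded `GRanges` of gene models (one TSS per model; see
#'   [collapse_gene_models()] for transcript-level input).
#' @param flank Extension in bp on each side (default 100).
#' @return Factor with levels `ATSS`, `Intragenic`, `Intergenic`.
#' @export
classify_cgi <- function(cgis, genes, flank = 100) {
  stopifnot(is(cgis, "GRanges"), is(genes, "GRanges"), flank >= 0)
  tss <- gene_tss(genes)  # errors on unstranded models
  ext <- suppressWarnings(trim_to_start(cgis + flank))
  atss <- suppressWarnings(
    IRanges::overlapsAny(ext, tss, ignore.strand = TRUE))
  intra <- suppressWarnings(
    IRanges::overlapsAny(ext, genes, ignore.strand = TRUE))
  cls <- ifelse(atss, "ATSS", ifelse(intra, "Intragenic", "Intergenic"))
  factor(cls, levels = c("ATSS", "Intragenic", "Intergenic"))
}

# clip extended intervals at position 1 (chromosome starts)
trim_to_start <- function(gr) {
  start(gr) <- pmax(start(gr), 1L)
  gr
}

#' Flag CGIs overlapping a feature peak set
#'
#' A CGI is flagged when, extended by `flank` bp, it overlaps at least one
#' feature interval by at least one base (an abutting feature does not
#' count). Used to intersect CGIs with H3K4me3 / RNAPII / H3K27me3 domains
#' or any other peak BED.
#'
#' @param cgis `GRanges` of CGIs.
#' @param feature_peaks Non-overlapping `GRanges` of feature intervals.
#' @param flank Extension in bp (default 100).
#' @return Logical vector, one flag per CGI.
#' @export
intersect_features <- function(cgis, feature_peaks, flank = 100) {
  stopifnot(is(cgis, "GRanges"), is(feature_peaks, "GRanges"), flank >= 0)
  ext <- trim_to_start(cgis + flank)
  suppressWarnings(
    IRanges::overlapsAny(ext, feature_peaks, ignore.strand = TRUE))
}

#' @rdname intersect_features
#' @param label Name of the metadata column to store the flags in.
#' @return `add_feature_flag()`: `cgis` with a logical metadata column
#'   `label`.
#' @export
add_feature_flag <- function(cgis, feature_peaks, label, flank = 100) {
  S4Vectors::mcols(cgis)[[label]] <-
    intersect_features(cgis, feature_peaks, flank = flank)
  cgis
}

#' Per-class feature-overlap percentages
#'
#' For each positional class and each feature flag, the percentage of CGIs
#' carrying the flag, plus an `Any` column for the union across flags.
#' Numerators and denominators are reported explicitly; an empty class
#' yields a missing percentage, not zero.
#'
#' @param cgis `GRanges` with a `class` metadata column (or supply
#'   `classes`) and logical flag columns.
#' @param flag_columns Character vector of flag column names.
#' @param classes Optional factor of classes, overriding `mcols(cgis)$class`.
#' @return data.frame with one row per (class, flag) cell: `class`, `flag`,
#'   `n`, `flagged`, `pct`.
#' @export
overlap_table <- function(cgis, flag_columns, classes = NULL) {
  stopifnot(is(cgis, "GRanges"))
  if (is.null(classes)) classes <- S4Vectors::mcols(cgis)$class
  if (is.null(classes)) stop("no 'class' column and no 'classes' given")
  classes <- as.factor(classes)
  flags <- as.data.frame(S4Vectors::mcols(cgis)[flag_columns])
  if (length(flag_columns) > 1)
    flags$Any <- Reduce(`|`, flags[flag_columns])
  rows <- list()
  for (cl in levels(classes)) {
    in_cl <- classes == cl
    for (fc in colnames(flags)) {
      n <- sum(in_cl)
      k <- sum(flags[[fc]][in_cl])
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, flag = fc, n = n, flagged = k,
        pct = if (n > 0) 100 * k / n else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Fraction of query intervals near a CGI
#'
#' Fraction of `query_intervals` lying within `max_dist` bp of the nearest
#' CGI; an overlapping query has distance 0 and a query separated from the
#' nearest CGI by a gap of exactly `max_dist` intervening bases is still
#' counted (inclusive bound). Used e.g. to ask what fraction of candidate
#' enhancer elements map near orphan CGIs.
#'
#' @param query_intervals `GRanges` of query elements.
#' @param cgis Non-empty `GRanges` of CGIs.
#' @param max_dist Maximum separation in bp (default 100).
#' @return A fraction in `[0, 1]`.
#' @export
proximity_fraction <- function(query_intervals, cgis, max_dist = 100) {
  stopifnot(is(query_intervals, "GRanges"), max_dist >= 0)
  if (!is(cgis, "GRanges") || length(cgis) == 0)
    stop("empty CGI set")
  d <- suppressWarnings(
    GenomicRanges::distanceToNearest(query_intervals, cgis,
                                     ignore.strand = TRUE))
  near <- S4Vectors::mcols(d)$distance <= max_dist
  sum(near) / length(query_intervals)
}

#' Match two interval sets by reciprocal overlap
#'
#' Pairs query and subject intervals whose overlap covers at least
#' `min_frac` of both. Used to score called peaks against planted truth
#' (the 50% reciprocal-overlap convention).
#'
#' @param query,subject `GRanges`.
#' @param min_frac Minimum fraction of each interval that must be covered
#'   by the overlap (default 0.5).
#' @return data.frame with `query` and `subject` indices of matched pairs.
#' @export
reciprocal_overlap_match <- function(query, subject, min_frac = 0.5) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE))
  if (length(hits) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  q <- query[S4Vectors::queryHits(hits)]
  s <- subject[S4Vectors::subjectHits(hits)]
  ov <- width(IRanges::pintersect(IRanges::ranges(q), IRanges::ranges(s)))
  keep <- ov >= min_frac * width(q) & ov >= min_frac * width(s)
  data.frame(query = S4Vectors::queryHits(hits)[keep],
             subject = S4Vectors::subjectHits(hits)[keep])
}
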