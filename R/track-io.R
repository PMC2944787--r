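#' Read a WIG file into a depth track
#'
#' Supports fixedStep and variableStep declarations (with `span`). WIG
#' coordinates are 1-based and map directly onto the track's base indexing;
#' bases not covered by any record get depth 0.
#'
#' @param path Path to a WIG file.
#' @param seqlengths Optional named chromosome lengths. When omitted, each
#'   chromosome's length is the largest covered position. Declared records
#'   must lie within the given bounds.
#' @return A [depth_track()].
#' @export
read_wig <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_wig_lines(path)
  gr <- tryCatch(rtracklayer::import(path, format = "wig"),
                 error = function(e)
                   stop("malformed WIG file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr <- as(gr, "GRanges")
  if (length(gr) && any(S4Vectors::mcols(gr)$score < 0))
    stop("negative depth value in WIG file: ", path)
  if (!is.null(seqlengths)) {
    bad <- end(gr) > seqlengths[as.character(seqnames(gr))]
    if (any(is.na(bad)) || any(bad))
      stop("WIG record outside declared chromosome bounds in ", path)
    sl <- seqlengths
  } else {
    if (length(gr) == 0) return(depth_track(list()))
    sl <- vapply(split(end(gr), as.character(seqnames(gr))), max, numeric(1))
    sl <- setNames(as.integer(sl), names(sl))
  }
  # build each chromosome's Rle directly from the (non-overlapping) records
  # so fractional depths survive bit-exactly
  cov <- lapply(names(sl), function(ch) {
    g <- gr[as.character(seqnames(gr)) == ch]
    if (length(g) == 0) return(S4Vectors::Rle(0, sl[[ch]]))
    g <- g[order(start(g))]
    s <- start(g); e <- end(g)
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping WIG records on ", ch, " in ", path)
    gap_before <- s - c(0L, e[-length(e)]) - 1L
    lens <- as.vector(rbind(gap_before, e - s + 1L))
    vals <- as.vector(rbind(0, S4Vectors::mcols(g)$score))
    tail_gap <- sl[[ch]] - e[length(e)]
    if (tail_gap > 0) {
      lens <- c(lens, tail_gap)
      vals <- c(vals, 0)
    }
    S4Vectors::Rle(vals[lens > 0], lens[lens > 0])
  })
  names(cov) <- names(sl)
  depth_track(cov, seqlengths = sl)
}

# Cheap structural scan so malformed input is reported with its line number;
# the actual parse is delegated to rtracklayer.
validate_wig_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grepl("^(track|browser|#)", lines)
  decl <- grepl("^(fixedStep|variableStep)([ \t]+\\w+=\\S+)+[ \t]*$", lines)
  num <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"
  data1 <- grepl(paste0("^[ \t]*", num, "[ \t]*$"), lines)
  data2 <- grepl(paste0("^[ \t]*[0-9]+[ \t]+", num, "[ \t]*$"), lines)
  blank <- grepl("^[ \t]*$", lines)
  bad <- which(!(header | decl | data1 | data2 | blank))
  if (length(bad))
    stop("malformed WIG line ", bad[1], " in '", path, "': ",
         lines[bad[1]], call. = FALSE)
  invisible(TRUE)
}

#' Write a depth track as WIG
#'
#' Emits one fixedStep block per run of equal depth (zero runs are omitted),
#' printing values with enough digits that `read_wig(write_wig(t))`
#' reproduces `t` exactly, including fractional depths produced by
#' normalization.
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @param name Track name for the `track` line.
#' @return Invisibly, `path`.
#' @export
write_wig <- function(track, path, name = "capmapr") {
  stopifnot(is(track, "DepthTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  for (ch in track_chroms(track)) {
    r <- track$depth[[ch]]
    rv <- S4Vectors::runValue(r)
    rl <- S4Vectors::runLength(r)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    keep <- rv != 0
    if (!any(keep)) next
    blocks <- sprintf("fixedStep chrom=%s start=%d step=%d span=%d\n%.17g",
                      ch, starts[keep], rl[keep], rl[keep], rv[keep])
    writeLines(blocks, con)
  }
  invisible(path)
}

#' Read/write BED intervals
#'
#' BED is 0-based half-open on disk; in memory intervals are `GRanges`
#' (1-based closed), converted at this boundary. Columns beyond the first
#' six are ignored with a warning. Overlapping records are preserved as-is.
#'
#' @param path BED file path.
#' @return `read_bed()`: a `GRanges` in file order with `name` and `score`
#'   columns when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:12), fill = TRUE,
                           comment.char = "#")
  if (ncol(raw) >= 3) {
    bad <- which(!(raw$V3 > raw$V2))
    if (length(bad))
      stop("BED line ", bad[1], ": start >= end", call. = FALSE)
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr <- as(gr, "GRanges")
  extra <- setdiff(colnames(S4Vectors::mcols(gr)), c("name", "score"))
  if (length(extra)) {
    warning("ignoring BED columns beyond BED6: ",
            paste(extra, collapse = ", "))
    S4Vectors::mcols(gr) <-
      S4Vectors::mcols(gr)[intersect(c("name", "score"),
                                     colnames(S4Vectors::mcols(gr)))]
  }
  gr
}

#' @rdname read_bed
#' @param intervals A `GRanges`; `name` and `score` metadata columns are
#'   written when present.
#' @return `write_bed()`: invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(is(intervals, "GRanges"))
  rtracklayer::export(intervals, path, format = "bed")
  invisible(path)
}

#' Read a FASTA genome
#'
#' Sequences are uppercase-normalized and keyed by the first
#' whitespace-delimited header token. Only the alphabet `A`,`C`,`G`,`T`,`N`
#' is accepted; `N` marks positions excluded from CpG statistics.
#'
#' @param path FASTA file path.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      stop("non-ACGTN character in record '", nm[i], "' at position ", bad)
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @return `write_fasta()`: invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Keeps rows of type `"gene"` (all rows when no `type` attribute is
#' present); each row must carry a `gene_id` attribute and a definite
#' strand, from which the transcription start site (TSS) is derived: the
#' interval start on `+`, the interval end on `-`. Callers working from
#' transcript-level annotation should first collapse isoforms with
#' [collapse_gene_models()].
#'
#' @param path GTF file path.
#' @return `GRanges` with a `gene_id` column.
#' @export
read_gtf_genes <- function(path) {
  gr <- as(rtracklayer::import(path, format = "gtf"), "GRanges")
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  if (!"gene_id" %in% colnames(S4Vectors::mcols(gr)) ||
      anyNA(S4Vectors::mcols(gr)$gene_id))
    stop("GTF gene models require a 'gene_id' attribute")
  if (any(strand(gr) == "*"))
    stop("gene model without strand: TSS undefined")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["gene_id"]
  gr
}

#' @rdname read_gtf_genes
#' @param genes `GRanges` of gene models with `gene_id`.
#' @return `write_gtf_genes()`: invisibly, `path`.
#' @export
write_gtf_genes <- function(genes, path) {
  stopifnot(is(genes, "GRanges"))
  g <- genes
  S4Vectors::mcols(g) <-
    S4Vectors::DataFrame(source = "capmapr", type = "gene",
                         gene_id = S4Vectors::mcols(genes)$gene_id)
  rtracklayer::export(g, path, format = "gtf")
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param genes Stranded `GRanges` of gene models.
#' @return Width-1 `GRanges` at each gene's TSS.
#' @export
gene_tss <- function(genes) {
  if (any(strand(genes) == "*"))
    stop("gene model without strand: TSS undefined")
  GenomicRanges::resize(genes, width = 1, fix = "start")
}

#' Collapse transcript-level models to one interval per gene
#'
#' @param models Stranded `GRanges` with a `gene_id` column (e.g. one row
#'   per transcript).
#' @return `GRanges` with one spanning interval per `gene_id`.
#' @export
collapse_gene_models <- function(models) {
  ids <- S4Vectors::mcols(models)$gene_id
  if (is.null(ids)) stop("'models' must carry a gene_id column")
  sp <- split(models, ids)
  out <- unlist(range(sp), use.names = FALSE)
  S4Vectors::mcols(out)$gene_id <- names(sp)
  out
}
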