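#' Dinucleotide-aware transition matrix
#'
#' First-order Markov chain over A/C/G/T whose stationary base composition
#' hits the requested G+C content exactly while the C-to-G transition is
#' damped so the chain's CpG dinucleotide frequency equals
#' `oe * p(C) * p(G)` — i.e. the sequence realizes the requested CpG
#' observed/expected ratio. Closed form: with target composition
#' `pi = ((1-gc)/2, gc/2, gc/2, (1-gc)/2)`, set `P(G|C) = oe * pi_G`,
#' give every non-C row the common distribution `q` with
#' `q_G = (pi_G - pi_C P(G|C)) / (1 - pi_C)` and `q_a` proportional to
#' `pi_a` for the other bases, and scale the rest of the C row to
#' `(1 - P(G|C))`; `pi` is then exactly stationary.
#'
#' @param gc Target G+C fraction in (0, 1).
#' @param oe Target CpG observed/expected ratio (> 0).
#' @return 4x4 row-stochastic matrix with dimnames A/C/G/T, and the
#'   stationary distribution as attribute `stationary`.
#' @keywords internal
dinuc_transition <- function(gc, oe) {
  stopifnot(gc > 0, gc < 1, oe > 0)
  bases <- c("A", "C", "G", "T")
  pi <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), bases)
  g <- oe * pi[["G"]]
  q_g <- (pi[["G"]] - pi[["C"]] * g) / (1 - pi[["C"]])
  if (g >= 1 || q_g <= 0)
    stop(sprintf(
      "infeasible (gc, oe) combination: need oe < %.3g at gc = %g",
      min(1 / pi[["G"]], 1 / pi[["C"]]), gc))
  q <- pi * (1 - q_g) / (1 - pi[["G"]])
  q[["G"]] <- q_g
  trans <- matrix(rep(q, each = 4), 4, 4, dimnames = list(bases, bases))
  row_c <- q * (1 - g) / (1 - q_g)
  row_c[["G"]] <- g
  trans["C", ] <- row_c
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-12))
  attr(trans, "stationary") <- pi
  trans
}

# one Markov-generated sequence on the current RNG stream
markov_seq <- function(n, gc, oe) {
  trans <- dinuc_transition(gc, oe)
  pi <- attr(trans, "stationary")
  init <- sample.int(4, 1, prob = pi)
  idx <- markov_sample_cpp(n, trans, init)
  paste(c("A", "C", "G", "T")[idx], collapse = "")
}

#' Generate a CpG-depleted background genome
#'
#' Simulates the bulk mammalian genome: a first-order Markov base chain
#' with the requested G+C content and a damped C-to-G transition giving a
#' CpG o/e around the genome-average value of 0.21. Deterministic per
#' seed.
#'
#' @param length Sequence length in bp (>= 10000).
#' @param gc Target G+C fraction (default 0.40).
#' @param cpg_oe Target CpG observed/expected ratio (default 0.21).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param chrom Chromosome name for the single generated sequence.
#' @return Named character vector of length 1.
#' @export
gen_background_genome <- function(length, gc = 0.40, cpg_oe = 0.21,
                                  seed = NULL, chrom = "chr1") {
  stopifnot(length >= 10000)
  if (!is.null(seed)) set.seed(seed)
  setNames(markov_seq(length, gc, cpg_oe), chrom)
}

#' Generate non-overlapping gene models
#'
#' Places `n` stranded genes along one chromosome with at least `gap` bp
#' between consecutive genes (and before the first / after the last),
#' distributing the remaining slack uniformly at random. Used as the
#' annotation substrate for planting classified CGIs.
#'
#' @param seqlen Chromosome length in bp.
#' @param n Number of genes.
#' @param chrom Chromosome name.
#' @param length_range Min/max gene length in bp.
#' @param gap Minimum gap between genes in bp.
#' @param seed Optional integer seed.
#' @return Stranded `GRanges` with a `gene_id` column, sorted.
#' @export
gen_gene_models <- function(seqlen, n = 80, chrom = "chr1",
                            length_range = c(4000, 12000), gap = 4000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- round(runif(n, length_range[1], length_range[2]))
  slack <- seqlen - sum(lens) - gap * (n + 1)
  if (slack < 0)
    stop("genes do not fit: need ", sum(lens) + gap * (n + 1),
         " bp, have ", seqlen)
  extras <- slack * diff(c(0, sort(runif(n)), 1))
  cur <- 1
  starts <- integer(n)
  for (i in seq_len(n)) {
    cur <- cur + gap + extras[i]
    starts[i] <- round(cur)
    cur <- cur + lens[i]
  }
  gr <- GRanges(chrom, IRanges(starts, width = lens),
                strand = sample(c("+", "-"), n, replace = TRUE))
  S4Vectors::mcols(gr)$gene_id <- sprintf("gene_%03d", seq_len(n))
  gr
}

#' Plant CpG islands into a background genome
#'
#' Replaces `n` non-overlapping segments of the genome with Markov-
#' generated island sequence at elevated G+C (default 0.65) and a CpG o/e
#' drawn uniformly from `oe_range` — at the defaults this yields roughly
#' 1 CpG every 10-25 bp over ~1 kb, the composition signature of real
#' CGIs against a CpG-deficient bulk genome. Island placement respects the
#' requested positional class mix relative to the supplied gene models:
#' `ATSS` islands straddle a (distinct) gene's TSS, `Intragenic` islands
#' sit inside a gene body at least `margin` bp from both gene ends, and
#' `Intergenic` islands keep at least `margin` bp clear of every gene.
#' Islands keep `min_gap` bp between one another so that peak calling and
#' profile windows cannot run neighbouring islands together.
#'
#' @param genome Length-1 named character vector (background genome).
#' @param gene_models Stranded `GRanges` from [gen_gene_models()].
#' @param n Number of islands.
#' @param class_mix Named proportions for `ATSS`, `Intragenic`,
#'   `Intergenic`; must sum to 1.
#' @param oe_range Min/max island CpG o/e.
#' @param length_range Min/max island length in bp (~1 kb).
#' @param island_gc Island G+C fraction.
#' @param min_gap Minimum distance between islands in bp.
#' @param margin Clearance from gene boundaries/TSS in bp; keep it larger
#'   than the classification flank so planted classes are unambiguous.
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per island before giving up.
#' @return List with `genome` (modified sequence) and `truth`, a sorted
#'   `GRanges` with `cgi_id`, `class` and `target_oe` columns.
#' @export
plant_islands <- function(genome, gene_models, n = 100,
                          class_mix = c(ATSS = 0.48, Intragenic = 0.26,
                                        Intergenic = 0.26),
                          oe_range = c(0.4, 1.1),
                          length_range = c(800, 1200), island_gc = 0.65,
                          min_gap = 2000, margin = 300, seed = NULL,
                          max_tries = 200) {
  stopifnot(length(genome) == 1, !is.null(names(genome)),
            abs(sum(class_mix) - 1) < 1e-6,
            all(c("ATSS", "Intragenic", "Intergenic") %in%
                  names(class_mix)))
  if (!is.null(seed)) set.seed(seed)
  chrom <- names(genome)
  seqlen <- nchar(genome[[1]])
  if (n == 0)
    return(list(genome = genome,
                truth = GRanges(seqinfo = GenomeInfoDb::Seqinfo(chrom, seqlen))))
  counts <- class_counts(n, class_mix)
  tss <- gene_tss(gene_models)
  perm <- sample(seq_along(gene_models))
  if (counts[["ATSS"]] + counts[["Intragenic"]] > length(gene_models))
    stop("need at least ", counts[["ATSS"]] + counts[["Intragenic"]],
         " genes for the requested class mix, have ", length(gene_models))
  atss_genes <- perm[seq_len(counts[["ATSS"]])]
  intra_genes <- perm[counts[["ATSS"]] + seq_len(counts[["Intragenic"]])]

  placed <- IRanges()
  classes <- character(0)
  place <- function(cand, len) {
    # accept iff inside bounds and min_gap clear of accepted islands
    if (is.na(cand) || cand < 1 || cand + len - 1 > seqlen) return(FALSE)
    ir <- IRanges(cand, width = len)
    if (length(placed) &&
        any(IRanges::overlapsAny(ir + min_gap, placed))) return(FALSE)
    placed <<- c(placed, ir)
    TRUE
  }
  achieved <- function()
    sprintf("placed %d of %d islands (%s)", length(placed), n,
            paste(names(table(classes)), table(classes),
                  sep = "=", collapse = ", "))

  lens <- round(runif(n, length_range[1], length_range[2]))
  li <- 0L
  for (g in atss_genes) {
    li <- li + 1L
    t_pos <- start(tss)[g]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      d <- round(runif(1, 0.35, 0.65) * lens[li])
      if (place(t_pos - d, lens[li])) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place ATSS island: ", achieved())
    classes <- c(classes, "ATSS")
  }
  for (g in intra_genes) {
    li <- li + 1L
    lo <- start(gene_models)[g] + margin
    hi <- end(gene_models)[g] - margin - lens[li] + 1
    ok <- FALSE
    if (hi >= lo) {
      for (try in seq_len(max_tries)) {
        if (place(round(runif(1, lo, hi)), lens[li])) { ok <- TRUE; break }
      }
    }
    if (!ok) stop("cannot place intragenic island: ", achieved())
    classes <- c(classes, "Intragenic")
  }
  gene_zone <- IRanges::reduce(IRanges::ranges(gene_models) + margin)
  for (i in seq_len(counts[["Intergenic"]])) {
    li <- li + 1L
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- round(runif(1, 1 + margin, seqlen - margin - lens[li] + 1))
      ir <- IRanges(cand, width = lens[li])
      if (any(IRanges::overlapsAny(ir + margin, gene_zone))) next
      if (place(cand, lens[li])) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place intergenic island: ", achieved())
    classes <- c(classes, "Intergenic")
  }

  target_oe <- runif(n, oe_range[1], oe_range[2])
  seq <- genome[[1]]
  for (i in seq_len(n)) {
    island <- markov_seq(width(placed)[i], island_gc, target_oe[i])
    substr(seq, start(placed)[i], end(placed)[i]) <- island
  }
  truth <- GRanges(chrom, placed,
                   seqinfo = GenomeInfoDb::Seqinfo(chrom, seqlen))
  S4Vectors::mcols(truth)$class <-
    factor(classes, levels = c("ATSS", "Intragenic", "Intergenic"))
  S4Vectors::mcols(truth)$target_oe <- target_oe
  ord <- order(start(truth))
  truth <- truth[ord]
  S4Vectors::mcols(truth)$cgi_id <- sprintf("cgi_%03d", seq_len(n))
  names(truth) <- S4Vectors::mcols(truth)$cgi_id
  list(genome = setNames(seq, chrom), truth = truth)
}

class_counts <- function(n, mix) {
  mix <- mix[c("ATSS", "Intragenic", "Intergenic")]
  cnt <- floor(n * mix)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- n * mix - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  setNames(as.integer(cnt), names(mix))
}

#' Assign per-tissue methylation and promoter-activity states
#'
#' Independent Bernoulli methylation per (CGI, somatic tissue) with
#' class-specific rates; the germline tissue is always unmethylated (CGIs
#' are hypomethylated in sperm, which is what makes it the reference).
#' Default rates follow the observed somatic preference for orphan CGIs:
#' ~3% of promoter (ATSS) CGIs, ~24% intragenic, ~14% intergenic.
#' Promoter activity per tissue is Bernoulli(`activity_rate`) among
#' unmethylated CGIs; methylated CGIs are inactive.
#'
#' @param truth `GRanges` from [plant_islands()].
#' @param tissues Character vector of tissue names (must include
#'   `germline`).
#' @param germline Name of the hypomethylated reference tissue.
#' @param rates Named methylation rates per class, each in `[0, 1]`.
#' @param activity_rate Probability an unmethylated CGI is an active
#'   promoter in a given tissue.
#' @param meth_matrix Optional logical matrix (CGIs x tissues) overriding
#'   the Bernoulli draw, e.g. for X-inactivation or tumour-cohort designs;
#'   the germline column is still forced to `FALSE`.
#' @param seed Optional integer seed.
#' @return `truth` with logical columns `meth_<tissue>` and
#'   `active_<tissue>`.
#' @export
assign_methylation <- function(truth, tissues, germline = "sperm",
                               rates = c(ATSS = 0.03, Intragenic = 0.24,
                                         Intergenic = 0.14),
                               activity_rate = 0.7, meth_matrix = NULL,
                               seed = NULL) {
  stopifnot(germline %in% tissues, !anyDuplicated(tissues),
            all(rates >= 0 & rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth)
  cls <- as.character(S4Vectors::mcols(truth)$class)
  p <- unname(rates[cls])
  for (t in tissues) {
    meth <- if (!is.null(meth_matrix)) meth_matrix[, t]
            else runif(n) < p
    if (t == germline) meth <- rep(FALSE, n)
    active <- !meth & runif(n) < activity_rate
    S4Vectors::mcols(truth)[[paste0("meth_", t)]] <- meth
    S4Vectors::mcols(truth)[[paste0("active_", t)]] <- active
  }
  truth
}

#' Simulation parameters for one enrichment assay
#'
#' The simulator fragments the genome into `fragment_len` tiles, gives
#' each tile a retention probability from its CpG content and methylation
#' state, and draws per-base depth as
#' `Poisson(mean_depth * retention + background_depth)`:
#'
#' * `CAP`: retention is a logistic function of the tile's *unmethylated*
#'   CpG density, `plogis((density - cap_stringency_mid)/cap_slope)` in
#'   CpGs/100 bp. The midpoint abstracts the salt-wash stringency of the
#'   CXXC column: the high-stringency default (5.0) loses relatively
#'   CpG-poor islands that the low-stringency default (3.5) retains.
#'   Outside islands, 1 - `background_meth` of bulk CpGs count as
#'   unmethylated.
#' * `MAP`: full retention when the tile's methyl-CpG density reaches
#'   `map_min_density` (default 1 meCpG/100 bp); otherwise the small
#'   `map_bulk_retention` models diffuse recovery of the partially
#'   methylated bulk genome (the background the normalization step
#'   removes). Bulk CpGs are methylated at `background_meth` (default
#'   0.75, the canonical 70-80%).
#' * `H3K4me3`: retention `k4_gain *` tile CpG density counting only CpGs
#'   of unmethylated islands — signal a monotone (linear) function of CpG
#'   density at unmethylated CGIs, absent at methylated ones.
#' * `RNAPII`: retention 1 on fragments overlapping a CGI active in the
#'   simulated tissue, 0 elsewhere.
#'
#' @param assay One of `"CAP"`, `"MAP"`, `"H3K4me3"`, `"RNAPII"`.
#' @param fragment_len Fragment/tile length in bp.
#' @param mean_depth Mean depth (reads/bp) over fully retained fragments.
#' @param cap_stringency `"high"` or `"low"`, setting
#'   `cap_stringency_mid` to 5.0 or 3.5 unless given explicitly.
#' @param cap_stringency_mid Logistic midpoint in CpGs/100 bp.
#' @param cap_slope Logistic steepness in CpGs/100 bp.
#' @param map_min_density Methyl-CpG density (per 100 bp) for full MAP
#'   retention.
#' @param map_bulk_retention MAP retention of sub-threshold bulk genome.
#' @param k4_gain H3K4me3 retention per unit CpG density.
#' @param background_depth Off-target depth (reads/bp) added everywhere.
#' @param background_meth Methylated fraction of bulk-genome CpGs.
#' @return An object of class `AssayParams`.
#' @export
assay_params <- function(assay = c("CAP", "MAP", "H3K4me3", "RNAPII"),
                         fragment_len = 200, mean_depth = 5,
                         cap_stringency = c("high", "low"),
                         cap_stringency_mid = NULL, cap_slope = 0.5,
                         map_min_density = 1.0, map_bulk_retention = 0.05,
                         k4_gain = 0.1, background_depth = 0.2,
                         background_meth = 0.75) {
  assay <- match.arg(assay)
  cap_stringency <- match.arg(cap_stringency)
  if (is.null(cap_stringency_mid))
    cap_stringency_mid <- if (cap_stringency == "high") 5.0 else 3.5
  stopifnot(fragment_len >= 1, mean_depth >= 0, cap_slope > 0,
            map_min_density >= 0, map_bulk_retention >= 0,
            map_bulk_retention <= 1, k4_gain >= 0, background_depth >= 0,
            background_meth >= 0, background_meth <= 1)
  structure(list(assay = assay, fragment_len = as.integer(fragment_len),
                 mean_depth = mean_depth,
                 cap_stringency = cap_stringency,
                 cap_stringency_mid = cap_stringency_mid,
                 cap_slope = cap_slope, map_min_density = map_min_density,
                 map_bulk_retention = map_bulk_retention,
                 k4_gain = k4_gain, background_depth = background_depth,
                 background_meth = background_meth),
            class = "AssayParams")
}

#' @export
print.AssayParams <- function(x, ...) {
  cat(sprintf("AssayParams: %s, %d bp fragments, mean depth %g/bp\n",
              x$assay, x$fragment_len, x$mean_depth))
  invisible(x)
}

# per-base Poisson rate for one assay/tissue; returns numeric vector
assay_rate <- function(genome, truth, params, tissue) {
  ch <- names(genome)
  s <- seq_chars(genome[[1]])
  n <- length(s)
  fl <- params$fragment_len
  n_tiles <- ceiling(n / fl)
  tile_len <- rep(fl, n_tiles)
  tile_len[n_tiles] <- n - fl * (n_tiles - 1L)
  cg <- which(s[-n] == "C" & s[-1] == "G")
  # island membership and methylation state per CpG
  in_island <- rep(FALSE, length(cg))
  meth <- rep(FALSE, length(cg))
  if (length(truth)) {
    mcol <- paste0("meth_", tissue)
    meth_state <- S4Vectors::mcols(truth)[[mcol]]
    if (is.null(meth_state))
      stop("truth has no methylation state for tissue ", tissue,
           "; run assign_methylation() first")
    idx <- findInterval(cg, start(truth))
    hit <- idx > 0 & cg <= end(truth)[pmax(idx, 1)]
    in_island[hit] <- TRUE
    meth[hit] <- meth_state[idx[hit]]
  }
  tile_of <- (cg - 1L) %/% fl + 1L
  tile_density <- function(w) {
    cnt <- numeric(n_tiles)
    if (length(w)) {
      agg <- rowsum(w, tile_of)
      cnt[as.integer(rownames(agg))] <- agg[, 1]
    }
    100 * cnt / tile_len
  }
  retention <- switch(params$assay,
    CAP = {
      w <- ifelse(in_island, ifelse(meth, 0, 1), 1 - params$background_meth)
      plogis((tile_density(w) - params$cap_stringency_mid) /
               params$cap_slope)
    },
    MAP = {
      w <- ifelse(in_island, ifelse(meth, 1, 0), params$background_meth)
      ifelse(tile_density(w) >= params$map_min_density, 1,
             params$map_bulk_retention)
    },
    H3K4me3 = {
      w <- as.numeric(in_island & !meth)
      params$k4_gain * tile_density(w)
    },
    RNAPII = {
      acol <- paste0("active_", tissue)
      act <- S4Vectors::mcols(truth)[[acol]]
      if (is.null(act))
        stop("truth has no activity state for tissue ", tissue)
      ret <- numeric(n_tiles)
      for (i in which(act)) {
        t1 <- (start(truth)[i] - 1L) %/% fl + 1L
        t2 <- (end(truth)[i] - 1L) %/% fl + 1L
        ret[t1:t2] <- 1
      }
      ret
    })
  rate <- rep(params$mean_depth * retention, times = tile_len) +
    params$background_depth
  setNames(list(rate), ch)
}

#' Simulate an enrichment depth track
#'
#' Draws per-base depth as Poisson noise around the assay's retention
#' model (see [assay_params()]) for one tissue. Deterministic per seed.
#'
#' @param genome Length-1 named character vector.
#' @param truth `GRanges` from [assign_methylation()].
#' @param params An [assay_params()].
#' @param tissue Tissue whose methylation/activity state drives the
#'   signal.
#' @param seed Optional integer seed.
#' @return A [depth_track()].
#' @export
simulate_track <- function(genome, truth, params, tissue, seed = NULL) {
  stopifnot(is(params, "AssayParams"))
  if (!is.null(seed)) set.seed(seed)
  rate <- assay_rate(genome, truth, params, tissue)
  depth_track(lapply(rate, function(l) rpois(length(l), l)))
}

#' Coupled high/low-stringency CAP simulation
#'
#' Simulates the same CAP library washed at two stringencies: the
#' low-stringency track is drawn as the high-stringency track plus
#' independent Poisson extra signal (`low = high + Poisson(rate_low -
#' rate_high)`), the superposition coupling implied by a gentler wash
#' retaining a superset of the fragments. Per-base depth is therefore
#' pointwise no smaller at low stringency, and peak coverage is nested —
#' the additional islands that only appear at low stringency are the
#' relatively CpG-poor ones.
#'
#' @param genome,truth,tissue,seed As in [simulate_track()].
#' @param params_high,params_low CAP [assay_params()] differing in
#'   `cap_stringency_mid` (`low` must have the lower midpoint).
#' @return List of two [depth_track()]s: `high`, `low`.
#' @export
simulate_cap_stringency_pair <- function(genome, truth, tissue,
                                         params_high =
                                           assay_params("CAP", cap_stringency = "high"),
                                         params_low =
                                           assay_params("CAP", cap_stringency = "low"),
                                         seed = NULL) {
  stopifnot(params_high$assay == "CAP", params_low$assay == "CAP")
  if (params_low$cap_stringency_mid >= params_high$cap_stringency_mid)
    stop("'params_low' must have the lower stringency midpoint")
  if (!is.null(seed)) set.seed(seed)
  rate_h <- assay_rate(genome, truth, params_high, tissue)
  rate_l <- assay_rate(genome, truth, params_low, tissue)
  high <- lapply(rate_h, function(l) rpois(length(l), l))
  extra <- mapply(function(lh, ll) rpois(length(lh), pmax(ll - lh, 0)),
                  rate_h, rate_l, SIMPLIFY = FALSE)
  low <- mapply(`+`, high, extra, SIMPLIFY = FALSE)
  list(high = depth_track(high), low = depth_track(low))
}
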