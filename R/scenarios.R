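#' Built-in simulation scenarios
#'
#' A scenario bundles every generator setting — genome size and
#' composition, gene models, island count, class mix, per-class somatic
#' methylation rates, assay parameters — into one object that
#' [simulate_scenario()] turns into data with ground truth.
#'
#' * `scenario_default()`: one 2 Mb chromosome, 80 genes, 100 planted
#'   islands (class mix 48/26/26), three tissues (sperm germline, blood,
#'   cerebellum), somatic methylation rates ATSS 3% / intragenic 24% /
#'   intergenic 14%, mean assay depth 5 reads/bp. The workhorse fixture
#'   for island recovery, differential methylation and profile summaries.
#' * `scenario_two_species()`: two independent genomes whose island o/e
#'   distributions are shifted ("human-like" higher, "mouse-like" lower)
#'   plus an ortholog pairing table; methylation of an ortholog is copied
#'   between species with probability `conserve`.
#' * `scenario_xinactivation()`: one X-like chromosome where a block of
#'   islands is methylated in the `female` sample only; the calibration
#'   design for the differential-methylation caller.
#' * `scenario_tumour()`: matched cohort of 5 normal and 5 tumour MAP
#'   samples; a planted tumour-specific island set (methylated in 3-5
#'   tumours, no normals), a shared set (methylated everywhere somatic),
#'   and polycomb (H3K27me3) flags enriched on the tumour-specific set.
#'
#' Any field can be overridden via `...` (e.g. a smaller `genome_length`
#' for quick tests).
#'
#' @param ... Named overrides of scenario fields.
#' @return An object of class `cgi_scenario`.
#' @export
scenario_default <- function(...) {
  sc <- list(
    name = "default", chrom = "chr1",
    genome_length = 2e6, gc = 0.40, background_oe = 0.21,
    n_genes = 80, gene_length = c(4000, 12000), gene_gap = 4000,
    n_islands = 100, island_gc = 0.65, oe_range = c(0.4, 1.1),
    island_length = c(800, 1200), min_gap = 2000, margin = 300,
    class_mix = c(ATSS = 0.48, Intragenic = 0.26, Intergenic = 0.26),
    tissues = c("sperm", "blood", "cerebellum"), germline = "sperm",
    rates = c(ATSS = 0.03, Intragenic = 0.24, Intergenic = 0.14),
    activity_rate = 0.7,
    mean_depth = 5, fragment_len = 200, background_depth = 0.2)
  scenario_override(sc, ...)
}

#' @rdname scenario_default
#' @export
scenario_two_species <- function(...) {
  sc <- scenario_override(scenario_default(), name = "two_species",
                          genome_length = 8e5, n_genes = 40,
                          n_islands = 50)
  sc$oe_range_a <- c(0.6, 1.2)   # human-like, denser islands
  sc$oe_range_b <- c(0.35, 1.0)  # mouse-like, CpG-poorer islands
  sc$conserve <- 0.8
  scenario_override(sc, ...)
}

#' @rdname scenario_default
#' @export
scenario_xinactivation <- function(...) {
  sc <- scenario_override(scenario_default(), name = "xinactivation",
                          chrom = "chrX", genome_length = 8e5,
                          n_genes = 32, n_islands = 40,
                          tissues = c("sperm", "female", "male"))
  sc$n_female_meth <- 15
  scenario_override(sc, ...)
}

#' @rdname scenario_default
#' @export
scenario_tumour <- function(...) {
  sc <- scenario_override(scenario_default(), name = "tumour",
                          genome_length = 1e6, n_genes = 50,
                          n_islands = 60,
                          tissues = c("sperm", paste0("C", 1:5),
                                      paste0("T", 1:5)))
  sc$n_tumour_specific <- 10
  sc$n_shared <- 8
  sc$min_tumour_meth <- 3
  sc$k27_rate_tumour_specific <- 0.7
  sc$k27_rate_background <- 0.1
  scenario_override(sc, ...)
}

scenario_override <- function(sc, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(sc), "name"))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  sc[names(dots)] <- dots
  structure(sc, class = "cgi_scenario")
}

#' @export
print.cgi_scenario <- function(x, ...) {
  cat(sprintf("cgi_scenario '%s': %g bp, %d genes, %d islands, tissues: %s\n",
              x$name, x$genome_length, x$n_genes, x$n_islands,
              paste(x$tissues, collapse = ", ")))
  invisible(x)
}

# genome + genes + classified, methylated truth for one chromosome
simulate_substrate <- function(sc, oe_range = sc$oe_range) {
  genome <- gen_background_genome(sc$genome_length, gc = sc$gc,
                                  cpg_oe = sc$background_oe,
                                  chrom = sc$chrom)
  genes <- gen_gene_models(sc$genome_length, n = sc$n_genes,
                           chrom = sc$chrom,
                           length_range = sc$gene_length,
                           gap = sc$gene_gap)
  pl <- plant_islands(genome, genes, n = sc$n_islands,
                      class_mix = sc$class_mix, oe_range = oe_range,
                      length_range = sc$island_length,
                      island_gc = sc$island_gc, min_gap = sc$min_gap,
                      margin = sc$margin)
  list(genome = pl$genome, genes = genes, truth = pl$truth)
}

#' Run a simulation scenario
#'
#' Generates the scenario's genome(s), gene models, classified ground
#' truth with methylation states, and the requested assay depth tracks.
#' One integer seed governs every random draw, so identical calls are
#' byte-identical.
#'
#' @param scenario A `cgi_scenario` (see [scenario_default()]).
#' @param seed Integer seed.
#' @param assays Assays to simulate tracks for; `NULL` picks a sensible
#'   set per scenario (CAP+MAP for `default`, MAP for `xinactivation` and
#'   `tumour`, CAP for `two_species`).
#' @return A list with `scenario`, `genome`, `genes`, `truth` and
#'   `tracks` (a list `tracks[[assay]][[tissue]]`); the two-species
#'   scenario returns `species_a`, `species_b` (each such a list) and
#'   `ortholog_pairs`.
#' @export
simulate_scenario <- function(scenario, seed,
                              assays = NULL) {
  stopifnot(is(scenario, "cgi_scenario"))
  set.seed(seed)
  sc <- scenario
  if (sc$name == "two_species") {
    if (is.null(assays)) assays <- "CAP"
    a <- simulate_substrate(sc, oe_range = sc$oe_range_a)
    b <- simulate_substrate(sc, oe_range = sc$oe_range_b)
    a$truth <- assign_methylation(a$truth, sc$tissues, sc$germline,
                                  rates = sc$rates,
                                  activity_rate = sc$activity_rate)
    # orthologs: pair islands by id; copy methylation with prob conserve
    bm <- as.matrix(S4Vectors::mcols(a$truth)[paste0("meth_", sc$tissues)])
    flip <- matrix(runif(length(bm)) > sc$conserve, nrow = nrow(bm))
    bm <- ifelse(flip, !bm, bm)
    bm[, match(paste0("meth_", sc$germline), colnames(bm))] <- FALSE
    colnames(bm) <- sc$tissues
    b$truth <- assign_methylation(b$truth, sc$tissues, sc$germline,
                                  meth_matrix = bm,
                                  activity_rate = sc$activity_rate)
    pairs <- data.frame(a = cgi_ids(a$truth), b = cgi_ids(b$truth))
    a$tracks <- scenario_tracks(a, sc, assays)
    b$tracks <- scenario_tracks(b, sc, assays)
    return(list(scenario = sc, species_a = a, species_b = b,
                ortholog_pairs = pairs, seed = seed))
  }
  sub <- simulate_substrate(sc)
  n <- length(sub$truth)
  if (sc$name == "xinactivation") {
    if (is.null(assays)) assays <- "MAP"
    mm <- matrix(FALSE, n, length(sc$tissues),
                 dimnames = list(NULL, sc$tissues))
    mm[sample.int(n, sc$n_female_meth), "female"] <- TRUE
    sub$truth <- assign_methylation(sub$truth, sc$tissues, sc$germline,
                                    meth_matrix = mm,
                                    activity_rate = sc$activity_rate)
  } else if (sc$name == "tumour") {
    if (is.null(assays)) assays <- "MAP"
    tumours <- grep("^T", sc$tissues, value = TRUE)
    normals <- grep("^C", sc$tissues, value = TRUE)
    mm <- matrix(FALSE, n, length(sc$tissues),
                 dimnames = list(NULL, sc$tissues))
    pick <- sample.int(n, sc$n_tumour_specific + sc$n_shared)
    ts <- pick[seq_len(sc$n_tumour_specific)]
    sh <- pick[-seq_len(sc$n_tumour_specific)]
    for (i in ts) {
      k <- sample(sc$min_tumour_meth:length(tumours), 1)
      mm[i, sample(tumours, k)] <- TRUE
    }
    mm[sh, c(tumours, normals)] <- TRUE
    sub$truth <- assign_methylation(sub$truth, sc$tissues, sc$germline,
                                    meth_matrix = mm,
                                    activity_rate = sc$activity_rate)
    S4Vectors::mcols(sub$truth)$tumour_specific <-
      seq_len(n) %in% ts
    S4Vectors::mcols(sub$truth)$shared_meth <- seq_len(n) %in% sh
    S4Vectors::mcols(sub$truth)$k27 <-
      runif(n) < ifelse(seq_len(n) %in% ts,
                        sc$k27_rate_tumour_specific,
                        sc$k27_rate_background)
  } else {
    if (is.null(assays)) assays <- c("CAP", "MAP")
    sub$truth <- assign_methylation(sub$truth, sc$tissues, sc$germline,
                                    rates = sc$rates,
                                    activity_rate = sc$activity_rate)
  }
  sub$tracks <- scenario_tracks(sub, sc, assays)
  c(list(scenario = sc), sub, list(seed = seed))
}

scenario_tracks <- function(sub, sc, assays) {
  out <- list()
  for (a in assays) {
    pars <- assay_params(a, fragment_len = sc$fragment_len,
                         mean_depth = sc$mean_depth,
                         cap_stringency = "low",
                         background_depth = sc$background_depth)
    out[[a]] <- lapply(setNames(nm = sc$tissues), function(t)
      simulate_track(sub$genome, sub$truth, pars, t))
  }
  out
}

#' Write a scenario to disk as a fixture bundle
#'
#' Materializes one scenario as plain-text files: genome FASTA, gene
#' models GTF, ground-truth TSV (1-based closed coordinates), one WIG per
#' assay and tissue, and a manifest with the seed, the scenario
#' parameters (JSON) and an md5 checksum per file. Re-running with the
#' same scenario and seed reproduces identical checksums.
#'
#' @param outdir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param scenario A `cgi_scenario`.
#' @param seed Integer seed.
#' @param assays Passed to [simulate_scenario()].
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the manifest data.frame.
#' @export
write_fixture_bundle <- function(outdir, scenario = scenario_default(),
                                 seed = 1, assays = NULL, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory is not empty: ", outdir,
         " (use force = TRUE to overwrite)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scenario(scenario, seed, assays = assays)
  subs <- if (scenario$name == "two_species")
    list(species_a = sim$species_a, species_b = sim$species_b)
  else list(. = sim)
  files <- character(0)
  for (nm in names(subs)) {
    sub <- subs[[nm]]
    pre <- if (nm == ".") "" else paste0(nm, "_")
    f <- file.path(outdir, paste0(pre, "genome.fa"))
    write_fasta(sub$genome, f); files <- c(files, f)
    f <- file.path(outdir, paste0(pre, "genes.gtf"))
    write_gtf_genes(sub$genes, f); files <- c(files, f)
    f <- file.path(outdir, paste0(pre, "truth.tsv"))
    df <- as.data.frame(sub$truth)
    names(df)[1] <- "chrom"
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    for (a in names(sub$tracks)) {
      for (t in names(sub$tracks[[a]])) {
        f <- file.path(outdir, paste0(pre, a, "_", t, ".wig"))
        write_wig(sub$tracks[[a]][[t]], f,
                  name = paste0(pre, a, "_", t))
        files <- c(files, f)
      }
    }
  }
  if (scenario$name == "two_species") {
    f <- file.path(outdir, "ortholog_pairs.tsv")
    utils::write.table(sim$ortholog_pairs, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- file.path(outdir, "scenario.json")
  jsonlite::write_json(c(list(seed = seed), unclass(scenario)), cfg,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = unname(file.size(files)))
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
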