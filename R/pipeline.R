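#' Write a synthetic input bundle to disk
#'
#' Materializes every format the pipeline reads: one dense segmentation
#' BED per condition, a peak table with differential statistics, a gene
#' table, the TF-activity matrices, the network tables and a
#' `truth.json` manifest of the planted signal.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param seed RNG seed; stage seeds are derived from it.
#' @return named list of written file paths, invisibly; the simulated
#'   objects are attached as attribute `"objects"`.
#' @export
write_synthetic_bundle <- function(cfg, dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- simulate_state_tracks(cfg, seed)
  genes <- simulate_genes(cfg, tracks, seed + 1L)
  peaks <- simulate_peaks(cfg, tracks, seed + 2L, mode = "statistics")
  tf <- simulate_tf_inputs(cfg, seed + 3L)
  nw <- simulate_network_inputs(cfg, seed + 4L)

  paths <- list(
    segmentation_a = file.path(dir, paste0("segmentation_",
                                           cfg$conditions[1], ".bed")),
    segmentation_b = file.path(dir, paste0("segmentation_",
                                           cfg$conditions[2], ".bed")),
    peaks = file.path(dir, "peaks.tsv"),
    genes = file.path(dir, "genes.tsv"),
    motif_z = file.path(dir, "motif_z.tsv"),
    fp_padj = file.path(dir, "fp_padj.tsv"),
    tf_tpm = file.path(dir, "tf_tpm.tsv"),
    motif_tf = file.path(dir, "motif_tf.tsv"),
    edges = file.path(dir, "network_edges.tsv"),
    truth = file.path(dir, "truth.json"))

  write_segmentation(tracks$track_a, paths$segmentation_a)
  write_segmentation(tracks$track_b, paths$segmentation_b)
  pk <- data.frame(chrom = peaks$chrom, start = peaks$start,
                   end = peaks$end,
                   summit_offset = peaks$summit - peaks$start,
                   log2fc = peaks$log2fc, fdr = peaks$fdr,
                   called_A1 = as.integer(peaks$called_A1),
                   called_A2 = as.integer(peaks$called_A2),
                   called_B1 = as.integer(peaks$called_B1),
                   called_B2 = as.integer(peaks$called_B2))
  write_tsv <- function(x, path, row_names = FALSE) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = row_names, col.names = TRUE)
  }
  write_tsv(pk, paths$peaks)
  write_tsv(genes, paths$genes)
  write_tsv(tf$input$motif_z, paths$motif_z, row_names = TRUE)
  write_tsv(tf$input$fp_padj, paths$fp_padj, row_names = TRUE)
  write_tsv(tf$input$tpm, paths$tf_tpm, row_names = TRUE)
  write_tsv(cbind(tf$input$motif_tf,
                  de_any = tf$input$de_any[tf$input$motif_tf$tf]),
            paths$motif_tf)
  write_tsv(nw$edges, paths$edges)
  truth <- list(joint_weights = tracks$truth,
                active_tfs = tf$truth,
                network_edges = nw$truth$edges,
                direct_targets = nw$truth$direct_targets)
  jsonlite::write_json(truth, paths$truth, digits = NA, pretty = TRUE)
  out <- paths
  attr(out, "objects") <- list(tracks = tracks, genes = genes,
                               peaks = peaks, tf = tf, network = nw)
  invisible(out)
}

#' Pipeline configuration
#'
#' Collects the seed, output directory and every analysis threshold.
#' Defaults equal the printed values of the underlying procedures;
#' overrides are recorded in the run manifest.
#'
#' @param outdir output directory.
#' @param seed integer seed driving every stochastic stage.
#' @param sim a [simulation_config()] describing the synthetic inputs.
#' @param n_perm shuffles for the transition null (default 1000).
#' @param fdr_max,lfc_min peak classification thresholds (0.01, 1).
#' @param max_dist nearest-gene cutoff in bp (50000).
#' @param min_tpm expression cutoff for nearest genes (1).
#' @param ratio_min,alpha association classification thresholds
#'   (1.2, 0.05).
#' @param z_abs,fp_alpha,tpm_min,r_min TF-activity thresholds
#'   (2, 0.001, 5, 0.5).
#' @param score_min,dist_network,dist_display network thresholds
#'   (0.7, 50000, 25000).
#' @param mask_fe,mask_bins display-mask thresholds (1.5, 200).
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            sim = simulation_config(),
                            n_perm = 1000L,
                            fdr_max = 0.01, lfc_min = 1,
                            max_dist = 50000, min_tpm = 1,
                            ratio_min = 1.2, alpha = 0.05,
                            z_abs = 2, fp_alpha = 0.001, tpm_min = 5,
                            r_min = 0.5,
                            score_min = 0.7, dist_network = 50000,
                            dist_display = 25000,
                            mask_fe = 1.5, mask_bins = 200) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("threshold '", nm, "' must be a single number")
    x
  }
  for (nm in c("n_perm", "fdr_max", "lfc_min", "max_dist", "min_tpm",
               "ratio_min", "alpha", "z_abs", "fp_alpha", "tpm_min",
               "r_min", "score_min", "dist_network", "dist_display",
               "mask_fe", "mask_bins"))
    num1(get(nm), nm)
  stopifnot(inherits(sim, "sim_config"))
  structure(as.list(environment())[c(
    "outdir", "seed", "sim", "n_perm", "fdr_max", "lfc_min",
    "max_dist", "min_tpm", "ratio_min", "alpha", "z_abs", "fp_alpha",
    "tpm_min", "r_min", "score_min", "dist_network", "dist_display",
    "mask_fe", "mask_bins")],
    class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping of [pipeline_config()] arguments (plus optional
#' `sim:` overrides for [simulation_config()]); unknown keys are an
#' error naming the key.
#'
#' @param path YAML file.
#' @param outdir,seed optional overrides of the file values.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  known <- setdiff(names(formals(pipeline_config)), "sim")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(simulation_config)))
    if (length(bad))
      stop("unknown sim key(s): ", paste(bad, collapse = ", "))
    if (!is.null(sim_args$chrom_sizes))
      sim_args$chrom_sizes <- unlist(sim_args$chrom_sizes)
    y$sim <- do.call(simulation_config, sim_args)
  }
  if (!is.null(outdir)) y$outdir <- outdir
  if (!is.null(seed)) y$seed <- seed
  do.call(pipeline_config, y)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in dependency order: input simulation and
#' serialization, segmentation re-reading, transition counting with the
#' permutation null and fold enrichment, gene- and peak-mode transition
#' association, integrated TF-activity selection, and network assembly.
#' All results are written as TSV (plus GraphML for the network) under
#' `outdir`, together with a JSON manifest recording the package
#' version, seed, thresholds and input checksums. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] or the path to a YAML file.
#' @param stages character vector of stages to run (default all):
#'   subset of `simulate`, `transitions`, `associate`, `tf_activity`,
#'   `network`.
#' @return named list of result objects, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "transitions",
                                    "associate", "tf_activity",
                                    "network")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  indir <- file.path(outdir, "inputs")
  message("simulating inputs -> ", indir)
  paths <- write_synthetic_bundle(config$sim, indir, config$seed)
  obj <- attr(paths, "objects")
  results <- list(inputs = paths)
  write_tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  grid <- genome_grid(config$sim$chrom_sizes, config$sim$bin_size)
  track_a <- read_segmentation(paths$segmentation_a, grid,
                               condition = config$sim$conditions[1],
                               alphabet = config$sim$states)
  track_b <- read_segmentation(paths$segmentation_b, grid,
                               condition = config$sim$conditions[2],
                               alphabet = config$sim$states)
  peaks <- read_peaks(paths$peaks)
  peaks$klass <- classify_dars(peaks, fdr_max = config$fdr_max,
                               lfc_min = config$lfc_min)
  peaks$bin <- assign_peak_bins(peaks, grid)
  genes <- read_genes(paths$genes)

  if ("transitions" %in% stages) {
    message("transition enrichment (", config$n_perm, " shuffles)")
    counts <- count_transitions(track_a, track_b)
    E <- expected_counts(track_a, track_b, method = "permutation",
                         n_perm = config$n_perm,
                         seed = config$seed + 10L)
    enr <- fold_enrichment(counts, E)
    tab <- transition_table(enr, min_fe = config$mask_fe,
                            min_bins = config$mask_bins)
    write_tsv(tab, "transitions.tsv")
    results$transitions <- enr
  }
  if ("associate" %in% stages) {
    message("transition association (genes, peaks)")
    ag <- associate_genes(track_a, track_b, genes,
                          contrast = config$sim$contrast,
                          conditions = config$sim$conditions,
                          max_dist = config$max_dist,
                          min_tpm = config$min_tpm,
                          ratio_min = config$ratio_min,
                          alpha = config$alpha)
    write_tsv(ag, "association_genes.tsv")
    ap <- associate_peaks(track_a, track_b, peaks,
                          ratio_min = config$ratio_min,
                          alpha = config$alpha)
    write_tsv(ap, "association_peaks.tsv")
    strat <- stratify_peaks_by_state(peaks, track_a, track_b)
    write_tsv(strat$groups, "peak_state_groups.tsv")
    results$association_genes <- ag
    results$association_peaks <- ap
  }
  if ("tf_activity" %in% stages) {
    message("TF activity integration")
    act <- select_active_motifs(obj$tf$input, z_abs = config$z_abs,
                                fp_alpha = config$fp_alpha,
                                tpm_min = config$tpm_min,
                                r_min = config$r_min)
    write_tsv(act, "tf_activity.tsv")
    results$tf_activity <- act
  }
  if ("network" %in% stages) {
    message("TF network assembly")
    nw <- obj$network
    med <- mediating_peak_distances(nw$footprints, nw$gain_peaks,
                                    nw$tf_genes)
    net <- build_network(nw$edges, nw$tpm, nw$criteria, med,
                         score_min = config$score_min,
                         tpm_min = config$tpm_min,
                         dist_network = config$dist_network,
                         dist_display = config$dist_display)
    direct <- identify_direct_targets(nw$rara_peaks, nw$tf_genes,
                                      config$sim$contrast)
    up_col <- nw$tf_genes[[paste0("de_", config$sim$contrast)]]
    cat_ <- categorize_ra_response(
      net$nodes, direct, nw$tf_genes$gene_id[up_col == "up"])
    write_tsv(net$edges, "network_edges.tsv")
    node_attrs <- data.frame(tf = names(cat_),
                             ra_category = as.character(cat_))
    write_tsv(node_attrs, "network_nodes.tsv")
    write_network_graphml(net, file.path(outdir, "network.graphml"),
                          node_attrs = node_attrs)
    results$network <- net
    results$direct_targets <- direct
  }

  thresholds <- config[setdiff(names(config), c("outdir", "sim"))]
  manifest <- list(
    package = "chromtransit",
    version = as.character(utils::packageVersion("chromtransit")),
    seed = config$seed,
    thresholds = thresholds,
    stages = stages,
    input_md5 = stats::setNames(as.list(unname(
      tools::md5sum(unlist(paths)))), names(paths)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
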