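#' Default pipeline configuration
#'
#' All tunables of the full pipeline with their defaults: outlier threshold 5
#' (modified z-score), flatness level 0.05, Spearman level 0.05, screening
#' threshold I_C >= 6 and network threshold I_C >= 7, top fractions 0.10
#' (interaction lists) and 0.25 (phosphopeptide lists), clustering with
#' k = 13 under both methods, one null simulation per mode, bin depth 2.
#' Every defaulted value is recorded in the run manifest.
#'
#' @param ... Named overrides of default entries; unknown names are rejected.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    measurements = NULL,       # path to measurement TSV/CSV (or NULL)
    annotation = NULL,         # path to bin annotation TSV/CSV (or NULL)
    log2_input = FALSE,        # TRUE when the input is raw-scale
    outlier_threshold = 5,
    alpha_flat = 0.05,
    spearman_alpha = 0.05,
    ic_screen = 6,
    ic_network = 7,
    top_fraction_interactions = 0.10,
    top_fraction_molecules = 0.25,
    cluster_k = 13L,
    cluster_methods = c("kmeans", "hierarchical"),
    simulation_modes = c("randomize_metabolites",
                         "randomize_phosphopeptides", "randomize_both"),
    simulation_reps = 1L,
    bin_depth = 2,
    seed = 1L,
    out_dir = "concordr_out"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, overrides)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override the defaults of [default_config()]; unknown
#' keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_config, parsed)
}

#' Run the full analysis pipeline
#'
#' preprocess -> concordance -> null simulation -> enrichment -> clustering
#' -> network, per genotype where applicable. Writes every module's output
#' table plus a JSON run manifest (configuration, seed, package version,
#' input row counts) into `config$out_dir`. Given identical configuration
#' and inputs the run is deterministic.
#'
#' @param config [default_config()] list.
#' @param data Optional long measurement tibble (otherwise read from
#'   `config$measurements`).
#' @param annotation Optional annotation tibble (otherwise read from
#'   `config$annotation`; otherwise bins default to `"unknown"`).
#' @return Invisible list with the main in-memory results (`summaries`,
#'   `pairs`, `connections`, `edges`, `fpr`, `assignments`, `d_gt`,
#'   `network`).
#' @export
run_pipeline <- function(config = default_config(), data = NULL,
                         annotation = NULL) {
  t0 <- Sys.time()
  if (is.null(data)) {
    if (is.null(config$measurements)) {
      stop("no measurement input: set config$measurements or pass `data`",
           call. = FALSE)
    }
    data <- read_measurements(config$measurements)
  }
  if (is.null(annotation) && !is.null(config$annotation)) {
    annotation <- read_annotation(config$annotation)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] %s: %d rows in, %d rows out", stage,
                    format(Sys.time(), "%H:%M:%S"), n_in, n_out))
  }

  # -- preprocessing ---------------------------------------------------------
  if (isTRUE(config$log2_input)) data <- log2_transform(data)
  data <- mask_outliers(data, threshold = config$outlier_threshold)
  summaries <- summarize_conditions(data, alpha_flat = config$alpha_flat)
  write_table(summaries, file.path(config$out_dir, "summaries.tsv"))
  log_stage("preprocess", nrow(data), nrow(summaries))

  genotypes <- unique(summaries$genotype)
  pairs <- list()
  fpr <- list()
  scores <- list()
  for (gt in genotypes) {
    # -- concordance ---------------------------------------------------------
    pt <- concordance_table(data, summaries, genotype = gt)
    pairs[[gt]] <- pt
    log_stage(paste0("concordance/", gt), nrow(summaries), nrow(pt))

    # -- null simulation -----------------------------------------------------
    dgt <- data[data$genotype == gt, , drop = FALSE]
    sgt <- summaries[summaries$genotype == gt, , drop = FALSE]
    for (mode in config$simulation_modes) {
      for (rep_i in seq_len(config$simulation_reps)) {
        sim_seed <- config$seed + 1000L * match(mode,
                                                config$simulation_modes) +
          rep_i
        sim <- simulate_dataset(dgt, sgt, mode = mode, seed = sim_seed)
        sim_sum <- summarize_conditions(sim$data,
                                        alpha_flat = config$alpha_flat)
        sim_pt <- concordance_table(sim$data, sim_sum, genotype = gt)
        for (ms in c("ic", "rho")) {
          fc <- fpr_curve(pt, sim_pt, measure = ms)
          fc$genotype <- gt
          fc$mode <- mode
          fc$rep <- rep_i
          fpr[[paste(gt, mode, rep_i, ms)]] <- fc
        }
        log_stage(paste0("nullsim/", gt, "/", mode), nrow(dgt), nrow(sim_pt))
      }
    }

    # -- enrichment ----------------------------------------------------------
    if (!is.null(annotation)) {
      labels <- rank_lists(pt, "ic", "descending", entity = "bin",
                           annotation = annotation,
                           bin_depth = config$bin_depth)
      ents <- unique(labels)
      xk <- vapply(ents, function(e) {
        weighted_score(fisher_profile(labels, e,
                                      config$top_fraction_interactions))
      }, numeric(1))
      scores[[gt]] <- tibble::tibble(entity = ents, genotype = gt, x_k = xk)
      log_stage(paste0("enrich/", gt), length(labels), length(ents))
    }
  }
  pairs_all <- dplyr::bind_rows(pairs)
  write_table(pairs_all, file.path(config$out_dir, "pairs.tsv"))
  fpr_all <- dplyr::bind_rows(fpr)
  write_table(fpr_all, file.path(config$out_dir, "fpr_curves.tsv"))
  if (length(scores) > 0L) {
    ranks <- scaled_ranks(dplyr::bind_rows(scores))
    write_table(ranks, file.path(config$out_dir, "bin_ranks.tsv"))
  } else {
    ranks <- NULL
  }

  # -- clustering ------------------------------------------------------------
  patterns <- pattern_vectors(summaries, "metabolite")
  n_nonflat <- nrow(pattern_matrix(patterns))
  k_use <- max(2L, min(config$cluster_k, n_nonflat - 1L))
  assignments <- dplyr::bind_rows(lapply(config$cluster_methods, function(m) {
    cluster_patterns(patterns, method = m, k = k_use, seed = config$seed)
  }))
  write_table(assignments, file.path(config$out_dir, "clusters.tsv"))
  d_gt <- if (length(genotypes) >= 2L) {
    genotype_distance(patterns, k = k_use, seed = config$seed)
  } else {
    NULL
  }
  if (!is.null(d_gt)) {
    write_table(d_gt, file.path(config$out_dir, "genotype_distance.tsv"))
  }
  log_stage("cluster", nrow(patterns), nrow(assignments))

  # -- network ---------------------------------------------------------------
  ann_use <- if (is.null(annotation)) {
    tibble::tibble(molecule_id = unique(pairs_all$phosphopeptide_id),
                   bin_code = "unknown", bin_name = NA_character_)
  } else {
    annotation
  }
  connections <- dplyr::bind_rows(lapply(pairs, function(pt) {
    filter_connections(pt, ic_min = config$ic_network,
                       alpha = config$spearman_alpha)
  }))
  write_table(connections, file.path(config$out_dir, "connections.tsv"))
  if (nrow(connections) > 0L) {
    edges <- aggregate_bins(connections, ann_use,
                            bin_depth = config$bin_depth)
    write_table(edges, file.path(config$out_dir, "bin_edges.tsv"))
    network <- build_network(edges)
    export_network(network, file.path(config$out_dir, "network.graphml"))
  } else {
    edges <- NULL
    network <- NULL
  }
  log_stage("network", nrow(connections),
            if (is.null(edges)) 0L else nrow(edges))

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    genotypes = genotypes,
    n_measurements = nrow(data),
    n_molecules = nrow(summaries),
    n_pairs = nrow(pairs_all),
    n_connections = nrow(connections),
    package_version = as.character(utils::packageVersion("concordr")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(summaries = summaries, pairs = pairs_all,
                 connections = connections, edges = edges, fpr = fpr_all,
                 ranks = ranks, assignments = assignments, d_gt = d_gt,
                 network = network))
}
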