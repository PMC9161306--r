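#' Filter concordant pairs into connections
#'
#' A connection is a metabolite-phosphopeptide pair with concordance index
#' at or above the threshold (inclusive), a significant Spearman rank
#' correlation, and non-flat patterns for both partners. The screening
#' threshold used throughout is I_C >= 6; network construction uses the
#' stricter default I_C >= 7. Discordant connections (I_C <= -threshold) are
#' available via `direction = "negative"`.
#'
#' @param pair_table [concordance_table()] output.
#' @param ic_min Concordance-index threshold (default 7).
#' @param alpha Spearman significance level (default 0.05).
#' @param direction `"positive"` (default) keeps `ic >= ic_min`;
#'   `"negative"` keeps `ic <= -ic_min`.
#' @return Tibble of surviving rows, ordered by descending |ic| then ids.
#' @export
filter_connections <- function(pair_table, ic_min = 7, alpha = 0.05,
                               direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  keep <- if (direction == "positive") {
    pair_table$ic >= ic_min
  } else {
    pair_table$ic <= -ic_min
  }
  keep <- keep & pair_table$rho_p <= alpha &
    !pair_table$flat_m & !pair_table$flat_p
  keep[is.na(keep)] <- FALSE
  out <- pair_table[keep, , drop = FALSE]
  ord <- order(-abs(out$ic), out$metabolite_id, out$phosphopeptide_id)
  out[ord, , drop = FALSE]
}

#' Aggregate connections into metabolite-bin edges
#'
#' Groups connections by (metabolite, functional bin, genotype); each edge
#' carries the arithmetic mean of the member connections' I_C values and the
#' connection count. A phosphopeptide mapped to several bins contributes to
#' each of them; unannotated phosphopeptides fall into bin `"unknown"` (with
#' a message).
#'
#' @param connections [filter_connections()] output.
#' @param annotation [read_annotation()] tibble mapping phosphopeptide ids to
#'   bin codes.
#' @param bin_depth Dotted-code truncation depth (default 2, e.g. `34.19`);
#'   `Inf` keeps full codes.
#' @return Tibble `metabolite_id`, `bin_code`, `genotype`, `mean_ic`,
#'   `n_connections`.
#' @export
aggregate_bins <- function(connections, annotation, bin_depth = 2) {
  ann <- annotation
  ann$bin_code <- bin_simplify(ann$bin_code, depth = bin_depth)
  ann <- dplyr::distinct(ann[, c("molecule_id", "bin_code")])
  joined <- dplyr::left_join(connections, ann,
                             by = c(phosphopeptide_id = "molecule_id"),
                             relationship = "many-to-many")
  n_unknown <- sum(is.na(joined$bin_code))
  if (n_unknown > 0L) {
    message(n_unknown, " connection(s) with unannotated phosphopeptides ",
            "assigned to bin \"unknown\"")
    joined$bin_code[is.na(joined$bin_code)] <- "unknown"
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$metabolite_id, .data$bin_code,
                    .data$genotype),
    mean_ic = mean(.data$ic),
    n_connections = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$genotype, .data$metabolite_id, .data$bin_code)
}

#' Assemble the bipartite metabolite-bin network
#'
#' Builds an igraph multigraph whose node sets are metabolites and
#' functional bins; each [aggregate_bins()] edge becomes one edge carrying
#' its genotype, mean I_C weight and connection count, so the same
#' (metabolite, bin) pair revealed in several genotypes yields parallel
#' edges distinguishable by the genotype attribute.
#'
#' @param edges [aggregate_bins()] output (one or several genotypes,
#'   row-bound).
#' @return An igraph graph with vertex attributes `type`
#'   (`"metabolite"`/`"bin"`) and edge attributes `genotype`, `mean_ic`
#'   (also copied to `weight`), `n_connections`.
#' @export
build_network <- function(edges) {
  if (nrow(edges) == 0L) stop("no edges", call. = FALSE)
  mets <- unique(edges$metabolite_id)
  bins <- unique(edges$bin_code)
  overlap <- intersect(mets, bins)
  if (length(overlap) > 0L) {
    stop("metabolite and bin namespaces overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  vertices <- data.frame(
    name = c(mets, bins),
    type = rep(c("metabolite", "bin"), c(length(mets), length(bins))),
    stringsAsFactors = FALSE
  )
  edge_df <- data.frame(
    from = edges$metabolite_id,
    to = edges$bin_code,
    genotype = edges$genotype,
    mean_ic = edges$mean_ic,
    weight = edges$mean_ic,
    n_connections = edges$n_connections,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                vertices = vertices)
}

#' Per-node degree and weight comparison across genotypes
#'
#' For every node (metabolite or bin): edge count (degree) and summed mean
#' I_C per genotype, plus presence flags and the max-min differences that
#' show where connectivity was gained or lost between genotypes.
#'
#' @param edges [aggregate_bins()] output covering >= 2 genotypes.
#' @return Tibble `node`, `node_type`, one `degree_<genotype>` and
#'   `sum_ic_<genotype>` column per genotype, `degree_diff`, `sum_ic_diff`,
#'   `present_in`.
#' @export
compare_genotypes <- function(edges) {
  genotypes <- sort(unique(edges$genotype))
  if (length(genotypes) < 2L) {
    stop("need edges from >= 2 genotypes", call. = FALSE)
  }
  long <- dplyr::bind_rows(
    tibble::tibble(node = edges$metabolite_id, node_type = "metabolite",
                   genotype = edges$genotype, ic = edges$mean_ic),
    tibble::tibble(node = edges$bin_code, node_type = "bin",
                   genotype = edges$genotype, ic = edges$mean_ic)
  )
  per <- dplyr::summarise(
    dplyr::group_by(long, .data$node, .data$node_type, .data$genotype),
    degree = dplyr::n(),
    sum_ic = sum(.data$ic),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per, names_from = "genotype",
                             values_from = c("degree", "sum_ic"),
                             values_fill = list(degree = 0L, sum_ic = 0))
  deg_cols <- paste0("degree_", genotypes)
  ic_cols <- paste0("sum_ic_", genotypes)
  degm <- as.matrix(wide[, deg_cols])
  icm <- as.matrix(wide[, ic_cols])
  wide$degree_diff <- apply(degm, 1L, max) - apply(degm, 1L, min)
  wide$sum_ic_diff <- apply(icm, 1L, max) - apply(icm, 1L, min)
  wide$present_in <- apply(degm > 0, 1L, function(r)
    paste(genotypes[r], collapse = ","))
  dplyr::arrange(wide, .data$node_type, .data$node)
}

#' Export a network to GraphML, GML or an edge-list TSV
#'
#' Edge weights (mean I_C) and genotype attributes are exported so an
#' external tool can run a force-directed layout; no layout is computed
#' here.
#'
#' @param graph [build_network()] graph.
#' @param path Output path.
#' @param format `"graphml"` (default), `"gml"` or `"tsv"` (flat edge list).
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("graphml", "gml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    el <- igraph::as_data_frame(graph, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), path, progress = FALSE)
  } else {
    igraph::write_graph(graph, path, format = format)
  }
  invisible(path)
}
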