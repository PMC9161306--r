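#' Truncate a dotted bin code to a given depth
#'
#' Mapman-style functional-category codes form a dotted hierarchy
#' (e.g. `34.19.2`); depth 1 keeps the highest-order category (`34`),
#' depth 2 keeps `34.19`, `Inf` (or 0) keeps the full code.
#'
#' @param code Character vector of bin codes.
#' @param depth Number of dotted levels to keep.
#' @return Character vector of truncated codes.
#' @export
bin_simplify <- function(code, depth = Inf) {
  if (!is.finite(depth) || depth <= 0) return(code)
  vapply(strsplit(as.character(code), ".", fixed = TRUE), function(parts) {
    paste(utils::head(parts, depth), collapse = ".")
  }, character(1))
}

#' Over-representation profile of an entity along a ranked list
#'
#' Walks the sorted list from the top: at every position n in
#' 1..floor(`top_fraction` * N) it tests whether the entity occurs more often
#' among the first n entries than expected, via a one-sided Fisher exact test
#' on the 2x2 table (k, n-k; K-k, (N-K)-(n-k)) where k and K count the
#' entity's occurrences in the top n and in the whole list. P-values are
#' Bonferroni-adjusted by the number of profile positions and capped at 1.
#' An entity over-represented along a substantial stretch of the profile is
#' more trustworthy than one significant at a single n.
#'
#' @param sorted_list Character vector of entity labels, best-ranked first.
#' @param entity Entity label to profile; must occur in the list.
#' @param top_fraction Fraction of the list to scan (default 0.10).
#' @return Tibble `entity`, `position_n`, `k`, `p_raw`, `p_adjusted`.
#' @export
fisher_profile <- function(sorted_list, entity, top_fraction = 0.10) {
  N <- length(sorted_list)
  K <- sum(sorted_list == entity)
  if (K == 0L) {
    stop("entity '", entity, "' does not occur in the list", call. = FALSE)
  }
  n_top <- max(1L, floor(top_fraction * N))
  n <- seq_len(n_top)
  k <- cumsum(sorted_list[n] == entity)
  p_raw <- fisher_enrichment_p(k, n, K, N)
  tibble::tibble(
    entity = entity,
    position_n = n,
    k = as.integer(k),
    p_raw = p_raw,
    p_adjusted = pmin(1, p_raw * n_top)
  )
}

# one-sided (enrichment) Fisher exact p = upper hypergeometric tail
# P(X >= k) with X ~ Hypergeom(N, K, n)
fisher_enrichment_p <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Weighted profile score
#'
#' Collapses an over-representation profile into the scalar
#' x_k = w^T v with v_i = -log10(adjusted p at position i) and descending
#' weights w^T = (n_top, n_top - 1, ..., 1), so enrichment near the very top
#' of the list weighs most.
#'
#' @param profile [fisher_profile()] tibble (or numeric vector of adjusted
#'   p-values in position order).
#' @return Non-negative scalar x_k.
#' @export
weighted_score <- function(profile) {
  p <- if (is.data.frame(profile)) profile$p_adjusted else as.numeric(profile)
  n_top <- length(p)
  v <- -log10(p)
  sum(seq.int(n_top, 1L) * v)
}

#' Scaled over-representation ranks across genotypes
#'
#' Per genotype, entities are ranked by their weighted score x_k in
#' descending order (rank 1 = most over-represented; ties broken by entity
#' label) and the rank is mapped into the open interval (0, 1) as
#' rank / (count + 1). Entities are returned sorted by ascending mean scaled
#' rank over the genotypes: lower means more consistently over-represented.
#'
#' @param scores Tibble with columns `entity`, `genotype`, `x_k`.
#' @return Tibble `entity`, `genotype`, `x_k`, `rho_sc`, `mean_rho_sc`,
#'   sorted by ascending `mean_rho_sc`.
#' @export
scaled_ranks <- function(scores) {
  if (length(unique(scores$entity)) < 2L) {
    stop("need >= 2 entities to rank", call. = FALSE)
  }
  ranked <- dplyr::mutate(
    dplyr::group_by(scores, .data$genotype),
    rho_sc = order(order(-.data$x_k, .data$entity)) / (dplyr::n() + 1)
  )
  ranked <- dplyr::ungroup(ranked)
  means <- dplyr::summarise(dplyr::group_by(ranked, .data$entity),
                            mean_rho_sc = mean(.data$rho_sc),
                            .groups = "drop")
  out <- dplyr::left_join(ranked, means, by = "entity")
  dplyr::arrange(out, .data$mean_rho_sc, .data$entity, .data$genotype)
}

#' Build ranked entity lists for over-representation analysis
#'
#' Sorts an input table by a key and maps each row to an entity label:
#' * a concordance table sorted by `ic` yields metabolite ids or (via
#'   `annotation`) the bin codes of the phosphopeptides;
#' * a molecule table sorted by mean abundance or a genotype-distance table
#'   sorted by `d_gt` yields bin codes of the molecules.
#'
#' Sorting is deterministic: ties are broken by the id columns. A row whose
#' molecule has several bin annotations contributes one label per bin (list
#' expansion); unannotated molecules are dropped from bin-labelled lists.
#'
#' @param table Data frame to rank.
#' @param sort_key Column to sort by (e.g. `"ic"`, `"mean_abundance"`,
#'   `"d_gt"`).
#' @param direction `"descending"` (default) or `"ascending"`.
#' @param entity `"metabolite"` (labels = `metabolite_id`), `"id"` (labels =
#'   `molecule_id`) or `"bin"` (labels = bin codes via `annotation`).
#' @param annotation [read_annotation()] tibble; required for
#'   `entity = "bin"`. The id column joined on is `phosphopeptide_id` when
#'   present, else `molecule_id`.
#' @param bin_depth Dotted-code truncation depth (default 1: highest-order
#'   categories).
#' @return Character vector of entity labels in list order.
#' @export
rank_lists <- function(table, sort_key,
                       direction = c("descending", "ascending"),
                       entity = c("metabolite", "id", "bin"),
                       annotation = NULL, bin_depth = 1) {
  direction <- match.arg(direction)
  entity <- match.arg(entity)
  if (!sort_key %in% names(table)) {
    stop("unknown sort key '", sort_key, "'", call. = FALSE)
  }
  id_col <- if ("phosphopeptide_id" %in% names(table)) {
    "phosphopeptide_id"
  } else {
    "molecule_id"
  }
  tie_cols <- intersect(c("metabolite_id", "phosphopeptide_id", "molecule_id"),
                        names(table))
  keyval <- table[[sort_key]]
  if (direction == "descending") keyval <- -xtfrm(keyval)
  ord <- do.call(order, c(list(keyval), lapply(tie_cols, function(cc)
    table[[cc]])))
  sorted <- table[ord, , drop = FALSE]
  if (entity == "metabolite") {
    if (!"metabolite_id" %in% names(sorted)) {
      stop("table has no metabolite_id column", call. = FALSE)
    }
    return(sorted$metabolite_id)
  }
  if (entity == "id") return(sorted[[id_col]])
  if (is.null(annotation)) {
    stop("entity = \"bin\" requires an annotation table", call. = FALSE)
  }
  ann <- annotation
  ann$bin_code <- bin_simplify(ann$bin_code, depth = bin_depth)
  labs <- split(ann$bin_code, ann$molecule_id)
  unlist(labs[sorted[[id_col]]], use.names = FALSE)
}
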