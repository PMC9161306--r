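#' Standardized condition-mean patterns
#'
#' Extracts the z-scored condition-mean pattern (order DR, DS, NR, NS) of
#' every molecule of one class from a summary table, together with its
#' flatness verdict. These 4-vectors are the objects that get clustered.
#'
#' @param summaries [summarize_conditions()] output.
#' @param molecule_class `"metabolite"` (default) or `"phosphopeptide"`.
#' @return Tibble `molecule_id`, `genotype`, `z_DR`..`z_NS`, `is_flat`.
#' @export
pattern_vectors <- function(summaries, molecule_class = "metabolite") {
  s <- summaries[summaries$molecule_class == molecule_class, , drop = FALSE]
  cols <- c("molecule_id", "genotype", paste0("z_", condition_levels()),
            "is_flat")
  tibble::as_tibble(s[, cols])
}

# z matrix of the non-flat, complete patterns; rownames molecule\rgenotype
pattern_matrix <- function(patterns) {
  z <- as.matrix(patterns[, paste0("z_", condition_levels())])
  rownames(z) <- paste(patterns$molecule_id, patterns$genotype, sep = "\r")
  keep <- !patterns$is_flat & stats::complete.cases(z)
  z[keep, , drop = FALSE]
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to the squared distance to the nearest chosen centre
kmeanspp_centers <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(z))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- z[idx, ]
  d2 <- rowSums((z - matrix(centers[1L, ], n, ncol(z), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- z[idx, ]
    d2 <- pmin(d2, rowSums((z - matrix(centers[j, ], n, ncol(z),
                                       byrow = TRUE))^2))
  }
  centers
}

# best-of-n_start k-means with ++ seeding
kmeans_pp <- function(z, k, n_start = 100L, iter_max = 300L) {
  best <- NULL
  for (r in seq_len(n_start)) {
    centers <- kmeanspp_centers(z, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(z, centers = centers, iter.max = iter_max)
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster standardized condition-mean patterns
#'
#' Flat molecules are assigned to the dedicated cluster `"Z"`; the remaining
#' patterns are partitioned into `k` clusters either by k-means (k-means++
#' seeding, 100 restarts, at most 300 iterations, Euclidean geometry) or by
#' hierarchical clustering (Euclidean distance, Ward linkage, tree cut at
#' `k`). Cluster labels are `"1"`..`"k"` plus `"Z"`.
#'
#' @param patterns [pattern_vectors()] tibble (one or several genotypes).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param k Number of clusters for the non-flat patterns.
#' @param n_start,iter_max k-means restarts and iteration cap.
#' @param seed Integer seed for the k-means restarts.
#' @return Tibble `molecule_id`, `genotype`, `config_id`, `cluster`.
#' @export
cluster_patterns <- function(patterns, method = c("kmeans", "hierarchical"),
                             k, n_start = 100L, iter_max = 300L, seed = 1L) {
  method <- match.arg(method)
  z <- pattern_matrix(patterns)
  if (k < 2L || k > nrow(z)) {
    stop("k must be in [2, number of non-flat patterns] (= ", nrow(z), ")",
         call. = FALSE)
  }
  if (method == "kmeans") {
    old_seed <- .Random.seed_get()
    on.exit(.Random.seed_set(old_seed), add = TRUE)
    set.seed(seed)
    labels <- kmeans_pp(z, k, n_start = n_start, iter_max = iter_max)$cluster
  } else {
    labels <- stats::cutree(stats::hclust(stats::dist(z), method = "ward.D2"),
                            k = k)
  }
  key <- paste(patterns$molecule_id, patterns$genotype, sep = "\r")
  cl <- as.character(labels)[match(key, rownames(z))]
  cl[is.na(cl)] <- "Z"
  tibble::tibble(
    molecule_id = patterns$molecule_id,
    genotype = patterns$genotype,
    config_id = paste0(method, "_k", k),
    cluster = cl
  )
}

#' Average pattern of each cluster
#'
#' @param assignment [cluster_patterns()] tibble.
#' @param patterns The clustered [pattern_vectors()] tibble.
#' @return Tibble `cluster`, `n`, `z_DR`..`z_NS` (arithmetic means of the
#'   member z-vectors).
#' @export
cluster_mean_pattern <- function(assignment, patterns) {
  zc <- paste0("z_", condition_levels())
  joined <- dplyr::inner_join(assignment, patterns,
                              by = c("molecule_id", "genotype"))
  dplyr::summarise(
    dplyr::group_by(joined, .data$cluster),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(zc), ~ mean(.x)),
    .groups = "drop"
  )
}

#' Genotype-overlapping clustering
#'
#' Pools the (molecule, genotype) patterns of all genotypes into a single
#' clustering so that each molecule receives one cluster label per genotype;
#' molecules whose pattern changes between genotypes land in different
#' clusters.
#'
#' @inheritParams cluster_patterns
#' @return As [cluster_patterns()]; `config_id` carries an `overall_` prefix.
#' @export
overlapping_clusters <- function(patterns, method = c("kmeans", "hierarchical"),
                                 k, n_start = 100L, iter_max = 300L,
                                 seed = 1L) {
  if (length(unique(patterns$genotype)) < 2L) {
    stop("genotype-overlapping clustering needs patterns from >= 2 genotypes",
         call. = FALSE)
  }
  out <- cluster_patterns(patterns, method = method, k = k, n_start = n_start,
                          iter_max = iter_max, seed = seed)
  out$config_id <- paste0("overall_", out$config_id)
  out
}

#' Silhouette-guided choice of k
#'
#' Runs k-means (++ seeding) over a k-range and returns the k maximizing the
#' mean silhouette width (Euclidean).
#'
#' @param patterns [pattern_vectors()] tibble.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @return List with `k` (best) and `scores` (tibble `k`, `mean_silhouette`).
#' @export
select_k_silhouette <- function(patterns, k_range = 2:15, seed = 1L) {
  z <- pattern_matrix(patterns)
  k_range <- k_range[k_range >= 2L & k_range <= nrow(z) - 1L]
  if (length(k_range) == 0L) stop("no admissible k in range", call. = FALSE)
  dmat <- stats::dist(z)
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed), add = TRUE)
  set.seed(seed)
  scores <- vapply(k_range, function(k) {
    cl <- kmeans_pp(z, k, n_start = 25L)$cluster
    if (length(unique(cl)) < 2L) return(NA_real_)
    mean(cluster::silhouette(cl, dmat)[, "sil_width"])
  }, numeric(1))
  tibble::tibble(k = k_range, mean_silhouette = scores) -> tab
  list(k = k_range[which.max(scores)], scores = tab)
}

#' Between-genotype pattern distance d_GT
#'
#' Quantifies, per molecule, how strongly its standardized pattern diverges
#' between genotypes. Two components on \[0, 1\] are combined with weights
#' summing to 1 (default 0.5/0.5):
#' * `change_component` - the fraction, over an ensemble of clustering
#'   configurations and over genotype pairs, of pairs assigned to different
#'   clusters (the flat cluster `"Z"` counts as a label of its own);
#' * `euclid_component` - the summed pairwise Euclidean distance between the
#'   molecule's z-vectors across genotypes, normalized by the dataset
#'   maximum (so the most divergent molecule scores 1).
#'
#' Molecules flat in all genotypes get `NA`.
#'
#' @param patterns [pattern_vectors()] tibble covering all genotypes.
#' @param ensemble List of genotype-overlapping [cluster_patterns()] /
#'   [overlapping_clusters()] assignments; `NULL` builds the default
#'   ensemble \{hierarchical, k-means\} x \{k-2, k, k+2\}.
#' @param k Central cluster count for the default ensemble (default 13).
#' @param weights Numeric `c(change, euclid)`; must sum to 1.
#' @param seed Integer seed for the ensemble's k-means runs.
#' @return Tibble `molecule_id`, `d_gt`, `change_component`,
#'   `euclid_component`, sorted by descending `d_gt`.
#' @export
genotype_distance <- function(patterns, ensemble = NULL, k = 13L,
                              weights = c(0.5, 0.5), seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1", call. = FALSE)
  }
  genotypes <- unique(patterns$genotype)
  if (length(genotypes) < 2L) {
    stop("need patterns from >= 2 genotypes", call. = FALSE)
  }
  if (is.null(ensemble)) {
    n_nonflat <- nrow(pattern_matrix(patterns))
    ks <- unique(pmax(2L, pmin(as.integer(k) + c(-2L, 0L, 2L),
                               n_nonflat - 1L)))
    ensemble <- list()
    for (m in c("kmeans", "hierarchical")) {
      for (kk in ks) {
        ensemble[[paste0(m, kk)]] <-
          overlapping_clusters(patterns, method = m, k = kk, seed = seed)
      }
    }
  }
  zc <- paste0("z_", condition_levels())
  ids <- unique(patterns$molecule_id)
  change <- rep(NA_real_, length(ids))
  euclid_sum <- rep(NA_real_, length(ids))
  for (ii in seq_along(ids)) {
    p <- patterns[patterns$molecule_id == ids[ii], , drop = FALSE]
    if (all(p$is_flat)) next
    # cluster-change fraction over configurations x genotype pairs
    diffs <- 0L
    total <- 0L
    for (asg in ensemble) {
      a <- asg[asg$molecule_id == ids[ii], , drop = FALSE]
      lab <- stats::setNames(a$cluster, a$genotype)
      gts <- intersect(genotypes, names(lab))
      if (length(gts) < 2L) next
      prs <- utils::combn(gts, 2L)
      for (cc in seq_len(ncol(prs))) {
        total <- total + 1L
        if (lab[[prs[1L, cc]]] != lab[[prs[2L, cc]]]) diffs <- diffs + 1L
      }
    }
    change[ii] <- if (total > 0L) diffs / total else NA_real_
    # summed pairwise Euclidean distance over genotypes with defined z
    z <- as.matrix(p[stats::complete.cases(p[, zc]), zc, drop = FALSE])
    if (nrow(z) >= 2L) {
      euclid_sum[ii] <- sum(stats::dist(z))
    } else {
      euclid_sum[ii] <- 0
    }
  }
  max_euclid <- max(euclid_sum, na.rm = TRUE)
  euclid <- if (is.finite(max_euclid) && max_euclid > 0) {
    euclid_sum / max_euclid
  } else {
    euclid_sum * 0
  }
  out <- tibble::tibble(
    molecule_id = ids,
    d_gt = weights[1L] * change + weights[2L] * euclid,
    change_component = change,
    euclid_component = euclid
  )
  dplyr::arrange(out, dplyr::desc(.data$d_gt))
}
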