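# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# long tibble for one molecule from a named list of per-condition replicate
# values
make_series <- function(values, molecule_id = "m1",
                        molecule_class = "metabolite", genotype = "wt") {
  rows <- lapply(names(values), function(cc) {
    v <- values[[cc]]
    tibble::tibble(
      molecule_id = molecule_id, molecule_class = molecule_class,
      genotype = genotype, condition = cc,
      replicate = seq_along(v), value = as.numeric(v)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$is_outlier <- FALSE
  out
}

# a summary row straight from means and sds (n = 5 each), bypassing replicates
make_summary_row <- function(means, sds, molecule_id = "m1",
                             molecule_class = "metabolite", genotype = "wt",
                             is_flat = FALSE) {
  lv <- concordr::condition_levels()
  out <- tibble::tibble(molecule_id = molecule_id,
                        molecule_class = molecule_class, genotype = genotype)
  for (j in 1:4) out[[paste0("mean_", lv[j])]] <- means[j]
  for (j in 1:4) out[[paste0("sd_", lv[j])]] <- sds[j]
  for (j in 1:4) out[[paste0("n_", lv[j])]] <- 5L
  out$variance_ratio <- NA_real_
  out$kw_p <- if (is_flat) 1 else 0.001
  out$is_flat <- is_flat
  ok <- !is.na(means)
  mu <- mean(means[ok])
  psd <- sqrt(mean((means[ok] - mu)^2))
  for (j in 1:4) {
    out[[paste0("z_", lv[j])]] <-
      if (ok[j] && psd > 0) (means[j] - mu) / psd else NA_real_
  }
  out
}

# random summary rows for property-style tests
random_summary <- function(id, class = "metabolite", genotype = "wt") {
  make_summary_row(stats::rnorm(4), abs(stats::rnorm(4)) + 0.1,
                   molecule_id = id, molecule_class = class,
                   genotype = genotype)
}

# pattern_vectors-shaped tibble from a matrix of z rows
make_patterns <- function(z, ids = NULL, genotype = "wt", is_flat = NULL) {
  lv <- concordr::condition_levels()
  n <- nrow(z)
  if (is.null(ids)) ids <- sprintf("mol_%02d", seq_len(n))
  if (is.null(is_flat)) is_flat <- rep(FALSE, n)
  out <- tibble::tibble(molecule_id = ids, genotype = genotype)
  for (j in 1:4) out[[paste0("z_", lv[j])]] <- z[, j]
  out$is_flat <- is_flat
  out
}

# independent oracle for the one-sided Fisher/hypergeometric enrichment p:
# explicit choose() tail enumeration
hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# every admissible (N, K, n, k) contingency configuration with N <= n_max
all_hyper_tables <- function(n_max = 30) {
  out <- list()
  for (N in 2:n_max) {
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        k <- max(0, n + K - N):min(n, K)
        out[[length(out) + 1L]] <- data.frame(N = N, K = K, n = n, k = k)
      }
    }
  }
  do.call(rbind, out)
}

# standardize rows of a matrix to mean 0, population sd 1
zrow <- function(m) {
  t(apply(m, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
}
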