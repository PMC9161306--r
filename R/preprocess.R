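#' Log2-transform a raw-scale measurement table
#'
#' @param data Long measurement tibble (see [read_measurements()]) on the raw
#'   scale; all values must be strictly positive.
#' @return The same tibble with `value` replaced by `log2(value)`.
#' @export
log2_transform <- function(data) {
  bad <- which(!is.finite(data$value) | data$value <= 0)
  if (length(bad) > 0L) {
    b <- data[bad[1L], ]
    stop("non-positive or non-finite value for molecule '", b$molecule_id,
         "' in condition ", b$condition, " (replicate ", b$replicate, "); ",
         length(bad), " offending value(s) in total", call. = FALSE)
  }
  data$value <- log2(data$value)
  data
}

#' Flag outliers by the modified z-score
#'
#' Iglewicz-Hoaglin modified z-score based on the median absolute deviation:
#' a point is flagged when |0.6745 (x - median) / MAD| exceeds `threshold`.
#' When the MAD is zero the score falls back to the mean absolute deviation
#' from the mean scaled by 1.2533; when that is also zero nothing is flagged.
#' The default threshold of 5 is deliberately conservative for the small
#' replicate groups typical of this design.
#'
#' @param x Numeric vector (one molecule, one condition group).
#' @param threshold Modified z-score cutoff (default 5).
#' @return Logical mask, `TRUE` for outliers. With fewer than 3 values no
#'   point is flagged and a warning is emitted.
#' @export
flag_outliers <- function(x, threshold = 5) {
  x <- as.numeric(x)
  if (length(x) < 3L) {
    warning("fewer than 3 values; no outlier flagging performed",
            call. = FALSE)
    return(rep(FALSE, length(x)))
  }
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0) {
    score <- 0.6745 * (x - med) / mad0
  } else {
    mean_ad <- mean(abs(x - mean(x)))
    if (mean_ad == 0) return(rep(FALSE, length(x)))
    score <- (x - med) / (1.2533 * mean_ad)
  }
  abs(score) > threshold
}

#' Mask outliers per molecule and condition group
#'
#' Applies [flag_outliers()] within each (molecule, genotype, condition)
#' replicate group and records the verdict in the `is_outlier` column.
#' Masked values are excluded from every downstream statistic.
#'
#' @param data Long measurement tibble.
#' @param threshold Modified z-score cutoff (default 5).
#' @return `data` with an updated logical `is_outlier` column.
#' @export
mask_outliers <- function(data, threshold = 5) {
  grp <- paste(data$molecule_id, data$molecule_class, data$genotype,
               data$condition, sep = "\r")
  mask <- logical(nrow(data))
  for (idx in split(seq_len(nrow(data)), grp)) {
    if (length(idx) < 3L) next  # too few values: keep all, silently
    mask[idx] <- flag_outliers(data$value[idx], threshold = threshold)
  }
  data$is_outlier <- mask
  data
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Kruskal-Wallis p-value over replicate groups; 1 when degenerate (all values
# tied, or fewer than two groups)
kw_pvalue <- function(values, groups) {
  if (length(unique(groups)) < 2L || length(unique(values)) < 2L) return(1)
  stats::kruskal.test(values, factor(groups))$p.value
}

#' Summarize per-condition statistics of every molecule
#'
#' For each (molecule, genotype): per-condition means, sample standard
#' deviations (denominator n-1) and replicate counts over unmasked values;
#' the variance ratio V_btw/V_within (sample variance of the condition means
#' over the pooled within-condition variance); the Kruskal-Wallis rank-test
#' p-value across the condition groups; the flatness verdict
#' (`is_flat` when `kw_p > alpha_flat`); and standardized condition means
#' (z-scores; population standardization over the four means, `NA` when all
#' means are equal).
#'
#' Conditions reduced below 2 unmasked replicates are treated as absent
#' (`NA` mean/sd, `n` as observed). Molecules with fewer than 2 usable
#' conditions are excluded with a message.
#'
#' @param data Long measurement tibble with `is_outlier` column (see
#'   [mask_outliers()]); rows with `is_outlier = TRUE` are ignored.
#' @param alpha_flat Flatness significance level (default 0.05).
#' @return Tibble with one row per molecule and genotype: `molecule_id`,
#'   `molecule_class`, `genotype`, `mean_DR`..`mean_NS`, `sd_DR`..`sd_NS`,
#'   `n_DR`..`n_NS`, `variance_ratio`, `kw_p`, `is_flat`, `z_DR`..`z_NS`.
#' @export
summarize_conditions <- function(data, alpha_flat = 0.05) {
  if (!"is_outlier" %in% names(data)) data$is_outlier <- FALSE
  data <- data[!data$is_outlier, , drop = FALSE]
  lv <- condition_levels()
  key <- paste(data$molecule_id, data$molecule_class, data$genotype,
               sep = "\r")
  ukey <- unique(key)
  kid <- match(key, ukey)
  cid <- match(data$condition, lv)
  cell <- (kid - 1L) * 4L + cid
  nk <- length(ukey)
  n <- tabulate(cell, nbins = nk * 4L)
  sum1 <- rep(0, nk * 4L)
  agg1 <- rowsum(data$value, cell)
  sum1[as.integer(rownames(agg1))] <- agg1[, 1L]
  m_all <- ifelse(n > 0L, sum1 / pmax(n, 1L), NA_real_)
  agg2 <- rowsum((data$value - m_all[cell])^2, cell)
  sumsq <- rep(0, nk * 4L)
  sumsq[as.integer(rownames(agg2))] <- agg2[, 1L]
  s_all <- ifelse(n > 1L, sqrt(sumsq / pmax(n - 1L, 1L)), NA_real_)

  N <- matrix(n, nrow = nk, ncol = 4L, byrow = TRUE)
  M <- matrix(m_all, nrow = nk, ncol = 4L, byrow = TRUE)
  S <- matrix(s_all, nrow = nk, ncol = 4L, byrow = TRUE)
  present <- N >= 2L
  M[!present] <- NA_real_
  S[!present] <- NA_real_

  usable <- rowSums(present) >= 2L
  if (any(!usable)) {
    first <- match(ukey[!usable], key)
    for (fi in first) {
      message("excluding molecule '", data$molecule_id[fi], "' (genotype ",
              data$genotype[fi],
              "): fewer than 2 conditions with >= 2 replicates")
    }
  }

  # between-condition variance of the means over pooled within variance
  n_pres <- rowSums(present)
  mu <- rowSums(M, na.rm = TRUE) / n_pres
  v_btw <- rowSums((M - mu)^2, na.rm = TRUE) / pmax(n_pres - 1L, 1L)
  v_within <- rowSums((N - 1L) * S^2 * present, na.rm = TRUE) /
    rowSums((N - 1L) * present, na.rm = TRUE)
  vr <- ifelse(v_within > 0, v_btw / v_within, ifelse(v_btw > 0, Inf, 0))

  # Kruskal-Wallis over the present condition groups, per molecule
  use_row <- present[kid, , drop = FALSE]
  keep <- use_row[cbind(seq_along(cid), cid)]
  kw_p <- rep(1, nk)
  vsplit <- split(data$value[keep], kid[keep])
  csplit <- split(cid[keep], kid[keep])
  for (nm in names(vsplit)) {
    kw_p[as.integer(nm)] <- kw_pvalue(vsplit[[nm]], csplit[[nm]])
  }

  # z-scores: population standardization of the present condition means
  zsd <- sqrt(rowSums((M - mu)^2, na.rm = TRUE) / n_pres)
  Z <- (M - mu) / ifelse(zsd > 0, zsd, NA_real_)

  first <- match(ukey, key)
  out <- tibble::tibble(
    molecule_id = data$molecule_id[first],
    molecule_class = data$molecule_class[first],
    genotype = data$genotype[first]
  )
  for (j in seq_len(4L)) out[[paste0("mean_", lv[j])]] <- M[, j]
  for (j in seq_len(4L)) out[[paste0("sd_", lv[j])]] <- S[, j]
  for (j in seq_len(4L)) out[[paste0("n_", lv[j])]] <- as.integer(N[, j])
  out$variance_ratio <- vr
  out$kw_p <- kw_p
  out$is_flat <- kw_p > alpha_flat
  for (j in seq_len(4L)) out[[paste0("z_", lv[j])]] <- Z[, j]
  out <- out[usable, , drop = FALSE]
  dplyr::arrange(out, .data$molecule_class, .data$genotype, .data$molecule_id)
}
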