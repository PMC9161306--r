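#' Condition deviations of one molecule
#'
#' For every ordered condition pair (j | i) (see [condition_pairs()]) the
#' deviation d_k = (mean_j - mean_i) / sd_i expresses the difference between
#' the two condition means in multiples of the sample standard deviation of
#' the reference condition i. When sd_i = 0 but the means differ, the
#' deviation is a signed infinity sentinel (it lands in the outermost
#' deviation class); when both means are equal it is 0. Pairs touching an
#' absent condition are marked invalid.
#'
#' @param summary One row of a [summarize_conditions()] table (data frame or
#'   list with `mean_*` and `sd_*` entries).
#' @return List with `d` (numeric 12-vector, names `"j|i"`) and `valid`
#'   (logical 12-vector).
#' @export
condition_deviations <- function(summary) {
  lv <- condition_levels()
  m <- vapply(lv, function(cc) as.numeric(summary[[paste0("mean_", cc)]]),
              numeric(1))
  s <- vapply(lv, function(cc) as.numeric(summary[[paste0("sd_", cc)]]),
              numeric(1))
  if (all(is.na(m))) stop("all conditions absent", call. = FALSE)
  cp <- condition_pairs()
  mi <- m[cp$i]
  mj <- m[cp$j]
  si <- s[cp$i]
  valid <- !is.na(mi) & !is.na(mj)
  d <- rep(NA_real_, 12L)
  ok <- valid
  diff <- mj[ok] - mi[ok]
  sd_i <- si[ok]
  d[ok] <- ifelse(diff == 0, 0,
                  ifelse(sd_i > 0, diff / sd_i, sign(diff) * Inf))
  names(d) <- pair_labels()
  names(valid) <- pair_labels()
  list(d = d, valid = valid)
}

# deviation matrices for a block of summary rows: list(d = n x 12, valid = n x 12)
deviation_matrix <- function(summaries) {
  lv <- condition_levels()
  M <- as.matrix(summaries[, paste0("mean_", lv)])
  S <- as.matrix(summaries[, paste0("sd_", lv)])
  colnames(M) <- lv
  colnames(S) <- lv
  cp <- condition_pairs()
  Mi <- M[, cp$i, drop = FALSE]
  Mj <- M[, cp$j, drop = FALSE]
  Si <- S[, cp$i, drop = FALSE]
  valid <- !is.na(Mi) & !is.na(Mj)
  diff <- Mj - Mi
  d <- ifelse(diff == 0, 0, ifelse(Si > 0, diff / Si, sign(diff) * Inf))
  d[!valid] <- NA_real_
  colnames(d) <- pair_labels()
  colnames(valid) <- pair_labels()
  rownames(d) <- summaries$molecule_id
  rownames(valid) <- summaries$molecule_id
  list(d = d, valid = valid)
}

#' Combine the condition deviations of a molecule pair
#'
#' z_k = sign(d_k(M)) sign(d_k(P)) min(|d_k(M)|, |d_k(P)|): the combined
#' deviation keeps the smaller magnitude and is positive when both molecules
#' deviate in the same direction, negative otherwise. Components where either
#' side is invalid (absent condition) or exactly zero contribute 0.
#'
#' @param dM,dP Deviation vectors from [condition_deviations()] (same fixed
#'   pair order).
#' @return Numeric 12-vector of combined condition deviations.
#' @export
combine_deviations <- function(dM, dP) {
  z <- sign(dM$d) * sign(dP$d) * pmin(abs(dM$d), abs(dP$d))
  z[!dM$valid | !dP$valid | is.na(z)] <- 0
  names(z) <- pair_labels()
  z
}

#' Discretize a combined condition deviation into its index component
#'
#' Maps |z| onto the five deviation classes
#' \[1, 2) -> 0.25, \[2, 3) -> 1, \[3, 5) -> 1.5, \[5, 10) -> 1.75,
#' \[10, Inf) -> 2 (|z| < 1 -> 0), and carries the sign of z onto the
#' component. The mapping is odd and non-decreasing, and the components are
#' exact quarter-multiples so index sums compare exactly against thresholds.
#'
#' @param z Numeric vector of combined condition deviations (finite or the
#'   infinity sentinel).
#' @return Numeric vector of components in
#'   \{0, ±0.25, ±1, ±1.5, ±1.75, ±2\}.
#' @export
discretize_deviation <- function(z) {
  comp_values <- c(0, 0.25, 1, 1.5, 1.75, 2)
  idx <- findInterval(abs(z), c(1, 2, 3, 5, 10))
  out <- sign(z) * comp_values[idx + 1L]
  out[is.na(z)] <- 0
  out
}

#' Concordance index of a molecule pair
#'
#' Combines the two deviation vectors ([combine_deviations()]), discretizes
#' each combined deviation ([discretize_deviation()]) and sums the resulting
#' components separately for negative and positive values: I_C(-) <= 0,
#' I_C(+) >= 0 and the combined index I_C = I_C(-) + I_C(+). I_C lies in
#' \[-24, 24\]; large positive values indicate concordant patterns, large
#' negative values discordant ones.
#'
#' @param dM,dP Deviation vectors from [condition_deviations()].
#' @return List with `z` (combined deviations), `components`, `ic_neg`,
#'   `ic_pos`, `ic` and `n_valid_components`.
#' @export
concordance_index <- function(dM, dP) {
  z <- combine_deviations(dM, dP)
  comp <- discretize_deviation(z)
  ic_neg <- sum(comp[comp < 0])
  ic_pos <- sum(comp[comp > 0])
  list(z = z, components = comp, ic_neg = ic_neg, ic_pos = ic_pos,
       ic = ic_neg + ic_pos,
       n_valid_components = sum(dM$valid & dP$valid))
}

# molecule values arranged in condition x replicate-index "slots":
# matrix molecules x (4 * max_replicate), NA = missing/masked
slot_matrix <- function(data, ids) {
  data <- data[!data$is_outlier & data$molecule_id %in% ids, , drop = FALSE]
  max_rep <- max(data$replicate)
  lv <- condition_levels()
  mat <- matrix(NA_real_, nrow = length(ids), ncol = 4L * max_rep,
                dimnames = list(ids, paste0(rep(lv, each = max_rep), "_",
                                            rep(seq_len(max_rep), 4L))))
  col <- (match(data$condition, lv) - 1L) * max_rep + data$replicate
  mat[cbind(match(data$molecule_id, ids), col)] <- data$value
  mat
}

# Spearman rho / p for one molecule (slot vector x) against a block of
# molecules (slot matrix P); pairing by shared non-NA slots, midrank ties,
# two-sided p via the t-approximation. Pairs with < 4 shared points get p = 1.
spearman_block <- function(x, P) {
  nP <- nrow(P)
  rho <- rep(NA_real_, nP)
  p <- rep(1, nP)
  n_rho <- integer(nP)
  okx <- which(!is.na(x))
  if (length(okx) == 0L) return(list(rho = rho, p = p, n = n_rho))
  Pok <- !is.na(P[, okx, drop = FALSE])
  pat <- apply(Pok, 1L, function(r) paste(which(r), collapse = ","))
  for (pk in unique(pat)) {
    ridx <- which(pat == pk)
    if (pk == "") next
    cols <- okx[as.integer(strsplit(pk, ",", fixed = TRUE)[[1L]])]
    n <- length(cols)
    n_rho[ridx] <- n
    if (n < 4L) next
    rx <- rank(x[cols])
    cx <- rx - (n + 1) / 2
    sx <- sum(cx^2)
    if (sx == 0) next
    R <- t(apply(P[ridx, cols, drop = FALSE], 1L, rank))
    CR <- R - (n + 1) / 2
    num <- as.vector(CR %*% cx)
    den <- sqrt(rowSums(CR^2) * sx)
    r <- ifelse(den > 0, num / den, NA_real_)
    r <- pmin(1, pmax(-1, r))
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
    pv <- ifelse(is.na(r), 1,
                 ifelse(is.finite(tt), 2 * stats::pt(tt, n - 2,
                                                     lower.tail = FALSE), 0))
    rho[ridx] <- r
    p[ridx] <- pmin(pv, 1)
  }
  list(rho = rho, p = p, n = n_rho)
}

#' Spearman rank correlation of a molecule pair
#'
#' Observations are paired by (condition, replicate index), truncated per
#' condition to the smaller replicate count of the two molecules. The
#' correlation uses midranks for ties; the two-sided p-value uses the
#' t-approximation on the number of paired points. With fewer than 4 paired
#' points the p-value is set to 1 and a warning is emitted (the significance
#' filter then always removes the pair).
#'
#' @param m,p Long measurement tibbles of one molecule each (columns
#'   `condition`, `replicate`, `value` and optionally `is_outlier`).
#' @return List with `rho`, `rho_p` and `n_rho`.
#' @export
spearman_pair <- function(m, p) {
  if (!"is_outlier" %in% names(m)) m$is_outlier <- FALSE
  if (!"is_outlier" %in% names(p)) p$is_outlier <- FALSE
  m$molecule_id <- "m"
  p$molecule_id <- "p"
  both <- dplyr::bind_rows(m, p)
  mat <- slot_matrix(both, c("m", "p"))
  res <- spearman_block(mat["m", ], mat["p", , drop = FALSE])
  if (res$n[1L] < 4L) {
    warning("fewer than 4 paired observations; rho_p set to 1", call. = FALSE)
  }
  list(rho = res$rho[1L], rho_p = res$p[1L], n_rho = res$n[1L])
}

#' Concordance table over all metabolite-phosphopeptide pairs
#'
#' Computes, for every (metabolite, phosphopeptide) pair of one genotype, the
#' concordance index I_C with its negative and positive parts, the Spearman
#' rank correlation co-filter and the flatness flags of both partners. With
#' 42 metabolites and 3,330 phosphopeptides this yields
#' 42 x 3330 = 139,860 rows.
#'
#' @param data Long measurement tibble (both molecule classes, at least the
#'   requested genotype).
#' @param summaries [summarize_conditions()] output for `data`.
#' @param genotype Genotype to analyse (default: the single genotype present).
#' @param components Also return the 12 discretized components as columns
#'   `comp_1`..`comp_12` (default `FALSE`).
#' @return Tibble with columns `metabolite_id`, `phosphopeptide_id`,
#'   `genotype`, `ic_neg`, `ic_pos`, `ic`, `rho`, `rho_p`, `n_rho`, `flat_m`,
#'   `flat_p`, `n_valid_components`.
#' @export
concordance_table <- function(data, summaries, genotype = NULL,
                              components = FALSE) {
  if (is.null(genotype)) {
    genotype <- unique(summaries$genotype)
    if (length(genotype) != 1L) {
      stop("multiple genotypes present; pass `genotype`", call. = FALSE)
    }
  }
  sm <- summaries[summaries$genotype == genotype &
                    summaries$molecule_class == "metabolite", , drop = FALSE]
  sp <- summaries[summaries$genotype == genotype &
                    summaries$molecule_class == "phosphopeptide", , drop = FALSE]
  if (nrow(sm) == 0L || nrow(sp) == 0L) {
    stop("need at least one metabolite and one phosphopeptide for genotype '",
         genotype, "'", call. = FALSE)
  }
  if (anyDuplicated(sm$molecule_id) || anyDuplicated(sp$molecule_id)) {
    stop("duplicate molecule ids within a class", call. = FALSE)
  }
  if (!"is_outlier" %in% names(data)) data$is_outlier <- FALSE
  dgt <- data[data$genotype == genotype, , drop = FALSE]
  devM <- deviation_matrix(sm)
  devP <- deviation_matrix(sp)
  slotM <- slot_matrix(dgt[dgt$molecule_class == "metabolite", ],
                       sm$molecule_id)
  slotP <- slot_matrix(dgt[dgt$molecule_class == "phosphopeptide", ],
                       sp$molecule_id)
  nM <- nrow(sm)
  nP <- nrow(sp)
  out <- vector("list", nM)
  few_pairs <- 0L
  for (a in seq_len(nM)) {
    dM <- devM$d[a, ]
    vM <- devM$valid[a, ]
    A <- matrix(dM, nrow = nP, ncol = 12L, byrow = TRUE)
    Z <- sign(A) * sign(devP$d) * pmin(abs(A), abs(devP$d))
    Z[matrix(!vM, nrow = nP, ncol = 12L, byrow = TRUE) | !devP$valid |
        is.na(Z)] <- 0
    comp <- matrix(discretize_deviation(as.vector(Z)), nrow = nP)
    ic_pos <- rowSums(comp * (comp > 0))
    ic_neg <- rowSums(comp * (comp < 0))
    n_valid <- rowSums(devP$valid &
                         matrix(vM, nrow = nP, ncol = 12L, byrow = TRUE))
    sb <- spearman_block(slotM[a, ], slotP)
    few_pairs <- few_pairs + sum(sb$n < 4L)
    row <- tibble::tibble(
      metabolite_id = sm$molecule_id[a],
      phosphopeptide_id = sp$molecule_id,
      genotype = genotype,
      ic_neg = ic_neg, ic_pos = ic_pos, ic = ic_neg + ic_pos,
      rho = sb$rho, rho_p = sb$p, n_rho = sb$n,
      flat_m = sm$is_flat[a], flat_p = sp$is_flat,
      n_valid_components = as.integer(n_valid)
    )
    if (components) {
      comp_df <- tibble::as_tibble(as.data.frame(comp))
      names(comp_df) <- paste0("comp_", seq_len(12L))
      row <- dplyr::bind_cols(row, comp_df)
    }
    out[[a]] <- row
  }
  if (few_pairs > 0L) {
    message(few_pairs, " pair(s) had fewer than 4 paired observations; ",
            "their rho_p was set to 1")
  }
  dplyr::bind_rows(out)
}
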