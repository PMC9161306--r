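#' Fit a three-parameter Gamma distribution to a molecule's condition means
#'
#' Method-of-moments fit of a location-shape-scale Gamma to the (at least 3)
#' condition means of one molecule: shape = (2/g)^2 from the sample skewness
#' g, scale from the sample variance, location from the sample mean. With
#' non-positive or negligible skewness (g <= 0.05) the distribution is
#' fitted to the reflected values and flagged `mirrored`; |g| is floored at
#' 0.05 so near-symmetric molecules yield a well-conditioned (large-shape,
#' near-normal) fit rather than a numerically absurd one. A zero-variance
#' molecule gets a degenerate fit that reproduces the constant.
#'
#' @param means Numeric vector of condition means (>= 3 non-`NA` values), or
#'   a [summarize_conditions()] row.
#' @return Object of class `gamma_fit`: list with `shape`, `scale`, `location`,
#'   `mirrored`, `degenerate`, `constant`.
#' @export
fit_condition_mean_distribution <- function(means) {
  if (is.list(means) || is.data.frame(means)) {
    means <- vapply(condition_levels(),
                    function(cc) as.numeric(means[[paste0("mean_", cc)]]),
                    numeric(1))
  }
  x <- means[!is.na(means)]
  if (length(x) < 3L) {
    stop("need >= 3 condition means to fit the Gamma distribution",
         call. = FALSE)
  }
  m <- mean(x)
  v <- stats::var(x)
  if (v == 0) {
    fit <- list(shape = 1, scale = 1, location = m, mirrored = FALSE,
                degenerate = TRUE, constant = m)
    class(fit) <- "gamma_fit"
    return(fit)
  }
  s2 <- mean((x - m)^2)
  g <- mean((x - m)^3) / s2^1.5
  mirrored <- g <= 0.05
  g_eff <- max(abs(g), 0.05)
  shape <- (2 / g_eff)^2
  scale <- sqrt(v / shape)
  location <- m - shape * scale
  if (mirrored) location <- -m - shape * scale  # fit of the reflected values
  fit <- list(shape = shape, scale = scale, location = location,
              mirrored = mirrored, degenerate = FALSE, constant = NA_real_)
  class(fit) <- "gamma_fit"
  fit
}

#' Draw condition means from a fitted Gamma distribution
#'
#' @param fit A [fit_condition_mean_distribution()] object.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (reflected back when the fit is
#'   mirrored; constant for a degenerate fit).
#' @export
draw_condition_means <- function(fit, n) {
  if (fit$degenerate) return(rep(fit$constant, n))
  draws <- fit$location + stats::rgamma(n, shape = fit$shape,
                                        scale = fit$scale)
  if (fit$mirrored) -draws else draws
}

#' Simulate one molecule under the null
#'
#' Draws one condition mean per condition from the molecule's Gamma fit and
#' then draws the replicate values from a normal distribution centred on the
#' drawn mean with the molecule's experimental per-condition sample standard
#' deviation; replicate counts match the experimental counts. Conditions
#' absent from the experimental data stay absent.
#'
#' @param molecule Long measurement tibble of one molecule (one genotype).
#' @param summary The molecule's [summarize_conditions()] row.
#' @param fit The molecule's [fit_condition_mean_distribution()] object.
#' @return A tibble shaped like `molecule` with simulated `value`s.
#' @export
simulate_molecule <- function(molecule, summary, fit) {
  lv <- condition_levels()
  mu <- stats::setNames(draw_condition_means(fit, 4L), lv)
  sds <- vapply(lv, function(cc) as.numeric(summary[[paste0("sd_", cc)]]),
                numeric(1))
  sds[is.na(sds)] <- 0
  out <- molecule
  for (cc in lv) {
    idx <- which(out$condition == cc)
    if (length(idx) == 0L) next
    out$value[idx] <- stats::rnorm(length(idx), mean = mu[[cc]],
                                   sd = sds[[cc]])
  }
  out$is_outlier <- FALSE
  out
}

#' Simulate a dataset under one of the three null modes
#'
#' Replaces the measurements of the randomized molecule class(es) by draws
#' from each molecule's fitted Gamma/normal null while the other class passes
#' through untouched: `"randomize_metabolites"`, `"randomize_phosphopeptides"`
#' or `"randomize_both"`. The simulation is fully reproducible from `seed`.
#'
#' @param data Long measurement tibble (one genotype).
#' @param summaries [summarize_conditions()] output for `data`.
#' @param mode Simulation mode (see above).
#' @param seed Integer seed for the random generator.
#' @return List with `data` (the simulated long tibble), `mode` and `seed`.
#' @export
simulate_dataset <- function(data,
                             summaries,
                             mode = c("randomize_metabolites",
                                      "randomize_phosphopeptides",
                                      "randomize_both"),
                             seed = 1L) {
  mode <- match.arg(mode)
  classes <- switch(mode,
                    randomize_metabolites = "metabolite",
                    randomize_phosphopeptides = "phosphopeptide",
                    randomize_both = c("metabolite", "phosphopeptide"))
  if (!"is_outlier" %in% names(data)) data$is_outlier <- FALSE
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed), add = TRUE)
  set.seed(seed)
  out <- data
  key <- paste(data$molecule_id, data$molecule_class, data$genotype,
               sep = "\r")
  skey <- paste(summaries$molecule_id, summaries$molecule_class,
                summaries$genotype, sep = "\r")
  for (kk in unique(key)) {
    idx <- which(key == kk)
    cls <- data$molecule_class[idx[1L]]
    if (!cls %in% classes) next
    srow <- summaries[match(kk, skey), , drop = FALSE]
    if (nrow(srow) == 0L || is.na(srow$molecule_id[1L])) next
    fit <- fit_condition_mean_distribution(srow)
    sim <- simulate_molecule(data[idx, , drop = FALSE], srow, fit)
    out$value[idx] <- sim$value
    out$is_outlier[idx] <- FALSE
  }
  list(data = out, mode = mode, seed = seed)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' False-positive calibration curve
#'
#' For each threshold t, the share of pairs whose co-expression measure
#' reaches t: on the positive branch (t >= 0) the fraction with measure >= t,
#' on the negative branch the fraction with measure <= t. Experimental and
#' simulated shares are reported side by side; points above the y = x
#' diagonal indicate more pairs in the experimental data than expected under
#' the null. The default grids are quarter-integers in \[-24, 24\] for I_C
#' and 100 equal classes on \[-1, 1\] for Spearman's rho.
#'
#' @param exp_pairs,sim_pairs Concordance tables ([concordance_table()]).
#' @param measure `"ic"` or `"rho"`.
#' @param thresholds Threshold grid; `NULL` for the measure's default.
#' @return Tibble with `measure`, `threshold`, `share_experimental`,
#'   `share_simulated`.
#' @export
fpr_curve <- function(exp_pairs, sim_pairs, measure = c("ic", "rho"),
                      thresholds = NULL) {
  measure <- match.arg(measure)
  if (nrow(exp_pairs) == 0L || nrow(sim_pairs) == 0L) {
    stop("empty pair table", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- if (measure == "ic") {
      seq(-24, 24, by = 0.25)
    } else {
      seq(-1, 1, length.out = 100L)
    }
  }
  xe <- exp_pairs[[measure]]
  xs <- sim_pairs[[measure]]
  share <- function(x, t) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(rep(NA_real_, length(t)))
    vapply(t, function(tt) {
      if (tt >= 0) mean(x >= tt) else mean(x <= tt)
    }, numeric(1))
  }
  tibble::tibble(
    measure = measure,
    threshold = thresholds,
    share_experimental = share(xe, thresholds),
    share_simulated = share(xs, thresholds)
  )
}
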