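#' Pattern archetypes of the synthetic generator
#'
#' Base patterns over (DR, DS, NR, NS), scaled by the effect size when
#' generating data:
#' * `tissue_dominant` (-1, +1, -1, +1) - shoot/root difference dominates;
#' * `time_dominant` (+1, +1, -1, -1) - day/night difference dominates;
#' * `interaction` (+1, -1, -1, +1) - tissue-by-time interaction;
#' * `flat` (0, 0, 0, 0) - no condition effect.
#'
#' A molecule's polarity (sign of the pattern) is drawn separately, so two
#' molecules sharing an archetype are concordant with equal signs and
#' discordant with opposite signs.
#'
#' @return Named list of 4-vectors.
#' @export
archetype_patterns <- function() {
  list(
    tissue_dominant = c(DR = -1, DS = 1, NR = -1, NS = 1),
    time_dominant   = c(DR = 1, DS = 1, NR = -1, NS = -1),
    interaction     = c(DR = 1, DS = -1, NR = -1, NS = 1),
    flat            = c(DR = 0, DS = 0, NR = 0, NS = 0)
  )
}

default_mixture <- function() {
  c(tissue_dominant = 0.25, time_dominant = 0.25,
    interaction = 0.20, flat = 0.30)
}

#' Generate a synthetic study dataset with planted archetypes
#'
#' Emulates the study's dimensions - by default 42 metabolites and 3,330
#' phosphopeptides per genotype, 3 genotypes, 4-6 replicates per condition -
#' on the log2 scale. Each molecule is assigned an archetype (see
#' [archetype_patterns()]) and a polarity; its replicate values are
#' baseline + polarity * base_pattern * effect_size + Gaussian noise.
#' Replicate counts are drawn uniformly from `replicates` per (genotype,
#' condition) and shared across molecules, as replicates are shared
#' biological samples. The molecules keep their archetypes across genotypes.
#' Everything is deterministic given `seed`.
#'
#' @param n_metabolites,n_phospho Molecules per class (defaults 42 / 3330).
#' @param genotypes Character vector of genotype names, or a count.
#' @param replicates Range of replicate counts per condition (default `4:6`).
#' @param mixture Named archetype proportions summing to 1 (default:
#'   tissue 0.25, time 0.25, interaction 0.20, flat 0.30).
#' @param effect_size Pattern amplitude in log2 units (default 2).
#' @param noise_sd Replicate noise standard deviation in log2 units
#'   (default 0.5).
#' @param polarity_prob Probability that a non-flat molecule carries the
#'   positive polarity (default 0.5). 1 makes every same-archetype pair
#'   concordant; 0.5 splits them evenly between concordant and discordant.
#' @param seed Integer seed.
#' @return List with `data` (long measurement tibble), `archetypes` (tibble
#'   `molecule_id`, `molecule_class`, `archetype`, `polarity`) and `truth`
#'   ([pair_truth()] of all metabolite-phosphopeptide pairs).
#' @export
generate_dataset <- function(n_metabolites = 42L, n_phospho = 3330L,
                             genotypes = c("wt", "mut1", "mut2"),
                             replicates = 4:6,
                             mixture = default_mixture(),
                             effect_size = 2, noise_sd = 0.5,
                             polarity_prob = 0.5, seed = 1L) {
  if (is.numeric(genotypes) && length(genotypes) == 1L) {
    genotypes <- paste0("gt", seq_len(genotypes))
  }
  arch <- archetype_patterns()
  if (is.null(names(mixture)) || !all(names(mixture) %in% names(arch))) {
    stop("mixture must be named by archetype: ",
         paste(names(arch), collapse = ", "), call. = FALSE)
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed), add = TRUE)
  set.seed(seed)

  lv <- condition_levels()
  mol <- tibble::tibble(
    molecule_id = c(sprintf("met_%03d", seq_len(n_metabolites)),
                    sprintf("pep_%04d", seq_len(n_phospho))),
    molecule_class = rep(c("metabolite", "phosphopeptide"),
                         c(n_metabolites, n_phospho))
  )
  mol$archetype <- sample(names(mixture), nrow(mol), replace = TRUE,
                          prob = mixture)
  mol$polarity <- ifelse(mol$archetype == "flat", 1L,
                         sample(c(1L, -1L), nrow(mol), replace = TRUE,
                                prob = c(polarity_prob, 1 - polarity_prob)))
  mol$baseline <- stats::rnorm(nrow(mol), mean = 10, sd = 1.5)

  blocks <- list()
  for (gt in genotypes) {
    n_rep <- sample(replicates, 4L, replace = TRUE)
    names(n_rep) <- lv
    for (cc in lv) {
      nr <- n_rep[[cc]]
      n_mol <- nrow(mol)
      mu <- mol$baseline +
        mol$polarity * arch_value(mol$archetype, cc) * effect_size
      vals <- stats::rnorm(n_mol * nr,
                           mean = rep(mu, each = nr), sd = noise_sd)
      blocks[[paste(gt, cc)]] <- tibble::tibble(
        molecule_id = rep(mol$molecule_id, each = nr),
        molecule_class = rep(mol$molecule_class, each = nr),
        genotype = gt,
        condition = cc,
        replicate = rep(seq_len(nr), n_mol),
        value = vals
      )
    }
  }
  data <- dplyr::bind_rows(blocks)
  data$is_outlier <- FALSE
  archetypes <- mol[, c("molecule_id", "molecule_class", "archetype",
                        "polarity")]
  list(data = data, archetypes = archetypes,
       truth = pair_truth(archetypes))
}

arch_value <- function(archetype, condition) {
  arch <- archetype_patterns()
  vapply(archetype, function(a) arch[[a]][[condition]], numeric(1),
         USE.NAMES = FALSE)
}

#' Pair-level ground truth of a synthetic dataset
#'
#' Classifies every metabolite-phosphopeptide pair: `concordant` when both
#' molecules share a non-flat archetype with equal polarity, `discordant`
#' when they share it with opposite polarity, `independent` otherwise
#' (different archetypes, or any flat partner).
#'
#' @param archetypes `archetypes` tibble from [generate_dataset()].
#' @return Tibble `metabolite_id`, `phosphopeptide_id`, `relation`.
#' @export
pair_truth <- function(archetypes) {
  met <- archetypes[archetypes$molecule_class == "metabolite", , drop = FALSE]
  pep <- archetypes[archetypes$molecule_class == "phosphopeptide", ,
                    drop = FALSE]
  grid <- tidyr::expand_grid(m = seq_len(nrow(met)), p = seq_len(nrow(pep)))
  am <- met$archetype[grid$m]
  ap <- pep$archetype[grid$p]
  same <- am == ap & am != "flat"
  same_sign <- met$polarity[grid$m] == pep$polarity[grid$p]
  tibble::tibble(
    metabolite_id = met$molecule_id[grid$m],
    phosphopeptide_id = pep$molecule_id[grid$p],
    relation = ifelse(same & same_sign, "concordant",
                      ifelse(same, "discordant", "independent"))
  )
}

#' Precision and recall of connection recovery against planted truth
#'
#' Compares a set of predicted connections (e.g. [filter_connections()]
#' output; positive direction predicts `concordant`, negative predicts
#' `discordant`) against the [pair_truth()] table.
#'
#' @param predicted Data frame with `metabolite_id`, `phosphopeptide_id`.
#' @param truth [pair_truth()] tibble over the same molecule universe.
#' @param relation Truth relation the predictions target (default
#'   `"concordant"`).
#' @return List with `precision`, `recall`, `n_predicted`, `n_true`
#'   (precision is `NA` when nothing was predicted).
#' @export
evaluate_recovery <- function(predicted, truth, relation = "concordant") {
  key_p <- paste(predicted$metabolite_id, predicted$phosphopeptide_id,
                 sep = "\r")
  key_t <- paste(truth$metabolite_id, truth$phosphopeptide_id, sep = "\r")
  if (!all(key_p %in% key_t)) {
    stop("predicted pairs contain ids absent from the truth table",
         call. = FALSE)
  }
  pos <- key_t[truth$relation == relation]
  tp <- sum(key_p %in% pos)
  list(
    precision = if (length(key_p) > 0L) tp / length(key_p) else NA_real_,
    recall = if (length(pos) > 0L) tp / length(pos) else NA_real_,
    n_predicted = length(key_p),
    n_true = length(pos)
  )
}
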