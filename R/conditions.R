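#' Sampling conditions
#'
#' The four tissue-by-time sampling conditions: end-of-day root (DR),
#' end-of-day shoot (DS), end-of-night root (NR) and end-of-night shoot (NS).
#' Their order is fixed everywhere in the package.
#'
#' @return Character vector `c("DR", "DS", "NR", "NS")`.
#' @export
condition_levels <- function() {
  c("DR", "DS", "NR", "NS")
}

#' Ordered condition pairs used for condition deviations
#'
#' Each molecule contributes one condition deviation per ordered pair
#' (j | i), i.e. the difference of condition means divided by the standard
#' deviation of the reference condition i. With four conditions there are
#' twelve ordered pairs; the enumeration order is fixed so that serialized
#' outputs are stable.
#'
#' @return A tibble with columns `k` (1..12), `i` (reference condition) and
#'   `j` (compared condition).
#' @export
condition_pairs <- function() {
  lv <- condition_levels()
  i <- rep(lv, each = 3L)
  j <- unlist(lapply(lv, function(ci) setdiff(lv, ci)), use.names = FALSE)
  tibble::tibble(k = seq_len(12L), i = i, j = j)
}

# ordered pair labels "j|i", used in component dumps
pair_labels <- function() {
  cp <- condition_pairs()
  paste0(cp$j, "|", cp$i)
}
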