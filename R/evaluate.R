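#' Per-pathway selection frequency over replicates
#'
#' Fraction of simulation replicates in which each pathway entered the tuned
#' boosting model (was selected at least once within `m_stop`).
#'
#' @param selections list with one character vector of selected pathway ids
#'   per replicate (as returned by [selected_pathways()]).
#' @param pathways character vector, the full pathway universe.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
selection_frequency <- function(selections, pathways) {
  if (!length(selections)) stop("need at least one replicate")
  vapply(stats::setNames(pathways, pathways), function(p) {
    mean(vapply(selections, function(s) p %in% s, TRUE))
  }, 0)
}

#' Per-pathway rejection frequency of a testing comparator
#'
#' Fraction of replicates in which each pathway's p-value falls below the
#' raw or Bonferroni-corrected significance threshold.
#'
#' @param p_values replicates x pathways matrix of p-values (pathway ids as
#'   column names).
#' @param alpha significance level.
#' @param bonferroni divide `alpha` by the number of pathways?
#' @return Named numeric vector of frequencies.
#' @export
rejection_frequency <- function(p_values, alpha = 0.05, bonferroni = FALSE) {
  p_values <- as.matrix(p_values)
  thr <- if (bonferroni) alpha / ncol(p_values) else alpha
  colMeans(p_values < thr)
}

#' Empirical false-selection rate under the null
#'
#' Percentage of (pathway, replicate) pairs in which a pathway entered the
#' tuned model although the phenotype was generated independently of the
#' genotypes, plus the number of replicates with an empty (offset-only)
#' model.
#'
#' @param selections list of selected-pathway vectors from null replicates.
#' @param n_pathways size of the pathway universe.
#' @return List with `rate` (percent), `n_selections`, `n_empty`,
#'   `n_replicates`.
#' @export
false_selection_rate <- function(selections, n_pathways) {
  n_rep <- length(selections)
  if (!n_rep) stop("need at least one replicate")
  counts <- vapply(selections, length, 1L)
  list(rate = 100 * sum(counts) / (n_pathways * n_rep),
       n_selections = sum(counts),
       n_empty = sum(counts == 0L),
       n_replicates = n_rep)
}

#' Optimal classification cut point by the Youden index
#'
#' Scans candidate thresholds (midpoints between consecutive observed
#' probabilities, plus one below and one above the observed range) and
#' returns the cut maximizing J = sensitivity + specificity - 1.
#'
#' @param y binary phenotype vector.
#' @param p_hat predicted case probabilities.
#' @return List with `cut` and `J`.
#' @export
youden_cutpoint <- function(y, p_hat) {
  y <- check_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  u <- sort(unique(p_hat))
  if (length(u) == 1) {
    warning("constant predictions: no informative cut point")
    return(list(cut = u, J = 0))
  }
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  J <- vapply(cuts, function(ct) {
    pred <- p_hat > ct
    sum(pred & y == 1) / n1 + sum(!pred & y == 0) / n0 - 1
  }, 0)
  best <- which.max(J)
  list(cut = cuts[best], J = J[best])
}

#' Misclassification rate at a probability cut point
#'
#' @param y binary phenotype vector.
#' @param p_hat predicted case probabilities.
#' @param cut classification threshold; predictions above `cut` are called
#'   cases.
#' @return Fraction of individuals whose thresholded prediction differs from
#'   `y`.
#' @export
misclassification_rate <- function(y, p_hat, cut) {
  y <- check_binary(y)
  mean((p_hat > cut) != (y == 1))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; midranks give the standard tie
#' correction.
#'
#' @param y binary phenotype vector.
#' @param p_hat predicted case probabilities (any monotone score).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, p_hat) {
  y <- check_binary(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(p_hat)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
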