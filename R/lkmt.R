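#' Logistic kernel machine score test for one pathway
#'
#' Single-pathway comparator: tests whether the logistic regression of the
#' case-control status on the (optional) covariates can be improved by a
#' nonparametric pathway effect from the reproducing kernel Hilbert space of
#' K. The variance-component score statistic is
#' \eqn{Q = \frac{1}{2} (y - \hat p)^\top K (y - \hat p)} with \eqn{\hat p}
#' from the covariate-only null model. The default p-value matches the first
#' two moments of Q under the null to a scaled chi-square (Satterthwaite);
#' alternatively a permutation p-value is computed by permuting the null
#' residuals.
#'
#' @param y binary phenotype vector.
#' @param K symmetric positive semidefinite pathway kernel.
#' @param X optional covariate matrix for the null model.
#' @param method `"satterthwaite"` (default) or `"permutation"`.
#' @param n_perm number of permutations for the permutation method.
#' @param seed optional seed for the permutation draw.
#' @return Object of class `lkmt_result` with `Q`, `p_value`, `method` and,
#'   for permutations, `n_perm`.
#' @export
lkmt_score_test <- function(y, K, X = NULL,
                            method = c("satterthwaite", "permutation"),
                            n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  y <- check_binary(y)
  K <- as.matrix(K)
  if (nrow(K) != length(y) || ncol(K) != length(y)) {
    stop("kernel dimension does not match the phenotype length")
  }
  null <- fit_offset_logistic(y, X)
  p0 <- stats::plogis(offset_linear_predictor(null, X, length(y)))
  r <- y - p0
  Q <- 0.5 * drop(crossprod(r, K %*% r))
  if (method == "satterthwaite") {
    v <- p0 * (1 - p0)
    if (is.null(X)) {
      # intercept-only null: P0 = v (I - 11'/n), so P0 K is a centering,
      # which avoids the n^3 product
      CK <- v * sweep(K, 2, colMeans(K))
    } else {
      Xd <- cbind(1, as.matrix(X))
      VX <- v * Xd
      # P0 = V - VX (X'VX)^{-1} X'V, covariance of the null residuals
      P0 <- diag(v) - VX %*% solve(crossprod(Xd, VX), t(VX))
      CK <- P0 %*% K
    }
    eQ <- sum(diag(CK)) / 2
    vQ <- sum(CK * t(CK)) / 2
    if (eQ <= 0 || vQ <= 0) {
      # degenerate kernel (e.g. K = 0): no evidence against the null
      p <- 1
    } else {
      kappa <- vQ / (2 * eQ)
      df <- 2 * eQ^2 / vQ
      p <- stats::pchisq(Q / kappa, df = df, lower.tail = FALSE)
    }
    structure(list(Q = Q, p_value = p, method = method), class = "lkmt_result")
  } else {
    if (!is.null(seed)) set.seed(seed)
    R <- vapply(seq_len(n_perm), function(i) sample(r), numeric(length(r)))
    Qp <- colSums(R * (K %*% R)) / 2
    p <- (1 + sum(Qp >= Q)) / (1 + n_perm)
    structure(list(Q = Q, p_value = p, method = method, n_perm = n_perm),
              class = "lkmt_result")
  }
}

#' @export
print.lkmt_result <- function(x, ...) {
  cat(sprintf("LKMT score test: Q = %.4g, p = %.4g (%s%s)\n", x$Q, x$p_value,
              x$method,
              if (!is.null(x$n_perm)) sprintf(", %d permutations", x$n_perm) else ""))
  invisible(x)
}

#' LKMT across a list of pathway kernels
#'
#' Applies [lkmt_score_test()] to every pathway and adds a Bonferroni
#' significance flag at level `alpha / P`.
#'
#' @param y binary phenotype vector.
#' @param learners named list of [kernel_base_learner()] objects or of
#'   kernel matrices.
#' @param X optional covariate matrix.
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame with columns `pathway`, `Q`, `p_value`, `bonferroni`.
#' @export
lkmt_pathways <- function(y, learners, X = NULL, alpha = 0.05) {
  ids <- names(learners)
  if (is.null(ids)) ids <- paste0("pathway", seq_along(learners))
  res <- lapply(learners, function(l) {
    K <- if (inherits(l, "kernel_base_learner")) l$K else as.matrix(l)
    lkmt_score_test(y, K, X = X)
  })
  thr <- alpha / length(learners)
  data.frame(
    pathway = ids,
    Q = vapply(res, `[[`, 0, "Q"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    bonferroni = vapply(res, `[[`, 0, "p_value") < thr,
    row.names = NULL
  )
}
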