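#' Logistic offset model for environmental covariates
#'
#' Fits the mandatory covariate model whose linear predictor initializes the
#' boosting fit, so that pathway effects are estimated on top of (rather than
#' in competition with) the environmental effects. Without covariates this is
#' the intercept-only model \eqn{\beta_0 = logit(\bar y)}.
#'
#' @param y binary phenotype vector (0 = control, 1 = case), both classes
#'   present.
#' @param X optional numeric covariate matrix (one row per individual,
#'   intercept excluded).
#' @return Object of class `covariate_offset_model` with elements `beta`
#'   (named coefficient vector, intercept first) and `covariates`.
#' @export
fit_offset_logistic <- function(y, X = NULL) {
  y <- check_binary(y)
  if (length(unique(y)) < 2) {
    stop("phenotype must contain both cases and controls")
  }
  if (is.null(X)) {
    beta <- c("(Intercept)" = stats::qlogis(mean(y)))
    covs <- character()
  } else {
    X <- as.matrix(X)
    if (nrow(X) != length(y)) stop("covariate rows must match the phenotype length")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    Xd <- cbind("(Intercept)" = 1, X)
    fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
    mu <- fit$fitted.values
    if (!fit$converged || any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
      stop(paste("offset logistic regression did not converge (possible perfect",
                 "separation); remove or regularize the offending covariate upstream"))
    }
    beta <- fit$coefficients
    if (any(!is.finite(beta))) stop("offset model produced non-finite coefficients")
    covs <- colnames(X)
  }
  structure(list(beta = beta, covariates = covs),
            class = "covariate_offset_model")
}

# Linear predictor of the offset model for n individuals.
offset_linear_predictor <- function(model, X = NULL, n) {
  stopifnot(inherits(model, "covariate_offset_model"))
  if (length(model$covariates)) {
    if (is.null(X)) {
      stop("the fitted offset model uses covariates; supply the covariate matrix")
    }
    X <- as.matrix(X)
    missing <- setdiff(model$covariates, colnames(X))
    if (length(missing)) {
      stop(sprintf("missing covariates: %s", paste(missing, collapse = ", ")))
    }
    drop(model$beta[1] + X[, model$covariates, drop = FALSE] %*% model$beta[-1])
  } else {
    rep(unname(model$beta[1]), n)
  }
}

#' Negative gradient of the binomial loss
#'
#' For the negative binomial log-likelihood loss with y coded 0/1 on the
#' logit scale, the negative gradient evaluated at the current additive
#' predictor is \eqn{u_i = y_i - expit(\eta_i)}: the working residual that
#' every base-learner is fitted to in a boosting iteration.
#'
#' @param y binary phenotype vector.
#' @param eta additive predictor (finite).
#' @return Numeric vector of the same length.
#' @export
negative_gradient <- function(y, eta) {
  y <- check_binary(y)
  if (any(!is.finite(eta))) stop("eta must be finite")
  y - stats::plogis(eta)
}

#' Component-wise gradient boosting with kernel base-learners
#'
#' Runs the functional gradient descent: starting from the offset linear
#' predictor, each iteration computes the negative gradient of the binomial
#' loss, fits every kernel base-learner to it by penalized least squares,
#' selects the learner with the smallest residual sum of squares (smallest
#' index on ties), and adds `nu` times its fit to the additive predictor and
#' to the winner's aggregated function estimate; all other estimates remain
#' unchanged.
#'
#' @param y binary phenotype vector.
#' @param learners list of [kernel_base_learner()] objects (the candidate
#'   pathways), all built on the same individuals as `y`.
#' @param offset optional fitted [fit_offset_logistic()] model; fitted from
#'   `y` and `X` when omitted.
#' @param X optional covariate matrix for the offset model.
#' @param nu step length in (0, 1]; 0.1 is the conventional default.
#' @param m_stop number of boosting iterations (>= 0; 0 yields the
#'   offset-only model).
#' @param trace if `TRUE`, log one line per iteration
#'   (`iteration, selected_pathway, rss, risk`).
#' @return Object of class `boost_fit` with the offset model, step length,
#'   `selection_path`, per-pathway aggregated estimates `fhat` (n x P), the
#'   training predictor `eta_train`, the empirical risk path and the updated
#'   learners.
#' @export
boost <- function(y, learners, offset = NULL, X = NULL, nu = 0.1, m_stop,
                  trace = FALSE) {
  y <- check_binary(y)
  if (!length(learners)) stop("need at least one base-learner")
  if (!all(vapply(learners, inherits, TRUE, "kernel_base_learner"))) {
    stop("'learners' must be kernel_base_learner objects")
  }
  if (nu <= 0 || nu > 1) stop("step length nu must be in (0, 1]")
  m_stop <- as.integer(m_stop)
  if (m_stop < 0) stop("m_stop must be >= 0")
  n <- length(y)
  if (any(vapply(learners, function(l) nrow(l$K), 1L) != n)) {
    stop("base-learner kernels do not match the phenotype length")
  }
  ids <- unname(vapply(learners, `[[`, "", "id"))
  P <- length(learners)
  if (is.null(offset)) offset <- fit_offset_logistic(y, X)
  eta0 <- offset_linear_predictor(offset, X, n)
  eta <- eta0
  fhat <- matrix(0, n, P, dimnames = list(NULL, ids))
  path <- integer(m_stop)
  risk <- numeric(m_stop + 1)
  risk[1] <- empirical_risk(y, eta)
  for (m in seq_len(m_stop)) {
    u <- y - stats::plogis(eta)
    uu <- sum(u^2)
    rss <- vapply(learners, learner_rss, 0, u = u, uu = uu)
    best <- which.min(rss)                 # ties resolve to the smallest index
    fit <- fit_base_learner(learners[[best]], u)
    learners[[best]]$cagg <- learners[[best]]$cagg + nu * fit$coef
    learners[[best]]$n_selected <- learners[[best]]$n_selected + 1L
    fhat[, best] <- fhat[, best] + nu * fit$fitted
    eta <- eta + nu * fit$fitted
    path[m] <- best
    risk[m + 1] <- empirical_risk(y, eta)
    if (trace) {
      message(sprintf("iteration=%d selected_pathway=%s rss=%.6g risk=%.6g",
                      m, ids[best], fit$rss, risk[m + 1]))
    }
  }
  # coefficients mapped back through K^{-1/2}: f*(new) = rho * K_new %*% alpha
  for (p in seq_len(P)) {
    learners[[p]]$alpha <- drop(learners[[p]]$V %*%
                                  (learners[[p]]$cagg / sqrt(learners[[p]]$d)))
  }
  structure(list(
    offset = offset, nu = nu, m_stop = m_stop,
    selection_path = path, pathway_ids = ids,
    learners = learners, fhat = fhat,
    eta_offset = eta0, eta_train = eta, risk_path = risk, y = y
  ), class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  sel <- selected_pathways(x)
  cat(sprintf("Kernel boosting fit: n = %d, %d pathways, m_stop = %d, nu = %g\n",
              length(x$y), length(x$pathway_ids), x$m_stop, x$nu))
  cat(sprintf("Selected pathways (%d): %s\n", length(sel),
              if (length(sel)) paste(sel, collapse = ", ") else "none"))
  invisible(x)
}

#' Pathways selected by a boosting fit
#'
#' @param fit a [boost_fit][boost()] object.
#' @return Character vector of pathway ids selected at least once within the
#'   fitted `m_stop` iterations (empty for the offset-only model).
#' @export
selected_pathways <- function(fit) {
  stopifnot(inherits(fit, "boost_fit"))
  fit$pathway_ids[sort(unique(fit$selection_path))]
}

# Smallest m attaining the minimum of a (0..m_max) mean risk curve.
choose_mstop <- function(mean_risk) {
  which.min(mean_risk) - 1L
}

#' Tune the number of boosting iterations by stratified subsampling
#'
#' For each fold, draws `floor(fraction * n)` individuals without
#' replacement, stratified by case status, refits the offset model and all
#' base-learners on the subsample (kernels are subset and recalibrated to the
#' same degrees of freedom), runs the boosting path to `m_max`, and evaluates
#' the mean negative binomial log-likelihood on the held-out individuals at
#' every `m` in `0..m_max`. The optimal `m_stop` minimizes the fold-mean risk
#' curve; ties resolve to the smallest `m`, and `m = 0` (the offset-only,
#' empty model) is part of the grid.
#'
#' @inheritParams boost
#' @param m_max largest number of iterations explored.
#' @param n_folds number of subsampling folds (>= 2).
#' @param fraction subsampling fraction in (0, 1).
#' @param seed optional integer seed for the fold draws.
#' @return Object of class `cv_result` with the fold risk matrix `risk`
#'   (`n_folds` x `m_max + 1`), `mean_risk`, `m_stop_opt`, the fold index
#'   sets and the tuning parameters.
#' @export
tune_mstop <- function(y, learners, offset = NULL, X = NULL, nu = 0.1,
                       m_max = 200, n_folds = 20, fraction = 0.5,
                       seed = NULL) {
  y <- check_binary(y)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  n1 <- floor(fraction * length(idx1))
  n0 <- floor(fraction * length(idx0))
  if (n1 < 1 || n0 < 1) {
    stop("stratified subsample would lack one of the classes; increase fraction or n")
  }
  P <- length(learners)
  risk <- matrix(NA_real_, n_folds, m_max + 1)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    ins <- sort(c(idx1[sample.int(length(idx1), n1)],
                  idx0[sample.int(length(idx0), n0)]))
    out <- setdiff(seq_len(n), ins)
    if (length(unique(y[out])) < 2) {
      stop("held-out set lacks one of the classes; use a smaller fraction")
    }
    folds[[f]] <- ins
    sub <- lapply(learners, function(bl) {
      kernel_base_learner(bl$K_raw[ins, ins], bl$id, df_target = bl$df_target,
                          tol_rel = bl$tol_rel, df_method = bl$df_method)
    })
    Xin <- if (is.null(X)) NULL else as.matrix(X)[ins, , drop = FALSE]
    Xout <- if (is.null(X)) NULL else as.matrix(X)[out, , drop = FALSE]
    off_f <- fit_offset_logistic(y[ins], Xin)
    eta_in <- offset_linear_predictor(off_f, Xin, length(ins))
    eta_out <- offset_linear_predictor(off_f, Xout, length(out))
    # held-out projections: f_out = rho * K_raw[out, in] V diag(1/(d+lambda)) a
    U <- lapply(seq_len(P), function(p) {
      sub[[p]]$rho * (learners[[p]]$K_raw[out, ins, drop = FALSE] %*% sub[[p]]$V)
    })
    yin <- y[ins]; yout <- y[out]
    risk[f, 1] <- empirical_risk(yout, eta_out)
    for (m in seq_len(m_max)) {
      u <- yin - stats::plogis(eta_in)
      uu <- sum(u^2)
      rss <- vapply(sub, learner_rss, 0, u = u, uu = uu)
      best <- which.min(rss)
      fit <- fit_base_learner(sub[[best]], u)
      eta_in <- eta_in + nu * fit$fitted
      eta_out <- eta_out +
        nu * drop(U[[best]] %*% (fit$coef / sqrt(sub[[best]]$d)))
      risk[f, m + 1] <- empirical_risk(yout, eta_out)
    }
  }
  mean_risk <- colMeans(risk)
  structure(list(
    risk = risk, mean_risk = mean_risk,
    m_stop_opt = choose_mstop(mean_risk),
    folds = folds, nu = nu, m_max = m_max, n_folds = n_folds,
    fraction = fraction, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Subsampling risk over m = 0..%d (%d folds, fraction %g): m_stop_opt = %d\n",
              x$m_max, x$n_folds, x$fraction, x$m_stop_opt))
  invisible(x)
}

#' Fit a subsampling-tuned kernel boosting model
#'
#' Convenience wrapper: tunes `m_stop` with [tune_mstop()] and refits the
#' model on the full data at the tuned stopping iteration.
#'
#' @inheritParams tune_mstop
#' @return A [boost_fit][boost()] with the `cv_result` attached as `$cv`.
#' @export
kernel_boost_cv <- function(y, learners, X = NULL, nu = 0.1, m_max = 200,
                            n_folds = 20, fraction = 0.5, seed = NULL) {
  cv <- tune_mstop(y, learners, X = X, nu = nu, m_max = m_max,
                   n_folds = n_folds, fraction = fraction, seed = seed)
  fit <- boost(y, learners, X = X, nu = nu, m_stop = cv$m_stop_opt)
  fit$cv <- cv
  fit
}

#' Predict case probabilities for new individuals
#'
#' Computes \eqn{\eta^* = X^* \beta + \sum_p K^*_p \hat\gamma_p} and returns
#' `expit(eta*)`. The per-pathway coefficient vector is the accumulated
#' `nu`-weighted sum over all iterations in which the pathway was selected,
#' mapped back through \eqn{K^{-1/2}}; prediction kernels are built from the
#' pathway metadata stored at fitting time, or can be supplied directly.
#'
#' @param fit a fitted [boost_fit][boost()] (or a model restored by
#'   [load_model()]).
#' @param Z_new genotype matrix of the individuals to predict, covering the
#'   training SNPs by name; required unless `Kstar` is given.
#' @param X_new covariate matrix, required when the offset model uses
#'   covariates.
#' @param Kstar optional named list of precomputed prediction kernels
#'   (n_new x n_train), one per pathway, overriding `Z_new`.
#' @return Numeric vector of predicted case probabilities.
#' @export
predict_proba <- function(fit, Z_new = NULL, X_new = NULL, Kstar = NULL) {
  stopifnot(inherits(fit, "boost_fit"))
  if (is.null(Z_new) && is.null(Kstar)) {
    stop("supply new genotypes (Z_new) or precomputed prediction kernels (Kstar)")
  }
  n_new <- if (!is.null(Z_new)) nrow(as.matrix(Z_new)) else nrow(Kstar[[1]])
  eta <- offset_linear_predictor(fit$offset, X_new, n_new)
  for (p in seq_along(fit$learners)) {
    bl <- fit$learners[[p]]
    if (all(bl$alpha == 0)) next
    if (!is.null(Kstar)) {
      Ks <- Kstar[[if (!is.null(names(Kstar))) bl$id else p]]
      if (is.null(Ks)) stop(sprintf("no prediction kernel for pathway '%s'", bl$id))
    } else {
      if (is.null(bl$meta)) {
        stop("fit has no pathway metadata; supply Kstar explicitly")
      }
      Zp <- as.matrix(Z_new)
      missing <- setdiff(bl$meta$snp_ids, colnames(Zp))
      if (length(missing)) {
        stop(sprintf("new genotypes lack %d SNPs of pathway '%s' (e.g. %s)",
                     length(missing), bl$id, missing[1]))
      }
      Ks <- (Zp[, bl$meta$snp_ids, drop = FALSE] %*% bl$meta$A) %*% bl$meta$NB
    }
    eta <- eta + bl$rho * drop(Ks %*% bl$alpha)
  }
  stats::plogis(eta)
}

#' @export
fitted.boost_fit <- function(object, ...) {
  stats::plogis(object$eta_train)
}
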