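#' Validate a genotype matrix of minor-allele counts
#'
#' Checks that a matrix contains only 0/1/2 minor-allele counts with no
#' missing values and carries SNP column names. Imputation of missing
#' genotypes is an upstream concern and deliberately not handled here.
#'
#' @param Z numeric matrix, individuals in rows, SNPs in columns.
#' @return The validated matrix (integer storage).
#' @export
validate_genotypes <- function(Z) {
  Z <- as.matrix(Z)
  if (anyNA(Z)) {
    bad <- which(is.na(Z), arr.ind = TRUE)
    stop(sprintf(
      "genotype matrix contains missing values (first at row %d, column %d); impute upstream",
      bad[1, 1], bad[1, 2]))
  }
  if (!all(Z %in% c(0, 1, 2))) {
    bad <- which(!(Z %in% c(0, 1, 2)))[1]
    idx <- arrayInd(bad, dim(Z))
    stop(sprintf("genotype entries must be minor-allele counts 0/1/2 (row %d, column %d is %s)",
                 idx[1], idx[2], format(Z[bad])))
  }
  storage.mode(Z) <- "integer"
  Z
}

#' Network-based pathway kernel
#'
#' Computes the genetic-similarity kernel \eqn{K = Z A N A^\top Z^\top}
#' combining genotypes Z, the SNP-gene mapping matrix A and the prepared
#' (symmetric, PSD-shifted) signed network adjacency N. Entry (i, j) is
#' interpreted as the pathway-specific genetic similarity of individuals i
#' and j.
#'
#' @param Z genotype matrix (n x n_s minor-allele counts).
#' @param A mapping matrix from [build_mapping_matrix()] (n_s x n_g).
#' @param N prepared network adjacency: a [signed_gene_network()] or an
#'   n_g x n_g symmetric matrix.
#' @return Symmetric n x n kernel matrix.
#' @export
network_kernel <- function(Z, A, N) {
  Z <- as.matrix(Z)
  A <- as.matrix(A)
  Nm <- if (inherits(N, "signed_gene_network")) N$adjacency else as.matrix(N)
  if (ncol(Z) != nrow(A)) stop("Z and A dimensions do not conform")
  if (ncol(A) != nrow(Nm) || nrow(Nm) != ncol(Nm)) {
    stop("A and N dimensions do not conform")
  }
  if (!isSymmetric(unname(Nm), tol = 1e-8)) {
    stop("network adjacency must be symmetric; run symmetrize_adjacency() first")
  }
  B <- Z %*% A
  K <- B %*% Nm %*% t(B)
  K <- (K + t(K)) / 2                     # exact symmetry despite round-off
  rownames(K) <- colnames(K) <- rownames(Z)
  K
}

#' Repair numerical PSD violations of a kernel matrix
#'
#' A theoretically positive semidefinite kernel can acquire slightly negative
#' eigenvalues through floating-point round-off. When the smallest eigenvalue
#' drops below `-tol`, the same eigenvalue-shift transformation used for the
#' network adjacency is applied: `rho * K + (1 - rho) * I` with
#' `rho = 1 / (1 - lambda_min)`. Otherwise the kernel is returned unchanged.
#'
#' @param K symmetric kernel matrix.
#' @param tol numerical PSD tolerance (default 1e-8).
#' @return List with `K` (possibly shifted kernel) and `rho` (the weight
#'   applied; 1 when no repair was necessary).
#' @export
ensure_psd_kernel <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-6)) {
    stop("kernel matrix must be symmetric")
  }
  lmin <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < -tol) {
    rho <- 1 / (1 - lmin)
    out <- rho * K + (1 - rho) * diag(nrow(K))
    dimnames(out) <- dimnames(K)
    list(K = out, rho = rho)
  } else {
    list(K = K, rho = 1)
  }
}

#' Inverse square root of a kernel matrix
#'
#' Computes \eqn{M = K^{-1/2}} on the numerically non-zero eigenspace of K,
#' so that the transformed design \eqn{\tilde K = K M} satisfies
#' \eqn{\tilde K \tilde K^\top \approx K} on the retained rank. Eigenvalues
#' at or below `tol_rel` times the largest eigenvalue are treated as zero and
#' excluded, the standard pseudo-inverse truncation for rank-deficient
#' kernels.
#'
#' @param K symmetric positive semidefinite matrix (run
#'   [ensure_psd_kernel()] first).
#' @param tol_rel relative eigenvalue truncation tolerance.
#' @return List with `M` (the inverse square root), `rank` (retained rank),
#'   `values`/`vectors` (the retained eigenpairs) and `tol_rel`.
#' @export
kernel_sqrt_inv <- function(K, tol_rel = 1e-10) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-6)) {
    stop("kernel matrix must be symmetric")
  }
  ed <- eigen(K, symmetric = TRUE)
  dmax <- max(ed$values)
  if (dmax <= 0) stop("degenerate kernel: no positive eigenvalue")
  keep <- ed$values > tol_rel * dmax
  if (!any(keep)) stop("degenerate kernel: all eigenvalues numerically zero")
  d <- ed$values[keep]
  V <- ed$vectors[, keep, drop = FALSE]
  M <- V %*% (t(V) / sqrt(d))
  M <- (M + t(M)) / 2
  list(M = M, rank = length(d), values = d, vectors = V, tol_rel = tol_rel)
}

#' Prediction kernel between new and training genotypes
#'
#' Computes \eqn{K^* = Z^* A N A^\top Z^\top}, the pathway similarity between
#' individuals to be predicted (rows) and the training individuals (columns).
#' The result is in general rectangular and need not be positive
#' semidefinite.
#'
#' @param Z_new genotype matrix of new individuals; its SNP columns must be
#'   in the same order as `Z_train`.
#' @param Z_train training genotype matrix.
#' @inheritParams network_kernel
#' @return n_new x n_train numeric matrix.
#' @export
prediction_kernel <- function(Z_new, Z_train, A, N) {
  Z_new <- as.matrix(Z_new)
  Z_train <- as.matrix(Z_train)
  if (ncol(Z_new) != ncol(Z_train)) {
    stop("new and training genotypes must cover the same SNPs")
  }
  if (!is.null(colnames(Z_new)) && !is.null(colnames(Z_train)) &&
      !identical(colnames(Z_new), colnames(Z_train))) {
    stop("SNP order of new genotypes does not match the training data")
  }
  A <- as.matrix(A)
  Nm <- if (inherits(N, "signed_gene_network")) N$adjacency else as.matrix(N)
  (Z_new %*% A) %*% Nm %*% t(Z_train %*% A)
}
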