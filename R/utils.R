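# Internal numerical helpers shared across modules.

# log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out[!small] <- x[!small] + log1p(exp(-x[!small]))
  out
}

# Empirical risk: mean negative binomial log-likelihood on the logit scale.
empirical_risk <- function(y, eta) {
  mean(log1pexp(eta) - y * eta)
}

check_binary <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("phenotype must be coded 0 (control) / 1 (case) without missing values")
  }
  y
}

# format doubles so that as.numeric() round-trips bit-identically
num17 <- function(x) sprintf("%.17g", as.numeric(x))

mat_to_list <- function(m) {
  list(dim = dim(m), data = num17(m),
       rownames = rownames(m), colnames = colnames(m))
}

list_to_mat <- function(l) {
  m <- matrix(as.numeric(unlist(l$data)), nrow = l$dim[1], ncol = l$dim[2])
  rn <- unlist(l$rownames)
  cn <- unlist(l$colnames)
  if (length(rn)) rownames(m) <- rn
  if (length(cn)) colnames(m) <- cn
  m
}
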