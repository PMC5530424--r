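# Shared fixture builders; everything is generated in code under fixed seeds.

# Small random PSD matrix with dominant-rank structure.
random_psd <- function(n, rank = n, jitter = 0) {
  A <- matrix(rnorm(n * rank), n, rank)
  K <- tcrossprod(A)
  if (jitter > 0) K <- K + jitter * diag(n)
  (K + t(K)) / 2
}

# Tiny complete study: networks + genotypes + phenotype + learners.
tiny_study <- function(n = 120, P = 3, genes = 8, snps = 3, seed = 1,
                       df_target = 3) {
  set.seed(seed)
  sc <- simulate_scenario("null", n = n, n_pathways = P,
                          genes_per_pathway = genes, snps_per_gene = snps,
                          density = 0.3)
  bl <- pathway_kernels(sc$Z, sc$annotation, sc$networks,
                        df_target = df_target)
  list(sc = sc, bl = bl, y = sc$y, Z = sc$Z)
}

# Independent elimination oracle for rewiring: removes one gene at a time
# with the multiplicative rule, written as plain index loops.
rewire_oracle <- function(N, keep) {
  genes <- colnames(N)
  for (g in setdiff(genes, keep)) {
    i <- match(g, colnames(N))
    nb <- which(N[i, ] != 0)
    nb <- nb[nb != i]
    if (length(nb) >= 2) {
      for (a in nb) for (b in nb) {
        if (a < b && N[a, b] == 0) {
          N[a, b] <- N[a, i] * N[i, b]
          N[b, a] <- N[a, b]
        }
      }
    }
    N <- N[-i, -i, drop = FALSE]
  }
  N[keep, keep, drop = FALSE]
}
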