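test_that("mapping matrix applies the 1/sqrt(m_g) gene-size adjustment", {
  net <- signed_gene_network(matrix(0, 3, 3), genes = c("gA", "gB", "gC"))
  ann <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    gene_id = c("gA", rep("gB", 4), "nowhere")
  )
  A <- build_mapping_matrix(ann, net, snp_order = paste0("s", 1:6))
  expect_equal(A["s1", "gA"], 1.0)                 # single-SNP gene
  expect_equal(unname(A[paste0("s", 2:5), "gB"]), rep(0.5, 4))
  expect_equal(unname(A["s6", ]), rep(0, 3))       # unannotated SNP row
  expect_identical(attr(A, "unrepresented"), "gC")
  # unit column norms for represented genes
  norms <- colSums(A^2)
  expect_equal(unname(norms[c("gA", "gB")]), c(1, 1))
  expect_error(
    build_mapping_matrix(data.frame(snp_id = "sX", gene_id = "gX"), net, "s1"),
    "empty overlap")
})

test_that("a SNP may map to several overlapping genes by position", {
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(150L, 500L))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                      start = c(100L, 140L), end = c(200L, 240L))
  ann <- annotate_snps(snps, genes)
  expect_setequal(ann$map$gene_id[ann$map$snp_id == "s1"], c("g1", "g2"))
  expect_false("s2" %in% ann$map$snp_id)
  # the flank pulls s2 into g2's extended region
  ann_fl <- annotate_snps(snps, genes, flank = 300)
  expect_true(any(ann_fl$map$snp_id == "s2" & ann_fl$map$gene_id == "g2"))
  expect_error(annotate_snps(snps, transform(genes, start = end + 1)),
               "start > end")
})

test_that("symmetrization mirrors entries and resolves conflicts upper-first", {
  N <- matrix(0, 3, 3)
  N[1, 2] <- 1
  net <- symmetrize_adjacency(signed_gene_network(N))
  expect_equal(net$adjacency[2, 1], 1)
  expect_equal(net$adjacency[1, 2], 1)

  sym <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(symmetrize_adjacency(signed_gene_network(sym))$adjacency,
                   signed_gene_network(sym)$adjacency)

  conf <- matrix(0, 2, 2)
  conf[1, 2] <- 1; conf[2, 1] <- -1
  out <- symmetrize_adjacency(signed_gene_network(conf))$adjacency
  expect_equal(unname(out), matrix(c(0, 1, 1, 0), 2))
})

test_that("rewiring multiplies dropped link weights and keeps existing links", {
  # chain a -(+1)- g -(-1)- b with g unrepresented
  N <- matrix(0, 3, 3, dimnames = list(c("a", "g", "b"), c("a", "g", "b")))
  N["a", "g"] <- N["g", "a"] <- 1
  N["g", "b"] <- N["b", "g"] <- -1
  out <- prune_and_rewire(signed_gene_network(N), c("a", "b"))
  expect_equal(out$adjacency["a", "b"], -1)

  # degree-1 unrepresented gene: simply removed
  N1 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "g"), c("a", "b", "g")))
  N1["a", "b"] <- N1["b", "a"] <- 1
  N1["b", "g"] <- N1["g", "b"] <- 1
  out1 <- prune_and_rewire(signed_gene_network(N1), c("a", "b"))
  expect_equal(sum(out1$adjacency != 0), 2)

  # two removed genes in a chain, all +1: a-b link with weight +1
  N2 <- matrix(0, 4, 4, dimnames = rep(list(c("a", "g1", "g2", "b")), 2))
  N2["a", "g1"] <- N2["g1", "a"] <- 1
  N2["g1", "g2"] <- N2["g2", "g1"] <- 1
  N2["g2", "b"] <- N2["b", "g2"] <- 1
  out2 <- prune_and_rewire(signed_gene_network(N2), c("a", "b"))
  expect_equal(out2$adjacency["a", "b"], 1)
  expect_equal(out2$adjacency,
               rewire_oracle(N2, c("a", "b")))

  # an existing direct link is never overwritten
  N3 <- N
  N3["a", "b"] <- N3["b", "a"] <- 1
  out3 <- prune_and_rewire(signed_gene_network(N3), c("a", "b"))
  expect_equal(out3$adjacency["a", "b"], 1)
})

test_that("rewiring matches the elimination oracle on random signed graphs", {
  set.seed(42)
  for (rep in 1:20) {
    ng <- sample(4:7, 1)
    genes <- paste0("g", seq_len(ng))
    N <- matrix(0, ng, ng, dimnames = list(genes, genes))
    up <- which(upper.tri(N))
    on <- up[runif(length(up)) < 0.5]
    N[on] <- sample(c(-1, 1), length(on), replace = TRUE)
    N <- N + t(N)
    keep <- sort(sample(genes, sample(2:(ng - 1), 1)))
    got <- prune_and_rewire(signed_gene_network(N), keep)$adjacency
    expect_equal(got, rewire_oracle(N, keep))
  }
})

test_that("rewiring sign pattern is removal-order invariant on unique-path graphs", {
  # star of chains: every 2-step path through a removed gene is unique
  genes <- c("c", "m1", "m2", "l1", "l2")
  N <- matrix(0, 5, 5, dimnames = list(genes, genes))
  N["c", "m1"] <- N["m1", "c"] <- 1
  N["m1", "l1"] <- N["l1", "m1"] <- -1
  N["c", "m2"] <- N["m2", "c"] <- -1
  N["m2", "l2"] <- N["l2", "m2"] <- -1
  keep <- c("c", "l1", "l2")
  ref <- prune_and_rewire(signed_gene_network(N), keep)$adjacency
  for (ord in list(c(5, 4, 3, 2, 1), c(2, 4, 1, 3, 5))) {
    perm <- genes[ord]
    got <- prune_and_rewire(
      signed_gene_network(N[perm, perm], perm), keep)$adjacency
    expect_equal(got[keep, keep], ref[keep, keep])
  }
})

test_that("eigenvalue shift maps the smallest eigenvalue to zero", {
  I3 <- diag(3)
  res <- psd_shift_matrix(I3)
  expect_identical(res$matrix, I3)
  expect_equal(res$rho, 1)

  M <- matrix(c(0, 1, 1, 0), 2)
  res <- psd_shift_matrix(M)
  expect_equal(res$rho, 0.5)
  expect_equal(unname(res$matrix), matrix(0.5, 2, 2))
  expect_equal(sort(eigen(res$matrix)$values), c(0, 1))

  expect_error(psd_shift_matrix(matrix(1:4, 2)), "symmetric")
})

test_that("shifted eigenvalues equal rho * lambda + (1 - rho)", {
  set.seed(7)
  for (rep in 1:10) {
    M <- matrix(rnorm(100), 10); M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    res <- psd_shift_matrix(M)
    got <- eigen(res$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(got, res$rho * ev + (1 - res$rho), tolerance = 1e-10)
    expect_gte(min(got), -1e-8)
  }
})

test_that("network descriptors match hand counts on canonical graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  s <- network_summary(signed_gene_network(tri))
  expect_equal(s$transitivity, 1)
  expect_equal(s$density, 1)
  expect_equal(s$diameter, 1)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  s <- network_summary(signed_gene_network(path3))
  expect_equal(s$transitivity, 0)
  expect_equal(s$diameter, 2)

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  s <- network_summary(signed_gene_network(star))
  expect_equal(s$average_degree, 1.5)
  expect_equal(s$diameter, 2)

  # one inhibiting edge in a triangle flips every closed triplet's sign
  tri_neg <- tri; tri_neg[1, 2] <- tri_neg[2, 1] <- -1
  s <- network_summary(signed_gene_network(tri_neg))
  expect_equal(s$transitivity, 1)
  expect_equal(s$signed_transitivity, -1)
  expect_equal(s$inhibition_links, 1)

  expect_error(network_summary(signed_gene_network(matrix(0, 0, 0))), "empty")
})
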