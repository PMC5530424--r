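#' Simulate pseudogene genotypes with within-gene LD
#'
#' Generates minor-allele-count genotypes for blocks of SNPs ("pseudogenes").
#' For each gene, per-SNP minor allele frequencies are drawn uniformly from
#' `maf_range` (unless supplied), and two haplotypes per individual are drawn
#' from a Gaussian copula with AR(1) correlation `ld_rho` between adjacent
#' SNPs of the gene, thresholded at the MAF quantile and summed. Genes are
#' mutually independent, emulating the large inter-gene distances used to
#' avoid LD leakage between genes.
#'
#' @param n number of individuals.
#' @param gene_layout named integer vector: number of SNPs per gene id.
#' @param maf_range length-2 numeric in (0, 0.5], the MAF sampling range.
#' @param ld_rho AR(1) haplotype correlation within a gene, in `[0, 1)`.
#' @param maf optional named per-SNP MAF vector (names `<gene>_s<j>`)
#'   overriding the uniform draw; used to keep frequencies fixed across
#'   batches of a rejection sampler.
#' @param seed optional integer seed.
#' @return Integer genotype matrix (n x total SNPs) with attributes
#'   `annotation` (data frame `snp_id`, `gene_id`) and `maf`.
#' @export
simulate_genotypes <- function(n, gene_layout, maf_range = c(0.05, 0.5),
                               ld_rho = 0.5, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(gene_layout)) {
    gene_layout <- stats::setNames(gene_layout$n_snps, gene_layout$gene_id)
  }
  stopifnot(length(gene_layout) >= 1, all(gene_layout >= 1))
  if (min(maf_range) <= 0 || max(maf_range) > 0.5) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  genes <- names(gene_layout)
  blocks <- vector("list", length(genes))
  mafs <- list()
  for (gi in seq_along(genes)) {
    k <- gene_layout[[gi]]
    ids <- paste0(genes[gi], "_s", seq_len(k))
    m <- if (!is.null(maf)) {
      if (!all(ids %in% names(maf))) stop("supplied 'maf' does not cover all SNPs")
      maf[ids]
    } else {
      stats::setNames(stats::runif(k, maf_range[1], maf_range[2]), ids)
    }
    # two haplotypes per individual from an AR(1) Gaussian copula
    E <- matrix(stats::rnorm(2 * n * k), 2 * n, k)
    H <- E
    if (k > 1 && ld_rho > 0) {
      for (j in 2:k) {
        H[, j] <- ld_rho * H[, j - 1] + sqrt(1 - ld_rho^2) * E[, j]
      }
    }
    alle <- sweep(H, 2, stats::qnorm(m), "<") * 1L
    G <- alle[seq_len(n), , drop = FALSE] + alle[n + seq_len(n), , drop = FALSE]
    colnames(G) <- ids
    blocks[[gi]] <- G
    mafs[[gi]] <- m
  }
  Z <- do.call(cbind, blocks)
  storage.mode(Z) <- "integer"
  attr(Z, "annotation") <- data.frame(
    snp_id = colnames(Z),
    gene_id = rep(genes, times = gene_layout),
    stringsAsFactors = FALSE
  )
  attr(Z, "maf") <- unlist(mafs)
  Z
}

#' Null phenotype, independent of all genotypes
#'
#' Case-control status drawn i.i.d. Bernoulli(0.5) with no dependence on the
#' genetic data: the noninformative scenario against which false selections
#' are counted.
#'
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return Integer 0/1 vector of length n.
#' @export
assign_phenotype_null <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  stats::rbinom(n, 1, 0.5)
}

#' Case-control sampling under an additive per-allele effect
#'
#' Assigns each individual in a genotype pool a case probability
#' \eqn{expit(\alpha + \log(rr) \sum_s z_{is})} over the effect SNPs, where
#' the intercept \eqn{\alpha} pins the marginal prevalence (odds ratio
#' approximates relative risk at low prevalence), and retains individuals in
#' pool order until exactly `n_cases` cases and `n_controls` controls are
#' collected.
#'
#' @param Z genotype pool (rows are candidate individuals).
#' @param effect_snps column names (or indices) of the influential SNPs.
#' @param rr_per_allele per-allele relative risk (1 reduces to the null).
#' @param n_cases,n_controls required case and control counts.
#' @param prevalence target marginal disease prevalence (default 0.1).
#' @param alpha optional fixed intercept; estimated from the pool's allele
#'   frequencies when omitted.
#' @param seed optional integer seed.
#' @return List with `Z` (retained rows) and `y`; errors if the pool is
#'   exhausted before the quota is met.
#' @export
assign_phenotype_effect <- function(Z, effect_snps, rr_per_allele,
                                    n_cases, n_controls, prevalence = 0.1,
                                    alpha = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rr_per_allele <= 0) stop("rr_per_allele must be positive")
  Z <- as.matrix(Z)
  Ze <- Z[, effect_snps, drop = FALSE]
  beta <- log(rr_per_allele)
  if (is.null(alpha)) {
    alpha <- stats::qlogis(prevalence) - beta * sum(colMeans(Ze))
  }
  p <- stats::plogis(alpha + beta * rowSums(Ze))
  case <- stats::rbinom(nrow(Z), 1, p)
  ic <- which(case == 1)
  iv <- which(case == 0)
  if (length(ic) < n_cases || length(iv) < n_controls) {
    stop(sprintf(
      "genotype pool exhausted before the quota was met (%d/%d cases, %d/%d controls)",
      length(ic), n_cases, length(iv), n_controls))
  }
  rows <- sort(c(ic[seq_len(n_cases)], iv[seq_len(n_controls)]))
  list(Z = Z[rows, , drop = FALSE], y = case[rows])
}

#' Sample interconnected effect genes from a pathway network
#'
#' Draws one seed gene with probability proportional to its betweenness
#' centrality (genes in topologically central positions are more likely to
#' carry disease effects), restricted to genes with at least `n_neighbours`
#' neighbours, then completes the connected effect set with `n_neighbours`
#' genes drawn uniformly from the seed's adjacency. When all eligible genes
#' have zero betweenness, the seed is drawn uniformly.
#'
#' @param network a [signed_gene_network()] (symmetric).
#' @param n_neighbours number of neighbours added to the seed gene.
#' @param seed optional integer seed.
#' @return Character vector: the seed gene followed by its sampled
#'   neighbours.
#' @export
sample_effect_genes <- function(network, n_neighbours = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(network, "signed_gene_network"))
  B <- (network$adjacency != 0) * 1
  diag(B) <- 0
  deg <- rowSums(B)
  elig <- which(deg >= n_neighbours)
  if (!length(elig)) {
    stop(sprintf("no gene has %d or more neighbours", n_neighbours))
  }
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  btw <- igraph::betweenness(g)
  w <- btw[elig]
  if (all(w == 0)) w <- rep(1, length(elig))
  sg <- elig[sample.int(length(elig), 1, prob = w)]
  nb <- which(B[sg, ] != 0)
  picked <- nb[sample.int(length(nb), n_neighbours)]
  network$genes[c(sg, picked)]
}

#' Generate toy signed pathway networks
#'
#' Erdos-Renyi stand-ins for curated gene-interaction pathways: each pathway
#' is an undirected graph with the requested edge density, a fraction of
#' links marked inhibiting (-1), and gene ids globally unique except for a
#' configurable overlap fraction shared with the previous pathway
#' (`round(overlap_fraction * genes_per_pathway)` genes), emulating the gene
#' overlap of real biological pathways.
#'
#' @param n_pathways number of networks.
#' @param genes_per_pathway genes per network.
#' @param density edge probability in (0, 1].
#' @param inhibition_fraction probability that a link is inhibiting.
#' @param overlap_fraction fraction of a pathway's genes reused from the
#'   previous pathway.
#' @param seed optional integer seed.
#' @return Named list of [signed_gene_network()] objects.
#' @export
make_toy_networks <- function(n_pathways, genes_per_pathway, density = 0.1,
                              inhibition_fraction = 0.14,
                              overlap_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  n_ov <- round(overlap_fraction * genes_per_pathway)
  nets <- vector("list", n_pathways)
  prev_genes <- character()
  for (k in seq_len(n_pathways)) {
    fresh <- sprintf("pw%02d_g%03d",
                     k, seq_len(genes_per_pathway - if (k > 1) n_ov else 0))
    genes <- if (k > 1 && n_ov > 0) {
      c(prev_genes[sample.int(length(prev_genes), n_ov)], fresh)
    } else {
      fresh
    }
    ng <- length(genes)
    N <- matrix(0, ng, ng, dimnames = list(genes, genes))
    up <- which(upper.tri(N))
    on <- up[stats::runif(length(up)) < density]
    signs <- ifelse(stats::runif(length(on)) < inhibition_fraction, -1, 1)
    N[on] <- signs
    N <- N + t(N)
    nets[[k]] <- signed_gene_network(N, genes)
    prev_genes <- genes
  }
  names(nets) <- sprintf("pw%02d", seq_len(n_pathways))
  nets
}

#' Simulate a complete null or effect study
#'
#' Assembles a full synthetic case-control dataset: toy pathway networks,
#' pseudogene genotypes (5 SNPs per gene by default, within-gene LD,
#' independent genes), and a phenotype that is either independent
#' Bernoulli(0.5) (null) or driven by additive per-allele effects of
#' relative risk `rr_per_allele` placed on 2 SNPs in each of 3
#' interconnected, betweenness-sampled genes per causal pathway, with
#' rejection sampling to exact 1:1 case-control quotas.
#'
#' @param scenario `"null"` or `"effect"`.
#' @param n number of individuals for the null scenario.
#' @param n_cases,n_controls case and control counts for the effect
#'   scenario.
#' @param rr_per_allele per-allele relative risk of the effect SNPs.
#' @param n_pathways,genes_per_pathway,snps_per_gene study dimensions.
#' @param n_causal number of causal pathways.
#' @param effect_genes_per_pathway interconnected effect genes per causal
#'   pathway (a seed gene plus its sampled neighbours).
#' @param snps_per_effect_gene influential SNPs per effect gene.
#' @param maf_range,ld_rho,density,inhibition_fraction,overlap_fraction
#'   generator parameters, see [simulate_genotypes()] and
#'   [make_toy_networks()].
#' @param prevalence marginal disease prevalence of the effect model.
#' @param seed optional integer seed; a fixed seed makes the whole scenario
#'   bit-reproducible.
#' @return List with `Z`, `y`, `networks`, `annotation` (data frame),
#'   `maf`, `effect` (causal pathways/genes/SNPs, `NULL` for the null
#'   scenario) and the scenario parameters.
#' @export
simulate_scenario <- function(scenario = c("null", "effect"), n = 1000,
                              n_cases = 500, n_controls = 500,
                              rr_per_allele = 1.5, n_pathways = 10,
                              genes_per_pathway = 30, snps_per_gene = 5,
                              n_causal = 2, effect_genes_per_pathway = 3,
                              snps_per_effect_gene = 2,
                              maf_range = c(0.05, 0.5), ld_rho = 0.5,
                              density = 0.1, inhibition_fraction = 0.14,
                              overlap_fraction = 0, prevalence = 0.1,
                              seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  networks <- make_toy_networks(n_pathways, genes_per_pathway, density,
                                inhibition_fraction, overlap_fraction)
  all_genes <- unique(unlist(lapply(networks, `[[`, "genes")))
  layout <- stats::setNames(rep(snps_per_gene, length(all_genes)), all_genes)
  if (scenario == "null") {
    Z <- simulate_genotypes(n, layout, maf_range, ld_rho)
    y <- assign_phenotype_null(n)
    effect <- NULL
  } else {
    causal <- sort(sample.int(n_pathways, n_causal))
    effect_genes <- lapply(causal, function(k) {
      sample_effect_genes(symmetrize_adjacency(networks[[k]]),
                          n_neighbours = effect_genes_per_pathway - 1)
    })
    maf <- stats::setNames(
      stats::runif(sum(layout), maf_range[1], maf_range[2]),
      paste0(rep(all_genes, times = layout), "_s",
             unlist(lapply(layout, seq_len)))
    )
    effect_snps <- unlist(lapply(unlist(effect_genes), function(g) {
      paste0(g, "_s", sort(sample.int(snps_per_gene, snps_per_effect_gene)))
    }))
    alpha <- stats::qlogis(prevalence) -
      log(rr_per_allele) * sum(2 * maf[effect_snps])
    need <- n_cases + n_controls
    pool_n <- ceiling(1.4 * max(n_cases / prevalence,
                                n_controls / (1 - prevalence), need))
    res <- NULL
    for (try in 1:3) {
      Zpool <- simulate_genotypes(pool_n, layout, maf_range, ld_rho, maf = maf)
      res <- tryCatch(
        assign_phenotype_effect(Zpool, effect_snps, rr_per_allele,
                                n_cases, n_controls, prevalence, alpha = alpha),
        error = function(e) NULL)
      if (!is.null(res)) break
      pool_n <- pool_n * 2
    }
    if (is.null(res)) stop("could not meet the case/control quota; check the effect model")
    ord <- sample.int(need)
    Z <- res$Z[ord, , drop = FALSE]
    attr(Z, "annotation") <- attr(res$Z, "annotation")
    y <- res$y[ord]
    effect <- list(pathways = names(networks)[causal],
                   genes = effect_genes, snps = effect_snps)
  }
  ann <- data.frame(
    snp_id = colnames(Z),
    gene_id = rep(all_genes, times = layout),
    stringsAsFactors = FALSE
  )
  list(Z = Z, y = y, networks = networks, annotation = ann,
       maf = if (scenario == "null") attr(Z, "maf") else maf,
       effect = effect,
       params = list(scenario = scenario, rr_per_allele = rr_per_allele,
                     n_pathways = n_pathways,
                     genes_per_pathway = genes_per_pathway,
                     snps_per_gene = snps_per_gene, ld_rho = ld_rho,
                     maf_range = maf_range, prevalence = prevalence,
                     seed = seed))
}
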