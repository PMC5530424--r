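#' Build kernel base-learners for a set of pathway networks
#'
#' Full preparation pipeline for every pathway: restrict the signed network
#' to genes represented by genotyped, annotated SNPs (rewiring links through
#' removed genes), symmetrize, shift to positive semidefiniteness, build the
#' size-adjusted SNP-gene mapping matrix, assemble the network kernel
#' \eqn{K = Z A N A^\top Z^\top} and wrap it into a df-calibrated
#' [kernel_base_learner()]. Kernels are built once and are immutable
#' afterwards; each learner carries the metadata (SNP ids, A, N) needed to
#' construct prediction kernels for new genotypes.
#'
#' @param Z genotype matrix (minor-allele counts, SNP column names).
#' @param annotation a [gene_annotation()] or data frame with `snp_id`,
#'   `gene_id`.
#' @param networks a named list of [signed_gene_network()] objects (or a
#'   single network).
#' @inheritParams kernel_base_learner
#' @return Named list of `kernel_base_learner` objects. Pathways with no
#'   genotyped gene are dropped with a warning.
#' @export
pathway_kernels <- function(Z, annotation, networks, df_target = 4,
                            tol_rel = 1e-10) {
  Z <- validate_genotypes(Z)
  if (is.null(colnames(Z))) stop("genotype matrix must have SNP column names")
  if (inherits(networks, "signed_gene_network")) networks <- list(pathway = networks)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("pathway", seq_along(networks))
  }
  map <- if (inherits(annotation, "gene_annotation")) annotation$map else
    as.data.frame(annotation)
  map <- map[map$snp_id %in% colnames(Z), , drop = FALSE]
  learners <- list()
  for (nm in names(networks)) {
    net <- networks[[nm]]
    represented <- intersect(net$genes, unique(map$gene_id))
    if (!length(represented)) {
      warning(sprintf("pathway '%s' has no genotyped gene; skipped", nm))
      next
    }
    prep <- prepare_network(net, represented)
    snp_ids <- colnames(Z)[colnames(Z) %in%
                             map$snp_id[map$gene_id %in% prep$network$genes]]
    A <- build_mapping_matrix(map, prep$network, snp_ids)
    Zp <- Z[, snp_ids, drop = FALSE]
    K <- network_kernel(Zp, A, prep$network)
    bl <- kernel_base_learner(K, id = nm, df_target = df_target,
                              tol_rel = tol_rel)
    bl$meta <- list(
      snp_ids = snp_ids,
      A = A,
      N = prep$network$adjacency,
      NB = prep$network$adjacency %*% t(Zp %*% A),  # K* = (Z* A) %*% NB
      rho_network = prep$rho
    )
    learners[[nm]] <- bl
  }
  if (!length(learners)) stop("no pathway could be represented by the genotype data")
  learners
}
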