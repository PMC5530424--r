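#' Signed gene-interaction network
#'
#' Container for a pathway's gene set together with its signed adjacency
#' matrix. Entries are canonically +1 (activation) or -1 (inhibition); links
#' created by [prune_and_rewire()] may carry products of such weights. The
#' diagonal of a raw adjacency is zero.
#'
#' @param adjacency square numeric matrix of signed interactions.
#' @param genes character vector of gene identifiers; defaults to the row
#'   names of `adjacency`.
#' @param directed_input flag recording whether the source edge list was
#'   directed (kept for provenance; all analysis is on the symmetrized graph).
#' @return An object of class `signed_gene_network` with elements `genes`,
#'   `adjacency` and `directed_input`.
#' @export
signed_gene_network <- function(adjacency, genes = NULL, directed_input = FALSE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency matrix must be square")
  }
  if (is.null(genes)) genes <- rownames(adjacency)
  if (is.null(genes)) {
    genes <- as.character(seq_len(nrow(adjacency)))
    if (length(genes)) genes <- paste0("g", genes)
  }
  genes <- as.character(genes)
  if (length(genes) != nrow(adjacency)) {
    stop("length of 'genes' must match the adjacency dimension")
  }
  dimnames(adjacency) <- list(genes, genes)
  structure(list(genes = genes, adjacency = adjacency,
                 directed_input = isTRUE(directed_input)),
            class = "signed_gene_network")
}

#' @export
print.signed_gene_network <- function(x, ...) {
  nl <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("Signed gene network: %d genes, %d links (%s input)\n",
              length(x$genes), nl,
              if (x$directed_input) "directed" else "undirected"))
  invisible(x)
}

#' Mirror a signed adjacency along its diagonal
#'
#' Combines an adjacency with its transpose so that every recorded
#' interaction becomes undirected. Where the two directions disagree in sign,
#' the entry from the upper triangle of the input wins (a deterministic,
#' documented tie rule).
#'
#' @param network a [signed_gene_network()].
#' @return A `signed_gene_network` with symmetric adjacency.
#' @export
symmetrize_adjacency <- function(network) {
  stopifnot(inherits(network, "signed_gene_network"))
  N <- network$adjacency
  Nt <- t(N)
  up <- upper.tri(N)
  merged <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
  # upper-triangle entry takes precedence when both directions are recorded
  merged[up] <- ifelse(N[up] != 0, N[up], Nt[up])
  merged <- merged + t(merged)
  diag(merged) <- diag(N)
  signed_gene_network(merged, network$genes, directed_input = network$directed_input)
}

#' Remove unrepresented genes, rewiring their neighbours
#'
#' Genes without any genotyped SNP cannot enter the kernel. To retain the
#' interaction information that flowed through such a gene, each pair of its
#' neighbours is linked directly with a weight equal to the product of the two
#' dropped link weights. Existing direct links are never overwritten. Genes
#' are eliminated one at a time in the network's gene order, which makes the
#' result deterministic when several rewired candidates compete for the same
#' pair.
#'
#' @param network a symmetric [signed_gene_network()].
#' @param represented_genes character vector of genes that have at least one
#'   annotated SNP; must be a subset of `network$genes`.
#' @return A `signed_gene_network` restricted to the represented genes.
#' @export
prune_and_rewire <- function(network, represented_genes) {
  stopifnot(inherits(network, "signed_gene_network"))
  represented_genes <- as.character(represented_genes)
  if (!all(represented_genes %in% network$genes)) {
    stop("'represented_genes' must be a subset of the network's genes")
  }
  N <- network$adjacency
  drop_genes <- setdiff(network$genes, represented_genes)
  for (g in drop_genes) {
    nb <- colnames(N)[N[g, ] != 0]
    nb <- setdiff(nb, g)
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        if (N[a, b] == 0) {
          w <- N[a, g] * N[g, b]
          N[a, b] <- w
          N[b, a] <- w
        }
      }
    }
    keep <- setdiff(colnames(N), g)
    N <- N[keep, keep, drop = FALSE]
  }
  keep <- intersect(network$genes, represented_genes)
  signed_gene_network(N[keep, keep, drop = FALSE], keep,
                      directed_input = network$directed_input)
}

#' Eigenvalue-shift transformation to positive semidefiniteness
#'
#' Returns `rho * M + (1 - rho) * I` with `rho = 1 / (1 - lambda_min)` when
#' the smallest eigenvalue `lambda_min` is negative, and `rho = 1` (input
#' unchanged) otherwise. This is the largest `rho` that makes the shifted
#' matrix positive semidefinite: the smallest eigenvalue is mapped exactly to
#' zero while as much of the original structure as possible is preserved.
#'
#' @param M symmetric numeric matrix.
#' @param tol symmetry check tolerance.
#' @return A list with elements `matrix` (the shifted matrix) and `rho`.
#' @export
psd_shift_matrix <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (!isSymmetric(unname(M), tol = tol)) {
    stop("psd_shift_matrix() requires a symmetric matrix")
  }
  if (nrow(M) == 0) return(list(matrix = M, rho = 1))
  lmin <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < 0) {
    rho <- 1 / (1 - lmin)
    out <- rho * M + (1 - rho) * diag(nrow(M))
    dimnames(out) <- dimnames(M)
  } else {
    rho <- 1
    out <- M
  }
  list(matrix = out, rho = rho)
}

#' Build the SNP-to-gene mapping matrix
#'
#' Constructs the \eqn{n_s \times n_g} matrix A that maps SNPs to network
#' genes. The entry for SNP s and gene g is \eqn{1/\sqrt{m_g}} if s is
#' annotated to g (with \eqn{m_g} the number of annotated SNPs for g among
#' `snp_order`) and 0 otherwise, so every represented gene column has unit
#' Euclidean norm regardless of gene size.
#'
#' @param annotation a [gene_annotation()] object or a data frame with
#'   columns `snp_id` and `gene_id`.
#' @param network a [signed_gene_network()] providing the gene order.
#' @param snp_order character vector fixing the SNP (row) order, typically
#'   the column names of the genotype matrix.
#' @return Numeric matrix with `snp_order` rows and `network$genes` columns;
#'   genes with no annotated SNP are recorded in the `"unrepresented"`
#'   attribute for removal by [prune_and_rewire()].
#' @export
build_mapping_matrix <- function(annotation, network, snp_order) {
  stopifnot(inherits(network, "signed_gene_network"))
  map <- if (inherits(annotation, "gene_annotation")) annotation$map else
    as.data.frame(annotation)
  if (!all(c("snp_id", "gene_id") %in% names(map))) {
    stop("annotation must provide 'snp_id' and 'gene_id' columns")
  }
  snp_order <- as.character(snp_order)
  if (!length(snp_order)) stop("'snp_order' must be non-empty")
  genes <- network$genes
  if (!length(genes)) stop("network has no genes")
  map <- unique(map[map$snp_id %in% snp_order & map$gene_id %in% genes,
                    c("snp_id", "gene_id")])
  if (nrow(map) == 0) {
    stop("no SNP maps to any gene of the network (empty overlap)")
  }
  A <- matrix(0, length(snp_order), length(genes),
              dimnames = list(snp_order, genes))
  A[cbind(match(map$snp_id, snp_order), match(map$gene_id, genes))] <- 1
  m_g <- colSums(A)
  nz <- m_g > 0
  A[, nz] <- sweep(A[, nz, drop = FALSE], 2, sqrt(m_g[nz]), "/")
  attr(A, "unrepresented") <- genes[!nz]
  A
}

#' Topological descriptors of a pathway network
#'
#' Computes the descriptors used to characterize pathway graphs: node and
#' link counts, inhibition links, average degree, density, inhibition degree
#' (mean number of inhibiting links per gene), global transitivity, signed
#' transitivity and diameter. Signed transitivity replaces the triangle count
#' by the sum over triangles of the product of the three edge signs (closed
#' signed triplets over connected triplets); it can therefore be negative.
#' The diameter is computed on the largest connected component.
#'
#' @param network a prepared (symmetric) [signed_gene_network()].
#' @return A list of class `network_summary`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "signed_gene_network"))
  S <- network$adjacency
  n <- nrow(S)
  if (n == 0) stop("cannot summarize an empty network")
  if (!isSymmetric(unname(S), tol = 1e-8)) {
    stop("network must be symmetrized first (see symmetrize_adjacency)")
  }
  B <- (S != 0) * 1
  diag(B) <- 0
  links <- sum(B[upper.tri(B)])
  inhibition_links <- sum(S[upper.tri(S)] < 0)
  deg <- rowSums(B)
  triples <- sum(deg * (deg - 1))          # 2 x connected triplets
  Sg <- sign(S); diag(Sg) <- 0
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  structure(list(
    nodes = n,
    links = links,
    inhibition_links = inhibition_links,
    average_degree = mean(deg),
    density = if (n > 1) links / choose(n, 2) else 0,
    inhibition_degree = mean(rowSums(S < 0)),
    transitivity = if (triples > 0) sum(diag(B %*% B %*% B)) / triples else 0,
    signed_transitivity = if (triples > 0) sum(diag(Sg %*% Sg %*% Sg)) / triples else 0,
    diameter = if (length(giant) > 1)
      igraph::diameter(igraph::induced_subgraph(g, giant)) else 0
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Pathway network descriptors:\n")
  for (f in names(unclass(x))) {
    cat(sprintf("  %-20s %s\n", f, format(x[[f]], digits = 4)))
  }
  invisible(x)
}

#' Prepare a raw network for kernel construction
#'
#' Convenience wrapper chaining [symmetrize_adjacency()],
#' [prune_and_rewire()] and [psd_shift_matrix()] in the order required before
#' the network enters the kernel.
#'
#' @inheritParams prune_and_rewire
#' @return List with `network` (prepared, PSD adjacency) and `rho` (the
#'   shift weight applied, 1 if no shift was needed).
#' @export
prepare_network <- function(network, represented_genes) {
  sym <- symmetrize_adjacency(network)
  pruned <- prune_and_rewire(sym, represented_genes)
  if (!length(pruned$genes)) {
    stop("no represented genes remain after pruning")
  }
  shifted <- psd_shift_matrix(pruned$adjacency)
  list(network = signed_gene_network(shifted$matrix, pruned$genes),
       rho = shifted$rho)
}

#' SNP-gene annotation
#'
#' Holds the SNP-to-gene map used to build mapping matrices, optionally with
#' the SNP and gene coordinate tables it was derived from.
#'
#' @param map data frame with columns `snp_id`, `gene_id`.
#' @param snps optional data frame `snp_id, chrom, pos` (1-based).
#' @param genes optional data frame `gene_id, chrom, start, end` (1-based,
#'   inclusive).
#' @param flank flank in bp that was applied to the gene boundaries.
#' @return Object of class `gene_annotation`.
#' @export
gene_annotation <- function(map, snps = NULL, genes = NULL, flank = 0) {
  map <- as.data.frame(map)
  if (!all(c("snp_id", "gene_id") %in% names(map))) {
    stop("'map' must have columns snp_id and gene_id")
  }
  map$snp_id <- as.character(map$snp_id)
  map$gene_id <- as.character(map$gene_id)
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    if (any(genes$start > genes$end)) {
      stop("gene table has start > end")
    }
  }
  structure(list(map = unique(map), snps = snps, genes = genes, flank = flank),
            class = "gene_annotation")
}

#' Annotate SNPs to genes by genomic position
#'
#' Assigns each SNP to every gene whose (flank-extended) interval contains
#' its position on the same chromosome. Coordinates are 1-based inclusive.
#' The flank emulates the extension of gene regions by adjacent LD blocks; a
#' SNP may map to several overlapping genes.
#'
#' @param snps data frame `snp_id, chrom, pos`.
#' @param genes data frame `gene_id, chrom, start, end`.
#' @param flank non-negative integer, bp added on both sides of each gene.
#' @return A [gene_annotation()].
#' @export
annotate_snps <- function(snps, genes, flank = 0) {
  snps <- as.data.frame(snps)
  genes <- as.data.frame(genes)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            flank >= 0)
  if (any(genes$start > genes$end)) stop("gene table has start > end")
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sel <- snps$chrom == g$chrom &
      snps$pos >= g$start - flank & snps$pos <= g$end + flank
    if (any(sel)) data.frame(snp_id = snps$snp_id[sel], gene_id = g$gene_id)
  })
  map <- do.call(rbind, hits)
  if (is.null(map)) map <- data.frame(snp_id = character(), gene_id = character())
  gene_annotation(map, snps = snps, genes = genes, flank = flank)
}
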