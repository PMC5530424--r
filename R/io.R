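#' Read a genotype matrix from disk
#'
#' Supports two plain-text dialects: the PLINK `.raw` export (header
#' `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`, allele-count columns with the
#' counted allele appended to the SNP id) and a plain delimited matrix with a
#' header row of SNP ids (optionally a leading sample-id column). Missing
#' values are rejected with a pointer to the offending cells; imputation
#' belongs upstream.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"plink-raw"` or `"delimited"`.
#' @return Integer genotype matrix with sample row names and SNP column
#'   names.
#' @export
read_genotypes <- function(path, dialect = c("auto", "plink-raw", "delimited")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  plink <- identical(header[1:6],
                     c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (dialect == "plink-raw" && !plink) {
    stop("file does not carry a PLINK .raw header")
  }
  if (dialect == "auto") dialect <- if (plink) "plink-raw" else "delimited"
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "na", ""))
  if (dialect == "plink-raw") {
    ids <- as.character(df$IID)
    G <- as.matrix(df[, -(1:6), drop = FALSE])
    colnames(G) <- sub("_[^_]*$", "", colnames(G))
  } else {
    first_num <- suppressWarnings(!anyNA(as.numeric(df[[1]])))
    if (!first_num) {
      ids <- as.character(df[[1]])
      G <- as.matrix(df[, -1, drop = FALSE])
    } else {
      ids <- as.character(seq_len(nrow(df)))
      G <- as.matrix(df)
    }
  }
  if (anyNA(G)) {
    bad <- which(is.na(G), arr.ind = TRUE)
    shown <- utils::head(sprintf("(sample %s, SNP %s)",
                                 ids[bad[, 1]], colnames(G)[bad[, 2]]), 5)
    stop(sprintf("missing genotype values at %s%s; impute upstream",
                 paste(shown, collapse = ", "),
                 if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else ""))
  }
  mode(G) <- "numeric"
  if (any(G != round(G))) stop("genotype file contains non-integer entries")
  G <- validate_genotypes(G)
  rownames(G) <- ids
  G
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] for both dialects; `write` then `read` is
#' the identity on the matrix, its sample ids and SNP ids.
#'
#' @param Z genotype matrix.
#' @param path output path.
#' @param dialect `"plink-raw"` or `"delimited"`.
#' @param phenotype optional 0/1 vector written to the PLINK PHENOTYPE
#'   column (as 1/2); `-9` when omitted.
#' @export
write_genotypes <- function(Z, path, dialect = c("plink-raw", "delimited"),
                            phenotype = NULL) {
  dialect <- match.arg(dialect)
  Z <- validate_genotypes(Z)
  ids <- rownames(Z)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Z)))
  if (dialect == "plink-raw") {
    pheno <- if (is.null(phenotype)) rep(-9L, nrow(Z)) else as.integer(phenotype) + 1L
    df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = pheno, check.names = FALSE)
    G <- as.data.frame(Z)
    names(G) <- paste0(colnames(Z), "_A")
    utils::write.table(cbind(df, G), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(sample_id = ids, as.data.frame(Z), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a signed gene-interaction edge list
#'
#' Tab- (or whitespace-) delimited lines `gene_a gene_b sign` with sign in
#' `{+1, -1, 1}`; lines starting with `#` and blank lines are ignored; CRLF
#' endings are tolerated.
#'
#' @param path file path.
#' @return A [signed_gene_network()] with `directed_input = TRUE` (call
#'   [symmetrize_adjacency()] or [prepare_network()] before analysis).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- sub("\r$", "", readLines(path))
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("edge list contains no edges")
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: '%s'", keep[bad[1]], lines[keep[bad[1]]]))
  }
  ga <- vapply(parts, `[[`, "", 1)
  gb <- vapply(parts, `[[`, "", 2)
  sg <- suppressWarnings(as.numeric(sub("^\\+", "", vapply(parts, `[[`, "", 3))))
  if (anyNA(sg) || any(!sg %in% c(-1, 1))) {
    bad <- which(is.na(sg) | !sg %in% c(-1, 1))[1]
    stop(sprintf("invalid sign on edge list line %d (must be +1 or -1)", keep[bad]))
  }
  genes <- unique(c(rbind(ga, gb)))
  N <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  N[cbind(ga, gb)] <- sg
  signed_gene_network(N, genes, directed_input = TRUE)
}

#' Write a signed network as an edge list
#'
#' Emits edges in canonical sorted order, one `gene_a<TAB>gene_b<TAB>sign`
#' line per link (upper triangle for symmetric networks).
#'
#' @param network a [signed_gene_network()].
#' @param path output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "signed_gene_network"))
  N <- network$adjacency
  sym <- isSymmetric(unname(N), tol = 1e-12)
  idx <- if (sym) which(upper.tri(N) & N != 0, arr.ind = TRUE) else
    which(N != 0, arr.ind = TRUE)
  edges <- data.frame(a = rownames(N)[idx[, 1]], b = colnames(N)[idx[, 2]],
                      s = format(N[idx], trim = TRUE))
  edges <- edges[order(edges$a, edges$b), ]
  writeLines(c("# gene_a\tgene_b\tsign",
               sprintf("%s\t%s\t%s", edges$a, edges$b, edges$s)), path)
  invisible(path)
}

#' Read SNP and gene annotation tables
#'
#' The SNP table is tab-delimited `snp_id chrom pos [gene_id]`; when a gene
#' table (`gene_id chrom start end`, 1-based inclusive) is supplied, SNPs
#' are (re)annotated by position with an optional flank, otherwise the
#' fourth column of the SNP table is used directly.
#'
#' @param snp_path path to the SNP table.
#' @param gene_path optional path to the gene table.
#' @param flank bp flank applied to gene boundaries during positional
#'   annotation.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(snp_path, gene_path = NULL, flank = 0) {
  snps <- utils::read.table(snp_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(gene_path)) {
    genes <- utils::read.table(gene_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#")
    annotate_snps(snps, genes, flank = flank)
  } else {
    if (!"gene_id" %in% names(snps)) {
      stop("SNP table has no gene_id column and no gene table was supplied")
    }
    gene_annotation(snps[, c("snp_id", "gene_id")], snps = snps, flank = flank)
  }
}

#' Read gene sets in GMT format
#'
#' One tab-delimited line per set: name, description, then gene ids.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d (need name, description, genes)", i))
    }
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' removed", parts[1]))
      genes <- unique(genes)
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

MODEL_FORMAT_VERSION <- 1L

#' Serialize a fitted boosting model to a text file
#'
#' Stores everything needed to reproduce predictions (offset coefficients,
#' per-pathway prediction-kernel metadata and accumulated coefficients) as
#' JSON, with all doubles written at full precision so that predictions of a
#' saved-and-restored model are bit-identical. An MD5 checksum of the
#' payload guards against tampering or truncation.
#'
#' @param fit a [boost_fit][boost()] fitted via [pathway_kernels()] (so that
#'   pathway metadata is available).
#' @param path output path.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "boost_fit"))
  learners <- lapply(fit$learners, function(bl) {
    if (is.null(bl$meta)) {
      stop("learner carries no pathway metadata; fit via pathway_kernels() to save")
    }
    list(id = bl$id, rho = num17(bl$rho), alpha = num17(bl$alpha),
         n_selected = bl$n_selected,
         snp_ids = bl$meta$snp_ids,
         A = mat_to_list(bl$meta$A), NB = mat_to_list(bl$meta$NB),
         N = mat_to_list(bl$meta$N))
  })
  payload <- list(
    version = MODEL_FORMAT_VERSION,
    config = list(nu = num17(fit$nu), m_stop = fit$m_stop),
    offset = list(beta = num17(fit$offset$beta),
                  beta_names = names(fit$offset$beta),
                  covariates = fit$offset$covariates),
    pathway_ids = fit$pathway_ids,
    selection_path = fit$selection_path,
    learners = learners
  )
  payload_json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                                null = "null"))
  writeLines(as.character(jsonlite::toJSON(list(
    format = "kernboost-model",
    checksum = md5_string(payload_json),
    payload = payload_json
  ), auto_unbox = TRUE)), path)
  invisible(path)
}

md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf, sep = "")
  unname(tools::md5sum(tf))
}

#' Restore a boosting model saved with [save_model()]
#'
#' @param path model file path.
#' @return A `boost_fit` object usable with [predict_proba()] and
#'   [selected_pathways()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  wrap <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                             simplifyVector = TRUE)
  if (!identical(wrap$format, "kernboost-model")) {
    stop("not a kernboost model file")
  }
  if (!identical(unname(md5_string(wrap$payload)), unname(wrap$checksum))) {
    stop("checksum mismatch: model file corrupted or tampered with")
  }
  pl <- jsonlite::fromJSON(wrap$payload, simplifyVector = TRUE)
  if (pl$version > MODEL_FORMAT_VERSION) {
    stop(sprintf("model format version %d is newer than this package supports",
                 pl$version))
  }
  beta <- stats::setNames(as.numeric(pl$offset$beta), pl$offset$beta_names)
  offset <- structure(list(beta = beta,
                           covariates = as.character(unlist(pl$offset$covariates))),
                      class = "covariate_offset_model")
  mk_learner <- function(l) {
    structure(list(id = l$id, rho = as.numeric(l$rho),
                   alpha = as.numeric(unlist(l$alpha)),
                   n_selected = as.integer(l$n_selected),
                   meta = list(snp_ids = unlist(l$snp_ids),
                               A = list_to_mat(l$A), NB = list_to_mat(l$NB),
                               N = list_to_mat(l$N))),
              class = "kernel_base_learner")
  }
  learners <- if (is.data.frame(pl$learners)) {
    lapply(seq_len(nrow(pl$learners)), function(i)
      mk_learner(lapply(pl$learners, function(col)
        if (is.list(col)) col[[i]] else col[i])))
  } else {
    lapply(pl$learners, mk_learner)
  }
  names(learners) <- vapply(learners, `[[`, "", "id")
  structure(list(
    offset = offset, nu = as.numeric(pl$config$nu),
    m_stop = as.integer(pl$config$m_stop),
    selection_path = as.integer(unlist(pl$selection_path)),
    pathway_ids = as.character(unlist(pl$pathway_ids)),
    learners = learners
  ), class = "boost_fit")
}
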