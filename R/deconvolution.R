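#' Build a pseudo-bulk signature matrix from labelled single cells
#'
#' Aggregates a gene x cell count matrix into one reference expression
#' profile per cell type by summing counts within each type (pseudo-bulk),
#' dropping genes with zero total expression, and normalizing every column
#' to counts-per-10k. The result is the "pure" reference used for
#' constrained deconvolution of mixed (bulk) samples.
#'
#' @param counts numeric gene x cell matrix with unique rownames (gene ids);
#'   sparse `Matrix` classes are accepted and densified.
#' @param labels cell-type label per column of `counts` (character or
#'   factor); every type must have at least one cell.
#' @param scale column target sum after normalization (default 1e4).
#' @return Object of class `signature_matrix`: numeric gene x cell-type
#'   matrix.
#' @export
build_signature <- function(counts, labels, scale = 1e4) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have gene rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  labels <- as.character(labels)
  if (length(labels) != ncol(counts))
    stop("one label per cell required")
  if (any(is.na(labels) | !nzchar(labels)))
    stop("empty cell-type label")
  types <- sort(unique(labels))
  sig <- vapply(types, function(ty)
    rowSums(counts[, labels == ty, drop = FALSE]), numeric(nrow(counts)))
  keep <- rowSums(sig) > 0
  sig <- sig[keep, , drop = FALSE]
  if (any(colSums(sig) == 0))
    stop("cell type with all-zero expression")
  sig <- sweep(sig, 2L, colSums(sig), "/") * scale
  structure(sig, class = c("signature_matrix", class(sig)))
}

#' Deconvolve bulk expression into cell-type fractions
#'
#' Estimates, per bulk sample, the convex combination of signature columns
#' that best explains the sample: minimize `||S f - b||^2` subject to
#' `f >= 0` and `sum(f) = 1`, solved as a quadratic programme. Both the
#' signature and the bulk matrix are restricted to their shared genes and
#' standardized per gene with the signature's row mean and SD before the
#' solve, so highly expressed genes do not dominate; because the map is
#' affine per gene and fractions sum to one, noise-free mixtures are still
#' recovered exactly.
#'
#' @param signature a [build_signature()] matrix (gene x cell type).
#' @param bulk numeric gene x sample matrix (or data.frame) with gene
#'   rownames.
#' @param standardize per-gene z-standardization on the shared feature
#'   space (default `TRUE`).
#' @return Object of class `deconvolution_result`: list with `fractions`
#'   (sample x cell-type matrix, rows on the unit simplex), `residual_norm`
#'   (per sample), `genes_used`.
#' @export
deconvolve <- function(signature, bulk, standardize = TRUE) {
  S <- as.matrix(signature)
  B <- as.matrix(bulk)
  if (is.null(rownames(S)) || is.null(rownames(B)))
    stop("signature and bulk must have gene rownames")
  shared <- intersect(rownames(S), rownames(B))
  if (!length(shared)) stop("no shared genes between signature and bulk")
  S <- S[shared, , drop = FALSE]
  B <- B[shared, , drop = FALSE]

  if (standardize) {
    mu <- rowMeans(S)
    sdv <- apply(S, 1L, stats::sd)
    keep <- sdv > 0
    S <- (S[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    B <- (B[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    shared <- shared[keep]
  }
  if (nrow(S) < ncol(S))
    warning("fewer shared genes than cell types; solution not unique")
  # rank on the sum-to-one affine subspace: per-gene centering removes one
  # dimension by construction, which the equality constraint restores
  if (qr(rbind(S, 1))$rank < ncol(S))
    warning("rank-deficient signature on the shared genes; ",
            "returning a pseudo-solution")

  k <- ncol(S)
  Dmat <- crossprod(S)
  # ridge for numerical positive definiteness; negligible vs. data scale
  Dmat <- Dmat + diag(1e-10 * max(1, mean(diag(Dmat))), k)
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  fractions <- matrix(NA_real_, ncol(B), k,
                      dimnames = list(colnames(B), colnames(S)))
  rnorm_ <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    sol <- quadprog::solve.QP(Dmat, crossprod(S, B[, j]), Amat, bvec,
                              meq = 1)
    f <- pmax(sol$solution, 0)
    f <- f / sum(f)
    fractions[j, ] <- f
    rnorm_[j] <- sqrt(sum((S %*% f - B[, j])^2))
  }
  structure(list(fractions = fractions, residual_norm = rnorm_,
                 genes_used = shared),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("Deconvolution of %d sample(s) over %d cell type(s), %d genes\n",
              nrow(x$fractions), ncol(x$fractions), length(x$genes_used)))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Score a gene module per cell and per cell type
#'
#' Computes, for every cell, the mean over the module genes of the
#' per-gene z-scored expression (genes absent from the matrix are ignored),
#' and summarizes the scores per cell type as arithmetic means. Genes with
#' zero variance contribute a zero z-score.
#'
#' @param expression numeric gene x cell matrix of log-normalized
#'   expression with gene rownames.
#' @param labels cell-type label per column.
#' @param module character vector of gene ids.
#' @param name module label.
#' @return Object of class `gene_module_score`: list with `module`,
#'   `genes_used`, `cell_scores`, `type_means` (named numeric).
#' @export
score_gene_module <- function(expression, labels, module, name = "module") {
  expression <- as.matrix(expression)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expression))
  genes <- intersect(module, rownames(expression))
  if (!length(genes))
    stop("no module gene present in the expression matrix")
  sub <- expression[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  sdv[sdv == 0] <- Inf   # constant genes score 0
  z <- (sub - mu) / sdv
  cell_scores <- colMeans(z)
  type_means <- tapply(cell_scores, labels, mean)
  structure(list(module = name, genes_used = genes,
                 cell_scores = cell_scores,
                 type_means = stats::setNames(as.numeric(type_means),
                                              names(type_means))),
            class = "gene_module_score")
}

#' @export
print.gene_module_score <- function(x, ...) {
  cat(sprintf("Module '%s': %d gene(s) scored over %d cells\n",
              x$module, length(x$genes_used), length(x$cell_scores)))
  print(round(x$type_means, 4))
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Thin wrapper over [stats::cor.test()] returning the Pearson correlation
#' and its two-sided p-value, with the pairing made explicit: when
#' `paired_by` is given, `x` and `y` are aligned by those labels first.
#'
#' @param x,y numeric vectors (length >= 3 after pairing).
#' @param paired_by optional labels; either one vector applying to both, or
#'   a list of two vectors `list(x_labels, y_labels)`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate <- function(x, y, paired_by = NULL) {
  if (!is.null(paired_by)) {
    if (is.list(paired_by)) {
      common <- intersect(paired_by[[1L]], paired_by[[2L]])
      x <- x[match(common, paired_by[[1L]])]
      y <- y[match(common, paired_by[[2L]])]
    } else {
      o <- order(paired_by)
      x <- x[o]; y <- y[o]
    }
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' All pairwise Pearson correlations between two sets of variables
#'
#' @param X,Y numeric matrices (observations x variables) with matching row
#'   order.
#' @param alpha significance flag threshold.
#' @return List of matrices `rho`, `p_value` and logical `significant`
#'   (`p < alpha`), variables of `X` in rows, of `Y` in columns.
#' @export
correlate_matrix <- function(X, Y, alpha = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  rho <- matrix(NA_real_, ncol(X), ncol(Y),
                dimnames = list(colnames(X), colnames(Y)))
  pv <- rho
  for (i in seq_len(ncol(X)))
    for (j in seq_len(ncol(Y))) {
      ct <- correlate(X[, i], Y[, j])
      rho[i, j] <- ct$rho
      pv[i, j] <- ct$p_value
    }
  list(rho = rho, p_value = pv, significant = pv < alpha)
}

#' Read gene sets and expression tables
#'
#' `read_gene_set()` reads a one-symbol-per-line text file;
#' `read_expression_tsv()` reads a genes-as-rows TSV with a header of
#' sample/cell names.
#'
#' @param path file path.
#' @return Character vector of gene ids, or a numeric matrix.
#' @export
read_gene_set <- function(path) {
  g <- readLines(path)
  g <- trimws(g)
  unique(g[nzchar(g)])
}

#' @rdname read_gene_set
#' @export
read_expression_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Read sparse single-cell counts from MatrixMarket triplets
#'
#' Reads a gene x cell count matrix stored as an uncompressed MatrixMarket
#' triplet file plus one-id-per-line gene and cell label files (the usual
#' sparse export layout).
#'
#' @param mtx_path path to the `.mtx` triplet file.
#' @param genes_path path to the gene-id file (one per matrix row).
#' @param cells_path path to the cell-id file (one per matrix column).
#' @return A sparse `Matrix` with gene rownames and cell colnames,
#'   directly usable by [build_signature()].
#' @export
read_mtx_counts <- function(mtx_path, genes_path, cells_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- trimws(genes[nzchar(trimws(genes))])
  cells <- trimws(cells[nzchar(trimws(cells))])
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("label files do not match the matrix dimensions")
  dimnames(m) <- list(genes, cells)
  m
}
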