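#' Connectivity matrix constructor
#'
#' Wraps a square region-by-region weight matrix with its parcel labels and a
#' modality tag. Structural matrices hold nonnegative streamline counts;
#' functional matrices hold correlation coefficients in \[-1, 1\]; fused
#' matrices are the horizontal concatenation of the two (regions x 2n) and are
#' exempt from the squareness and symmetry checks.
#'
#' Symmetry is enforced by averaging with the transpose; asymmetries larger
#' than `tol` are an error, as are NaN/NA entries.
#'
#' @param values numeric matrix of weights.
#' @param region_ids character vector of parcel labels (defaults to rownames).
#' @param modality one of `"structural"`, `"functional"`, `"fused"`.
#' @param tol maximum tolerated asymmetry before averaging.
#' @return an object of class `connectivity_matrix` with elements `values`,
#'   `region_ids`, `modality`.
#' @export
connectivity_matrix <- function(values,
                                region_ids = rownames(values),
                                modality = c("structural", "functional", "fused"),
                                tol = 1e-8) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("connectivity matrix contains NA/NaN/Inf values")
  if (is.null(region_ids)) region_ids <- paste0("r", seq_len(nrow(values)))
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids))
    stop("duplicate region labels: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  if (length(region_ids) != nrow(values))
    stop("region_ids length does not match matrix rows")
  if (modality != "fused") {
    if (nrow(values) != ncol(values))
      stop("non-square connectivity matrix (", nrow(values), " x ", ncol(values), ")")
    asym <- max(abs(values - t(values)))
    if (asym > tol)
      stop("matrix asymmetry ", format(asym), " exceeds tolerance ", format(tol))
    values <- (values + t(values)) / 2
  }
  if (modality == "structural" && any(values < 0))
    stop("negative structural weights")
  if (modality == "functional" && (any(values < -1) || any(values > 1)))
    stop("functional weights outside [-1, 1]")
  dimnames(values) <- NULL
  structure(list(values = values, region_ids = region_ids, modality = modality),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d regions x %d columns\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_conn_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Independently for each row, sets the smallest `floor(sparsity * n)` entries
#' to zero and keeps the rest (the convention that "default sparsity 0.9"
#' keeps the top 10% of weights per row). Ties at the cut are broken by
#' column index: among tied values the smaller column index is dropped first.
#' The output is not re-symmetrised; the affinity kernel downstream restores
#' symmetry.
#'
#' @param matrix a `connectivity_matrix` or numeric matrix.
#' @param sparsity fraction in \[0, 1) of entries zeroed per row.
#' @return object of the same type as the input with sparsified values.
#' @export
sparsify_rows <- function(matrix, sparsity = 0.9) {
  if (!is.numeric(sparsity) || length(sparsity) != 1 || sparsity < 0 || sparsity >= 1)
    stop("sparsity must be a single value in [0, 1)")
  vals <- as_conn_values(matrix)
  n <- ncol(vals)
  k <- floor(sparsity * n)
  if (k > 0) {
    for (i in seq_len(nrow(vals))) {
      o <- order(vals[i, ], seq_len(n))
      vals[i, o[seq_len(k)]] <- 0
    }
  }
  if (inherits(matrix, "connectivity_matrix")) {
    matrix$values <- vals
    matrix
  } else vals
}

#' Normalised-angle affinity kernel
#'
#' Converts a (row-sparsified) connectivity matrix into a similarity matrix
#' with entries `A(i,j) = 1 - acos(cossim(x_i, x_j)) / pi`, where `cossim` is
#' the cosine similarity of the two rows. Identical profiles map to 1,
#' orthogonal profiles to 0.5 and antiparallel profiles to 0. Cosines are
#' clamped to \[-1, 1\] before `acos`; the diagonal is set to 1 and the result
#' symmetrised by averaging.
#'
#' @param matrix `connectivity_matrix` or numeric matrix; no all-zero rows.
#' @return square numeric affinity matrix with entries in \[0, 1\].
#' @export
normalized_angle <- function(matrix) {
  vals <- as_conn_values(matrix)
  ids <- if (inherits(matrix, "connectivity_matrix")) matrix$region_ids
         else rownames(vals)
  rn <- sqrt(rowSums(vals^2))
  if (any(rn == 0)) {
    bad <- if (is.null(ids)) which(rn == 0) else ids[rn == 0]
    stop("all-zero row(s), cosine similarity undefined for region(s): ",
         paste(bad, collapse = ", "))
  }
  cs <- tcrossprod(vals / rn)
  cs <- pmin(pmax(cs, -1), 1)
  # snap numerically parallel/antiparallel profiles so that acos, whose
  # derivative diverges at +/-1, returns exactly 1 and 0 for them
  cs[abs(cs - 1) < 1e-12] <- 1
  cs[abs(cs + 1) < 1e-12] <- -1
  A <- 1 - acos(cs) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  A
}

#' Diffusion map embedding of an affinity matrix
#'
#' Computes gradients (eigenmaps) of the diffusion operator built from a
#' symmetric nonnegative affinity matrix. With `d` the row sums of `A`, the
#' anisotropic kernel is `W = A / (d_i^alpha * d_j^alpha)`; with `d'` the row
#' sums of `W`, the Markov operator is `P = W / d'`. The trivial constant
#' eigenvector (eigenvalue 1) is discarded and component k is the k-th
#' nontrivial right eigenvector of `P`, unit-normalised and scaled by
#' `lambda_k / (1 - lambda_k)` (the automatic diffusion-time convention).
#' Components are ordered by descending eigenvalue and each component's sign
#' is fixed so that its largest-magnitude entry is positive.
#'
#' Internally the symmetric conjugate `S = D'^(-1/2) W D'^(-1/2)` is
#' eigendecomposed; right eigenvectors of `P` are recovered as
#' `D'^(-1/2) v`.
#'
#' @param affinity square symmetric nonnegative matrix (e.g. from
#'   [normalized_angle()]).
#' @param n_components number of gradients to return (< number of regions).
#' @param alpha diffusion anisotropy exponent in \[0, 1\]; 0.5 by default.
#' @return object of class `gradient_set`: `scores` (regions x components,
#'   columns G1, G2, ...), `eigenvalues` (non-increasing), `aligned = FALSE`.
#' @export
diffusion_embed <- function(affinity, n_components = 10, alpha = 0.5) {
  A <- as.matrix(affinity)
  n <- nrow(A)
  if (n != ncol(A)) stop("affinity must be square")
  if (any(A < 0)) stop("affinity must be nonnegative")
  if (n_components >= n) stop("n_components must be smaller than the region count")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  ids <- rownames(A)
  d <- rowSums(A)
  if (any(d == 0)) stop("affinity has an isolated region (zero row sum)")
  W <- A / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  s <- 1 / sqrt(d2)
  S <- W * outer(s, s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  if (sum(lam > 1 - 1e-10) > 1)
    stop("affinity graph is disconnected (multiple unit eigenvalues); ",
         "lower the sparsity")
  keep <- seq.int(2, n_components + 1)
  lamk <- lam[keep]
  V <- e$vectors[, keep, drop = FALSE] * s   # right eigenvectors of P
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  # deterministic sign: largest-magnitude entry positive
  for (k in seq_along(lamk)) {
    m <- which.max(abs(V[, k]))
    if (V[m, k] < 0) V[, k] <- -V[, k]
  }
  scores <- sweep(V, 2, lamk / (1 - lamk), "*")
  colnames(scores) <- paste0("G", seq_along(lamk))
  if (!is.null(ids)) rownames(scores) <- ids
  structure(list(scores = scores, eigenvalues = lamk, aligned = FALSE,
                 lambda0 = lam[1]),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d regions x %d components, %saligned\n",
              nrow(x$scores), ncol(x$scores), if (x$aligned) "" else "un"))
  invisible(x)
}

#' Group-level gradient template
#'
#' Averages the control connectivity matrices element-wise and runs the full
#' gradient pipeline (row sparsification, normalised-angle kernel, diffusion
#' map embedding) on the mean matrix.
#'
#' @param matrices list of `connectivity_matrix` objects with identical
#'   `region_ids` and modality (typically the control group).
#' @param config an [analysis_config()]; `sparsity`, `n_components` and
#'   `alpha` are used.
#' @return unaligned `gradient_set` of the group mean matrix.
#' @export
group_template <- function(matrices, config = analysis_config()) {
  if (length(matrices) < 1) stop("need at least one control matrix")
  ref <- matrices[[1]]
  for (m in matrices) {
    if (!identical(m$region_ids, ref$region_ids)) stop("region_id mismatch across matrices")
    if (!identical(m$modality, ref$modality)) stop("modality mismatch across matrices")
  }
  mean_vals <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  mean_mat <- ref
  mean_mat$values <- mean_vals
  subject_gradients(mean_mat, config)
}

#' Gradient pipeline for a single matrix
#'
#' Convenience wrapper: sparsify rows, normalised-angle kernel, diffusion map
#' embedding, using the parameters in `config`.
#'
#' @inheritParams group_template
#' @param matrix a `connectivity_matrix`.
#' @return unaligned `gradient_set`.
#' @export
subject_gradients <- function(matrix, config = analysis_config()) {
  sp <- sparsify_rows(matrix, config$sparsity)
  A <- normalized_angle(sp)
  rownames(A) <- colnames(A) <- matrix$region_ids
  diffusion_embed(A, n_components = config$n_components, alpha = config$alpha)
}

#' Procrustes alignment of an individual gradient set to a template
#'
#' Single-pass orthogonal Procrustes: finds the orthogonal matrix `R`
#' (rotation/reflection, no scaling or centring) minimising
#' `|| individual %*% R - template ||_F` and returns the rotated individual
#' scores. The Frobenius norm of the scores is preserved exactly.
#'
#' @param individual `gradient_set` to align.
#' @param template `gradient_set` with the same region and component counts.
#' @return `gradient_set` with rotated scores and `aligned = TRUE`.
#' @export
procrustes_align <- function(individual, template) {
  X <- individual$scores
  Tm <- template$scores
  if (!all(dim(X) == dim(Tm)))
    stop("dimension mismatch between individual and template gradient sets")
  sv <- svd(crossprod(X, Tm))
  R <- sv$u %*% t(sv$v)
  aligned <- X %*% R
  dimnames(aligned) <- dimnames(X)
  out <- individual
  out$scores <- aligned
  out$aligned <- TRUE
  out
}

#' Fuse structural and functional connectivity matrices
#'
#' Horizontally concatenates the two matrices after rescaling each block to
#' unit Frobenius norm, so that neither modality dominates the row profiles
#' entering the cosine kernel. The result is a regions x 2n `fused`
#' connectivity matrix.
#'
#' @param structural structural `connectivity_matrix`.
#' @param functional functional `connectivity_matrix` with the same
#'   `region_ids`.
#' @return fused `connectivity_matrix`.
#' @export
fuse <- function(structural, functional) {
  if (!identical(structural$region_ids, functional$region_ids))
    stop("region_id mismatch between structural and functional matrices")
  s <- structural$values / norm(structural$values, "F")
  f <- functional$values / norm(functional$values, "F")
  structure(list(values = cbind(s, f),
                 region_ids = structural$region_ids,
                 modality = "fused"),
            class = "connectivity_matrix")
}
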