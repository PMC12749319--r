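# Partial least squares regression of a regional map on region x gene
# expression, with spin-based significance for the first component's
# variance explained and for per-gene weights.

# z-score columns with population SD; drop zero-variance columns with warning
standardise_X <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdv > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  Xs
}

standardise_y <- function(y) {
  s <- sqrt(mean((y - mean(y))^2))
  if (s == 0) stop("constant response map")
  (y - mean(y)) / s
}

#' Partial least squares regression of a t-map on gene expression
#'
#' NIPALS PLS1 regression with deflation: predictor matrix X is the region
#' x gene expression table (columns z-scored internally, population SD;
#' zero-variance genes dropped with a warning) and the response Y is the
#' z-scored regional map. For a univariate response each NIPALS component
#' converges in a single step (`w` proportional to `X'y`). Components are
#' extracted in order of deflation; per-component variance explained in Y is
#' reported, and every component's sign is fixed so its region scores
#' correlate positively with the original response.
#'
#' @param expression regions x genes numeric matrix (region ids as
#'   rownames).
#' @param t_map named numeric regional map (the response).
#' @param n_components number of components (>= 1, at most the matrix
#'   rank).
#' @param tol NIPALS convergence tolerance.
#' @param max_iter maximum NIPALS iterations per component.
#' @return list of class `pls_result`: `weights` (genes x components,
#'   PLS1 in column 1), `region_scores` (regions x components),
#'   `variance_explained` (in Y, per component), `y` (standardised
#'   response), `genes`.
#' @export
pls_fit <- function(expression, t_map, n_components = 3,
                    tol = 1e-12, max_iter = 500) {
  if (n_components < 1) stop("n_components must be >= 1")
  y0 <- t_map[rownames(expression)]
  if (anyNA(y0)) stop("t_map does not cover every region of the expression table")
  Xs <- standardise_X(expression)
  y <- standardise_y(y0)
  n <- nrow(Xs); g <- ncol(Xs)
  if (n_components > min(n - 1, g))
    stop("more components than the rank of the predictor matrix")
  ss_y <- sum(y^2)
  W <- matrix(NA_real_, g, n_components,
              dimnames = list(colnames(Xs), paste0("PLS", seq_len(n_components))))
  Tm <- matrix(NA_real_, n, n_components,
               dimnames = list(rownames(Xs), colnames(W)))
  varexp <- numeric(n_components)
  Xd <- Xs; yd <- y
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {   # single pass for univariate y; kept general
      tt <- Xd %*% w
      cq <- sum(yd * tt) / sum(tt^2)
      u <- yd * cq
      w_new <- crossprod(Xd, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    tt <- as.vector(Xd %*% w)
    pl <- as.vector(crossprod(Xd, tt)) / sum(tt^2)
    cq <- sum(yd * tt) / sum(tt^2)
    varexp[k] <- cq^2 * sum(tt^2) / ss_y
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - tt * cq
    # sign convention: region scores correlate positively with the response
    if (stats::cor(tt, y) < 0) { w <- -w; tt <- -tt }
    W[, k] <- w
    Tm[, k] <- tt
  }
  structure(list(weights = W, region_scores = Tm,
                 variance_explained = varexp, y = y,
                 genes = colnames(Xs)),
            class = "pls_result")
}

#' Spin significance of the first PLS component's variance explained
#'
#' Refits PLS1 with the response map permuted by each spin of the ensemble
#' and compares the observed variance explained by the first component to
#' the null distribution: `p = (1 + #(null >= observed)) / (n + 1)`. For a
#' univariate response the first-component fit reduces to `w` proportional
#' to `X'y`, which makes the permutation refits exact and fast.
#'
#' @param result `pls_result` from [pls_fit()] on the same data.
#' @param expression regions x genes matrix used for the fit.
#' @param t_map the response map used for the fit.
#' @param spins `spin_ensemble` on the same parcellation.
#' @return list with `p`, `observed`, `null` (variance explained under each
#'   spin).
#' @export
pls_component_significance <- function(result, expression, t_map, spins) {
  Xs <- suppressWarnings(standardise_X(expression))
  ord <- match(spins$region_id, rownames(Xs))
  if (anyNA(ord)) stop("spins built on a different parcellation")
  Xs <- Xs[ord, , drop = FALSE]
  y <- standardise_y(t_map[rownames(Xs)])
  obs <- result$variance_explained[1]
  Yp <- matrix(y[spins$permutations], nrow = length(y))
  Yp <- scale(Yp) * sqrt(nrow(Yp) / (nrow(Yp) - 1))  # population-SD z-score
  nulls <- pls1_varexp(Xs, Yp)
  p <- (1 + sum(nulls >= obs)) / (spins$n_permutations + 1)
  list(p = p, observed = obs, null = nulls)
}

# first-component variance explained for each column of a response matrix
pls1_varexp <- function(Xs, Y) {
  W <- crossprod(Xs, Y)                       # genes x nperm
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  Tm <- Xs %*% W                              # regions x nperm
  cq <- colSums(Y * Tm) / colSums(Tm^2)
  cq^2 * colSums(Tm^2) / colSums(Y^2)
}

#' Spin significance of per-gene PLS1 weights
#'
#' For every gene, the observed |PLS1 weight| is compared two-sidedly
#' against that gene's own null weight distribution from spin refits of the
#' response; p values are Benjamini-Hochberg adjusted across genes and the
#' significant set (q below `fdr_level`) is reported with the sign of the
#' observed weight (negative = down-weighted).
#'
#' @inheritParams pls_component_significance
#' @param fdr_level FDR threshold for the significant set.
#' @return data.frame of class `gene_weight_table`: `gene`, `weight`, `p`,
#'   `q`, `significant`.
#' @export
gene_weight_significance <- function(expression, t_map, spins,
                                     fdr_level = 0.05) {
  Xs <- suppressWarnings(standardise_X(expression))
  ord <- match(spins$region_id, rownames(Xs))
  if (anyNA(ord)) stop("spins built on a different parcellation")
  Xs <- Xs[ord, , drop = FALSE]
  y <- standardise_y(t_map[rownames(Xs)])
  w_obs <- as.vector(crossprod(Xs, y))
  w_obs <- w_obs / sqrt(sum(w_obs^2))
  tt <- Xs %*% w_obs
  if (stats::cor(tt, y) < 0) w_obs <- -w_obs
  Yp <- matrix(y[spins$permutations], nrow = length(y))
  W <- crossprod(Xs, Yp)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  ge <- rowSums(abs(W) >= abs(w_obs))
  p <- (1 + ge) / (spins$n_permutations + 1)
  q <- fdr(p)
  out <- data.frame(gene = colnames(Xs), weight = w_obs, p = p, q = q,
                    significant = q < fdr_level)
  rownames(out) <- NULL
  class(out) <- c("gene_weight_table", "data.frame")
  out
}

#' Hypergeometric over-enrichment test for two term sets
#'
#' One-sided p value for observing at least the given overlap between two
#' sets drawn from a finite universe:
#' `p = P(overlap >= observed)` under hypergeometric sampling.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all candidate labels.
#' @return list with `p`, `overlap`, `expected` (expected overlap under
#'   independence).
#' @export
term_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  N <- length(universe)
  ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(ov - 1, length(set_a), N - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(p = p, overlap = ov,
       expected = length(set_a) * length(set_b) / N)
}

#' Spearman similarity of two rankings on their shared labels
#'
#' Restricts both orderings to the labels they share (at least 3 required)
#' and computes the Spearman correlation of the rank positions.
#'
#' @param ranked_a,ranked_b character vectors of labels in ranked order
#'   (best first).
#' @return Spearman rho.
#' @export
rank_similarity <- function(ranked_a, ranked_b) {
  shared <- intersect(ranked_a, ranked_b)
  if (length(shared) < 3) stop("need at least 3 shared labels")
  stats::cor(match(shared, ranked_a), match(shared, ranked_b),
             method = "spearman")
}
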