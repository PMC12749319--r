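#' Build a spin-permutation ensemble for a parcel sphere
#'
#' For each permutation one uniform random 3-D rotation is drawn and applied
#' to the left-hemisphere parcel centroids; its x-mirrored counterpart is
#' applied to the right hemisphere, so both hemispheres rotate jointly with
#' mirror symmetry. Each parcel is then reassigned the value of the nearest
#' rotated centroid within its own hemisphere (nearest neighbour; a source
#' parcel may be used more than once). These spatially constrained
#' permutations preserve the spatial autocorrelation of regional maps and
#' are the null family for all contextualisation inference.
#'
#' @param sphere `parcel_sphere` with both hemispheres.
#' @param n_permutations number of spins (>= 1).
#' @param seed integer seed.
#' @return list of class `spin_ensemble`: `permutations` (n_regions x
#'   n_permutations integer matrix of source indices), `n_permutations`,
#'   `seed`, `region_id`.
#' @export
build_spins <- function(sphere, n_permutations = 1000, seed = 0) {
  hems <- unique(sphere$hemisphere)
  if (length(hems) < 2)
    stop("sphere must contain both hemispheres")
  X <- as.matrix(sphere[, c("x", "y", "z")])
  n <- nrow(X)
  iL <- which(sphere$hemisphere == "L")
  iR <- which(sphere$hemisphere == "R")
  M <- diag(c(-1, 1, 1))
  perms <- matrix(NA_integer_, n, n_permutations)
  with_seed(seed, {
    for (k in seq_len(n_permutations)) {
      Q <- rand_rotation()
      QR <- M %*% Q %*% M
      rotL <- X[iL, , drop = FALSE] %*% t(Q)
      rotR <- X[iR, , drop = FALSE] %*% t(QR)
      # nearest rotated centroid to each parcel's original position
      perms[iL, k] <- iL[max.col(tcrossprod(X[iL, , drop = FALSE], rotL),
                                 ties.method = "first")]
      perms[iR, k] <- iR[max.col(tcrossprod(X[iR, , drop = FALSE], rotR),
                                 ties.method = "first")]
    }
  })
  structure(list(permutations = perms, n_permutations = n_permutations,
                 seed = seed, region_id = sphere$region_id),
            class = "spin_ensemble")
}

#' Spin permutation test for the correlation of two regional maps
#'
#' Observed statistic: Spearman correlation of `map_a` with `map_b`. Null:
#' `map_a` is permuted by each spin of the ensemble and re-correlated with
#' the intact `map_b`; the two-sided p value is
#' `(1 + #(|null| >= |observed|)) / (n_permutations + 1)`, bounded below by
#' `1 / (n_permutations + 1)`.
#'
#' @param map_a named numeric regional map (the map that is spun; by
#'   convention the disease t-map).
#' @param map_b named numeric regional map (held fixed; the annotation).
#' @param spins `spin_ensemble` built on the same parcellation.
#' @return list of class `spin_result`: `rho_observed`, `null_rhos`,
#'   `p_spin`.
#' @export
spin_test <- function(map_a, map_b, spins) {
  a <- map_a[spins$region_id]
  b <- map_b[spins$region_id]
  if (anyNA(a) || anyNA(b))
    stop("maps must cover every region of the spin ensemble's parcellation")
  if (length(unique(a)) == 1 || length(unique(b)) == 1)
    stop("constant map: correlation undefined")
  rb <- rank(b)
  obs <- stats::cor(rank(a), rb)
  spun <- matrix(a[spins$permutations], nrow = length(a))
  spun_ranks <- apply(spun, 2, rank)
  nulls <- as.vector(stats::cor(spun_ranks, rb))
  p <- (1 + sum(abs(nulls) >= abs(obs))) / (spins$n_permutations + 1)
  structure(list(rho_observed = obs, null_rhos = nulls, p_spin = p),
            class = "spin_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH with monotonicity enforcement, as implemented by
#' [stats::p.adjust()] with `method = "BH"`. Applied across a declared
#' family of spin p values this yields q_spin.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return numeric vector of q values.
#' @export
fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
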