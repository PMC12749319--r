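#' Per-subject spread statistics of regional gradient scores
#'
#' For each subject's aligned gradient set, summarises the spread of the
#' chosen component's regional scores with three statistics: the SD
#' (primary), the range (max - min), and the mean absolute deviation from
#' the median. All three operationalise "spread between extremes" of the
#' gradient distribution; expansion widens them, contraction narrows them.
#'
#' @param gradients named list of aligned `gradient_set` objects (names are
#'   subject ids).
#' @param component component label, e.g. `"G1"`.
#' @return data.frame with columns `subject_id`, `component`, `spread_sd`,
#'   `spread_range`, `spread_meanabs`.
#' @export
spread_stats <- function(gradients, component = "G1") {
  if (!length(gradients)) stop("no gradient sets supplied")
  rows <- lapply(names(gradients), function(sid) {
    g <- gradients[[sid]]
    if (!isTRUE(g$aligned))
      stop("gradient set for ", sid, " is not aligned; align to the template first")
    x <- g$scores[, component]
    data.frame(subject_id = sid, component = component,
               spread_sd = stats::sd(x),
               spread_range = max(x) - min(x),
               spread_meanabs = mean(abs(x - stats::median(x))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of per-subject values across groups
#'
#' Rank-based H test with tie correction against a chi-square reference
#' (via [stats::kruskal.test()]), followed by Dunn pairwise z tests on mean
#' ranks with FDR correction across the pairs.
#'
#' @param values numeric vector, one value per subject (e.g. `spread_sd`).
#' @param groups group labels, same length.
#' @return list with `H`, `p`, `df`, `degenerate` (TRUE when all values are
#'   tied) and `pairwise` (data.frame: group1, group2, z, p, q).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  if (length(unique(values)) == 1) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p = 1, q = 1)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1,
                degenerate = TRUE, pairwise = pw))
  }
  kt <- stats::kruskal.test(values, groups)
  # Dunn post-hoc: z on mean ranks with tie-corrected variance
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tiecor
  mr <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(v0 * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (mr[[a]] - mr[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = z, p = p, q = stats::p.adjust(p, "BH"))
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE, pairwise = pw)
}

#' Region-wise group comparison of gradient scores
#'
#' Ordinary least squares per region of gradient score on a group indicator
#' plus covariates (age and a binary sex indicator by default), returning
#' the unthresholded t-map for the group term with two-sided p values and
#' Benjamini-Hochberg q values across regions. Subjects with missing
#' covariates are excluded listwise with a warning.
#'
#' @param scores subject x region matrix of aligned gradient scores for one
#'   component (rownames are subject ids).
#' @param cohort cohort data.frame (see [as_cohort()]).
#' @param contrast character pair `c(test_group, reference_group)`; the t
#'   statistic is positive where the test group's scores exceed the
#'   reference group's.
#' @param covariates covariate column names in `cohort`.
#' @return data.frame of class `group_tmap` with columns `region_id`, `t`,
#'   `p`, `q`, plus attributes `contrast` and `df`.
#' @export
regional_model <- function(scores, cohort, contrast = c("LBD", "HC"),
                           covariates = c("age", "sex")) {
  stopifnot(length(contrast) == 2)
  if (!all(contrast %in% cohort$group))
    stop("both contrast groups must be present in the cohort")
  keep <- cohort$group %in% contrast
  coh <- cohort[keep, , drop = FALSE]
  coh <- coh[match(intersect(rownames(scores), coh$subject_id), coh$subject_id), ]
  Y <- scores[coh$subject_id, , drop = FALSE]
  X <- cbind(intercept = 1, group = as.numeric(coh$group == contrast[1]))
  for (cv in covariates) {
    v <- coh[[cv]]
    if (is.null(v)) stop("missing covariate column: ", cv)
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) excluded listwise for missing covariates")
    X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (e.g. a constant covariate within the contrast)")
  n <- nrow(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXi["group", "group"] * sigma2)
  tval <- beta["group", ] / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(region_id = colnames(scores), t = unname(tval),
                    p = unname(p), q = stats::p.adjust(p, "BH"))
  attr(out, "contrast") <- contrast
  attr(out, "df") <- df
  class(out) <- c("group_tmap", "data.frame")
  out
}

#' Aligned gradient scores for a whole cohort
#'
#' Runs the full per-subject pipeline: control-template construction from
#' the HC matrices, individual embedding, and Procrustes alignment to the
#' template; returns the subject x region score matrix for one component
#' together with the per-subject gradient sets and the template.
#'
#' Alignment operates on the orthonormal eigenvector basis (each component
#' rescaled to unit norm before the Procrustes rotation) and the subject's
#' own diffusion-time scaling `lambda / (1 - lambda)` is re-applied to the
#' rotated components. A subject's spectral scale measures its inter-
#' regional differentiation and is a property of its own connectome; under
#' the alternative of rotating the scaled scores directly, the rotation
#' leaks variance from the dominant component into weaker ones whenever a
#' subject's regional organisation differs from the template's, which
#' masquerades as gradient contraction in subjects whose organisation is
#' merely rearranged.
#'
#' @param matrices named list of `connectivity_matrix` (names are subject
#'   ids).
#' @param cohort cohort data.frame identifying the HC subjects.
#' @param config `analysis_config`.
#' @param component component label to extract as a matrix.
#' @return list with `scores` (subject x region matrix), `gradients` (named
#'   list of aligned `gradient_set`), `template` (`gradient_set`).
#' @export
cohort_gradients <- function(matrices, cohort, config = analysis_config(),
                             component = "G1") {
  hc_ids <- cohort$subject_id[cohort$group == "HC"]
  if (!length(hc_ids)) stop("no HC subjects to build the template from")
  template <- group_template(matrices[hc_ids], config)
  tmpl_basis <- normalise_components(template)
  grads <- lapply(matrices, function(m) {
    g <- subject_gradients(m, config)
    aligned <- procrustes_align(normalise_components(g), tmpl_basis)
    scale_k <- g$eigenvalues / (1 - g$eigenvalues)
    aligned$scores <- sweep(aligned$scores, 2, scale_k, "*")
    aligned$eigenvalues <- g$eigenvalues
    aligned
  })
  scores <- t(vapply(grads, function(g) g$scores[, component],
                     numeric(nrow(template$scores))))
  colnames(scores) <- matrices[[1]]$region_ids
  rownames(scores) <- names(matrices)
  list(scores = scores, gradients = grads, template = template)
}

# unit-norm columns: the orthonormal eigenvector basis of a gradient set
normalise_components <- function(g) {
  g$scores <- sweep(g$scores, 2, sqrt(colSums(g$scores^2)), "/")
  g
}
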