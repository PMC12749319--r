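#' Control reference norms per region
#'
#' Per-region mean and sample SD (denominator n - 1) of aligned gradient
#' scores across control subjects. These are the mu and sigma entering the
#' composite gradient difference score.
#'
#' @param control_scores control subject x region matrix of aligned gradient
#'   scores.
#' @return list with named numeric vectors `mu` and `sigma`.
#' @export
control_norms <- function(control_scores) {
  if (nrow(control_scores) < 2)
    stop("need at least 2 controls for sigma to be defined")
  mu <- colMeans(control_scores)
  sigma <- apply(control_scores, 2, stats::sd)
  if (any(sigma == 0))
    stop("zero control SD in region(s): ",
         paste(colnames(control_scores)[sigma == 0], collapse = ", "))
  list(mu = mu, sigma = sigma)
}

#' Composite gradient difference score Gs
#'
#' `Gs = sum over regions of |x - mu| / sigma`, the sum of absolute
#' control-referenced z-scores of a subject's regional gradient values.
#' Gs is 0 exactly when the subject equals the control mean in every region;
#' higher Gs reflects a more different overall cortical organisation than
#' controls.
#'
#' @param subject_scores named numeric vector of one subject's regional
#'   gradient scores (or a subject x region matrix for several subjects).
#' @param norms control norms from [control_norms()].
#' @return numeric Gs value (or named vector, one per subject).
#' @export
composite_gs <- function(subject_scores, norms) {
  if (is.matrix(subject_scores)) {
    if (!all(names(norms$mu) %in% colnames(subject_scores)))
      stop("missing region(s) in subject scores")
    z <- abs(sweep(subject_scores[, names(norms$mu), drop = FALSE], 2, norms$mu)) /
      rep(norms$sigma, each = nrow(subject_scores))
    return(rowSums(z))
  }
  if (!all(names(norms$mu) %in% names(subject_scores)))
    stop("missing region(s) in subject scores")
  sum(abs(subject_scores[names(norms$mu)] - norms$mu) / norms$sigma)
}

#' Spearman correlation of Gs with a clinical severity score
#'
#' Unadjusted: Spearman rank correlation with the p value from
#' [stats::cor.test()] (exact for n < 1290 without ties, AS89/t
#' approximation otherwise). Adjusted: partial Spearman computed by rank
#' transforming both variables and every numeric covariate, residualising
#' each variable on the covariates by least squares, and applying a Pearson
#' t test to the residual correlation with n - 2 - k degrees of freedom.
#' Missing values are removed pairwise and n is reported.
#'
#' @param gs numeric vector of composite scores.
#' @param score numeric vector of clinical values, same length.
#' @param adjust_for optional data.frame/matrix of covariates.
#' @return list with `rho`, `p`, `n` and `adjusted`.
#' @export
severity_correlation <- function(gs, score, adjust_for = NULL) {
  ok <- stats::complete.cases(gs, score)
  if (!is.null(adjust_for)) {
    adjust_for <- as.data.frame(adjust_for)
    adjust_for[] <- lapply(adjust_for, function(v)
      if (is.numeric(v)) v else as.numeric(factor(v)) - 1)
    ok <- ok & stats::complete.cases(adjust_for)
  }
  n <- sum(ok)
  if (n < 5) stop("need at least 5 paired observations")
  g <- gs[ok]; s <- score[ok]
  if (length(unique(g)) == 1 || length(unique(s)) == 1)
    stop("all values tied in one of the variables")
  if (is.null(adjust_for)) {
    ct <- suppressWarnings(stats::cor.test(g, s, method = "spearman"))
    return(list(rho = unname(ct$estimate), p = ct$p.value, n = n,
                adjusted = FALSE))
  }
  covs <- adjust_for[ok, , drop = FALSE]
  covs[] <- lapply(covs, function(v)
    if (length(unique(v)) > 2) rank(v) else v)   # binary indicators kept as-is
  Z <- cbind(1, as.matrix(covs))
  rg <- stats::lsfit(Z, rank(g), intercept = FALSE)$residuals
  rs <- stats::lsfit(Z, rank(s), intercept = FALSE)$residuals
  rho <- stats::cor(rg, rs)
  df <- n - 2 - (ncol(Z) - 1)
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, adjusted = TRUE)
}

#' Composite cognitive score from task z-scores
#'
#' Average of the per-task z-scores (each task standardised across the
#' supplied subjects), the construction used for a multi-domain cognitive
#' composite (global cognition plus one task per cognitive domain). Tasks
#' where lower raw scores mean better performance should be negated
#' beforehand.
#'
#' @param tasks data.frame or matrix of task scores, one row per subject.
#' @return numeric vector of composite scores (NA where any task is
#'   missing).
#' @export
composite_cognitive_score <- function(tasks) {
  z <- scale(as.matrix(tasks))
  rowMeans(z)
}
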