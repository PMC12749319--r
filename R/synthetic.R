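# Synthetic cohort generator. Connectomes are generated from a latent 1-D
# gradient: the expected edge weight between two regions decays exponentially
# with the distance between their latent coordinates, so the principal
# diffusion-map gradient of a generated matrix recovers the latent axis.
# Disease regimes act on the latent coordinates: expansion/contraction scale
# them (gamma), reorganisation permutes a fraction of them while leaving the
# overall distribution intact.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Effect specification for a simulated disease regime
#'
#' Encodes how a group's latent gradient coordinates differ from the control
#' template: `expansion` scales them by `gamma > 1` (widening the extremes of
#' the gradient distribution), `contraction` by `gamma < 1` (narrowing it),
#' and `reorganisation` permutes a fraction of coordinates at unchanged scale
#' (regional rank changes with a preserved overall distribution). `none` is
#' the control regime.
#'
#' @param regime one of `"none"`, `"expansion"`, `"contraction"`,
#'   `"reorganisation"`.
#' @param gamma positive latent scale factor; defaults to 1 (none,
#'   reorganisation), 1.3 (expansion), 0.8 (contraction).
#' @param reorg_fraction fraction in \[0, 1\] of regions whose latent
#'   coordinates are permuted (reorganisation only).
#' @param noise_sd nonnegative edge-noise scale (log-normal multiplicative
#'   noise on structural kernel means; additive Fisher-z noise for
#'   functional edges).
#' @param latent_jitter SD of per-subject Gaussian jitter added to the
#'   latent coordinates; models individual variability around the group
#'   regime.
#' @param reorg_perm optional full region permutation to use for
#'   reorganisation; when generating a cohort the permutation is drawn once
#'   per group so the planted reorganisation is a group-consistent pattern.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(regime = c("none", "expansion", "contraction", "reorganisation"),
                        gamma = NULL, reorg_fraction = 0,
                        noise_sd = 0.1, latent_jitter = 0.12,
                        reorg_perm = NULL) {
  regime <- match.arg(regime)
  if (is.null(gamma))
    gamma <- switch(regime, none = 1, expansion = 1.3, contraction = 0.8,
                    reorganisation = 1)
  if (gamma <= 0) stop("gamma must be positive")
  if (regime == "expansion" && gamma <= 1) stop("expansion requires gamma > 1")
  if (regime == "contraction" && gamma >= 1) stop("contraction requires gamma < 1")
  if (regime == "reorganisation") {
    if (reorg_fraction <= 0) stop("reorganisation requires reorg_fraction > 0")
    if (gamma != 1) stop("reorganisation requires gamma = 1")
  }
  if (reorg_fraction < 0 || reorg_fraction > 1)
    stop("reorg_fraction must be in [0, 1]")
  if (noise_sd < 0 || latent_jitter < 0)
    stop("noise scales must be nonnegative")
  structure(list(regime = regime, gamma = gamma,
                 reorg_fraction = reorg_fraction, noise_sd = noise_sd,
                 latent_jitter = latent_jitter, reorg_perm = reorg_perm),
            class = "effect_spec")
}

#' Exponential latent-distance kernel
#'
#' Expected edge strength between regions i and j:
#' `exp(-|latent_i - latent_j| / length_scale)`. Nearby regions on the latent
#' axis are strongly connected; the kernel's dominant nontrivial eigenvector
#' is aligned with the latent axis.
#'
#' @param latent numeric latent coordinates.
#' @param length_scale kernel length scale (default 1).
#' @return square matrix of expected weights in (0, 1\].
#' @export
latent_kernel <- function(latent, length_scale = 1) {
  exp(-abs(outer(latent, latent, "-")) / length_scale)
}

#' Quasi-uniform parcel centroids on the unit sphere
#'
#' Places `n_regions / 2` points per hemisphere using a Fibonacci lattice
#' rotated by a seeded random rotation; right-hemisphere centroids mirror the
#' left in the x coordinate. This is the substrate for spin permutations.
#'
#' @param n_regions even integer >= 4.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return `parcel_sphere` data.frame with columns `region_id`,
#'   `hemisphere`, `x`, `y`, `z`.
#' @export
make_parcel_sphere <- function(n_regions, seed = 0) {
  if (n_regions < 4) stop("n_regions must be at least 4")
  if (n_regions %% 2 != 0) stop("n_regions must be even")
  # each hemisphere is registered to its own full unit sphere (the
  # spherical-registration convention under which spin rotations are
  # boundary-free symmetries); the right hemisphere mirrors the left in x
  m <- n_regions / 2
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(m) - 1) * pi * (3 - sqrt(5))
  pts <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  with_seed(seed, {
    Q <- rand_rotation()
    pts <- pts %*% t(Q)
  })
  left <- pts
  right <- pts
  right[, 1] <- -right[, 1]
  df <- data.frame(
    region_id = c(sprintf("L_%03d", seq_len(m)), sprintf("R_%03d", seq_len(m))),
    hemisphere = rep(c("L", "R"), each = m),
    x = c(left[, 1], right[, 1]),
    y = c(left[, 2], right[, 2]),
    z = c(left[, 3], right[, 3]))
  class(df) <- c("parcel_sphere", "data.frame")
  df
}

# uniform random rotation (det +1) from the current RNG stream
rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# draw one connectivity matrix at given latent coordinates (current RNG)
draw_matrix <- function(latent, modality, params, noise_sd = 0) {
  n <- length(latent)
  K <- latent_kernel(latent, params$length_scale)
  ut <- upper.tri(K)
  if (modality == "structural") {
    mu <- params$count_scale * K[ut]
    if (noise_sd > 0)
      mu <- mu * exp(stats::rnorm(sum(ut), -noise_sd^2 / 2, noise_sd))
    vals <- matrix(0, n, n)
    vals[ut] <- stats::rnbinom(sum(ut), size = params$dispersion, mu = mu)
    vals <- vals + t(vals)
    diag(vals) <- 0
  } else {
    z <- atanh(pmin(pmax(2 * K[ut] - 1, -0.999), 0.999))
    if (noise_sd > 0) z <- z + stats::rnorm(sum(ut), 0, noise_sd)
    vals <- matrix(0, n, n)
    vals[ut] <- tanh(z)
    vals <- vals + t(vals)
    diag(vals) <- 1
  }
  connectivity_matrix(vals, region_ids = params$region_ids, modality = modality)
}

#' Generate a template connectome with a latent 1-D gradient
#'
#' Latent coordinates are drawn uniformly on (-`latent_range`,
#' `latent_range`) and centred; expected edge weight decays exponentially
#' with latent distance. Structural matrices carry overdispersed
#' negative-binomial streamline counts around the kernel mean (variance >
#' mean, zero diagonal); functional matrices carry correlation-like values
#' obtained by mapping the kernel into \[-1, 1\] with Fisher-z noise (unit
#' diagonal).
#'
#' @param n_regions integer >= 10.
#' @param modality `"structural"` or `"functional"`.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @param latent_range half-width of the uniform latent distribution.
#' @param length_scale kernel length scale.
#' @param count_scale expected streamline count at zero latent distance.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @return list of class `synth_template`: `matrix` (a
#'   `connectivity_matrix`), `latent` (centred coordinates) and the
#'   generator parameters.
#' @export
make_template <- function(n_regions, modality = c("structural", "functional"),
                          seed = 0, latent_range = 1.5, length_scale = 1,
                          count_scale = 150, dispersion = 8) {
  modality <- match.arg(modality)
  if (n_regions < 10) stop("n_regions must be at least 10")
  params <- list(length_scale = length_scale, count_scale = count_scale,
                 dispersion = dispersion,
                 region_ids = sprintf("roi_%03d", seq_len(n_regions)))
  with_seed(seed, {
    latent <- stats::runif(n_regions, -latent_range, latent_range)
    latent <- latent - mean(latent)
    mat <- draw_matrix(latent, modality, params)
    structure(list(matrix = mat, latent = latent, modality = modality,
                   params = params),
              class = "synth_template")
  })
}

# subject-level latent coordinates under an effect (current RNG stream)
subject_latent <- function(latent, effect) {
  n <- length(latent)
  l <- effect$gamma * latent
  if (effect$regime == "reorganisation") {
    perm <- effect$reorg_perm
    if (is.null(perm)) perm <- draw_reorg_perm(n, effect$reorg_fraction)
    l <- l[perm]
  }
  l + stats::rnorm(n, 0, effect$latent_jitter)
}

# cyclic-shift permutation moving exactly ceiling(fraction * n) regions
# (two regions when the ceiling is 1, since a single element cannot move)
draw_reorg_perm <- function(n, fraction) {
  k <- max(2L, as.integer(ceiling(fraction * n)))
  idx <- sample.int(n, k)
  perm <- seq_len(n)
  perm[idx] <- idx[c(seq_len(k)[-1], 1L)]
  perm
}

#' Generate one subject's connectome from a template and an effect
#'
#' The subject's latent coordinates are `gamma` times the template latent,
#' with a `reorg_fraction` of coordinates permuted (reorganisation regime)
#' and per-subject jitter added; edges are then re-drawn from the kernel at
#' the subject latent plus edge noise, preserving the modality constraints.
#' With `regime = "none"`, `noise_sd = 0` and `latent_jitter = 0`, the
#' subject's kernel mean equals the template's entrywise.
#'
#' @param template `synth_template` from [make_template()].
#' @param effect `effect_spec`.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @param latent optional latent coordinates overriding the template's.
#' @return `connectivity_matrix` with the subject's latent coordinates in
#'   attribute `"latent"`.
#' @export
make_subject <- function(template, effect = effect_spec("none"), seed = NULL,
                         latent = template$latent) {
  stopifnot(inherits(template, "synth_template"), inherits(effect, "effect_spec"))
  with_seed(seed, {
    l <- subject_latent(latent, effect)
    mat <- draw_matrix(l, template$modality, template$params, effect$noise_sd)
    attr(mat, "latent") <- l
    mat
  })
}

#' Gaussian-copula score rank-coupled to a reference variable
#'
#' Draws a continuous score whose Spearman correlation with `values` targets
#' `rho`: normal scores of the ranks of `values` are mixed with independent
#' Gaussian noise at the Pearson level `2 sin(pi rho / 6)` that corresponds
#' to the requested Spearman coefficient under a Gaussian copula.
#'
#' @param values numeric vector to couple to.
#' @param rho target Spearman correlation in (-1, 1).
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return numeric vector of scores (standard normal marginal).
#' @export
couple_score <- function(values, rho, seed = NULL) {
  with_seed(seed, couple_score_impl(values, rho))
}

couple_score_impl <- function(values, rho) {
  n <- length(values)
  if (abs(rho) >= 1) stop("coupling_rho must be in (-1, 1)")
  zd <- stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
  rp <- 2 * sin(pi * rho / 6)          # Pearson on normal scores targeting Spearman rho
  rp * zd + sqrt(1 - rp^2) * stats::rnorm(n)
}

#' Generate a full synthetic cohort with planted group effects
#'
#' Builds one control template connectome and one connectome per subject,
#' applying each group's effect regime. Defaults emulate the study
#' conditions: 23 HC, 46 PD-NC, 62 LBD; PD-NC planted as gradient expansion
#' (gamma 1.3), LBD as regional reorganisation (30% of regions, shared
#' within the group); ages and male proportions drawn per group from the
#' cohort demographics (HC 66.8 (8.6) years, 48% male; PD-NC 62.3 (7.2),
#' 48%; LBD 70.1 (6.7), 81%). A synthetic cognitive score is rank-coupled to
#' each subject's planted latent deviation at Spearman `coupling_rho` via a
#' Gaussian copula (negated so that worse cognition accompanies larger
#' deviation, as for a cognitive composite).
#'
#' @param group_sizes named integer vector (names HC, PD-NC, LBD).
#' @param effects named list of `effect_spec`, one per group.
#' @param coupling_rho target Spearman correlation in (-1, 1) between
#'   planted deviation and the synthetic cognitive score.
#' @param seed integer seed.
#' @param n_regions number of parcels (even; default 200).
#' @param modality connectome modality.
#' @param ... further arguments passed to [make_template()].
#' @return list with elements `cohort` (data.frame: subject_id, group, age,
#'   sex, cognitive_score, planted_deviation), `matrices` (named list of
#'   `connectivity_matrix`), `template` (`synth_template`), and `sphere`
#'   (`parcel_sphere`).
#' @export
make_cohort <- function(group_sizes = c(HC = 23, "PD-NC" = 46, LBD = 62),
                        effects = list(
                          HC = effect_spec("none"),
                          "PD-NC" = effect_spec("expansion"),
                          LBD = effect_spec("reorganisation", reorg_fraction = 0.3)),
                        coupling_rho = 0.5, seed = 0, n_regions = 200,
                        modality = "structural", ...) {
  if (any(group_sizes < 1)) stop("empty group in group_sizes")
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% c("HC", "PD-NC", "LBD")))
    stop("group_sizes must be named with labels among HC, PD-NC, LBD")
  if (!all(groups %in% names(effects)))
    stop("missing effect_spec for group(s): ",
         paste(setdiff(groups, names(effects)), collapse = ", "))
  demog <- list("HC" = c(66.8, 8.6, 0.478),
                "PD-NC" = c(62.3, 7.2, 0.478),
                "LBD" = c(70.1, 6.7, 0.806))
  with_seed(seed, {
    template <- make_template(n_regions, modality, seed = NULL, ...)
    sphere <- make_parcel_sphere(n_regions, seed = NULL)
    template$matrix$region_ids <- sphere$region_id
    template$params$region_ids <- sphere$region_id
    subjects <- list(); matrices <- list()
    idx <- 0
    for (g in groups) {
      eff <- effects[[g]]
      # one reorganisation pattern per group: the planted pattern is a
      # disease trait, shared across that group's subjects
      if (eff$regime == "reorganisation" && is.null(eff$reorg_perm))
        eff$reorg_perm <- draw_reorg_perm(n_regions, eff$reorg_fraction)
      for (i in seq_len(group_sizes[[g]])) {
        idx <- idx + 1
        sid <- sprintf("sub-%03d", idx)
        mat <- make_subject(template, eff, seed = NULL)
        dev <- mean(abs(attr(mat, "latent") - template$latent))
        subjects[[sid]] <- data.frame(
          subject_id = sid, group = g,
          age = stats::rnorm(1, demog[[g]][1], demog[[g]][2]),
          sex = if (stats::runif(1) < demog[[g]][3]) "M" else "F",
          planted_deviation = dev)
        matrices[[sid]] <- mat
      }
    }
    cohort <- do.call(rbind, subjects)
    rownames(cohort) <- NULL
    cohort$cognitive_score <- -couple_score(cohort$planted_deviation, coupling_rho)
    cohort <- as_cohort(cohort)
    list(cohort = cohort, matrices = matrices, template = template,
         sphere = sphere)
  })
}

#' Spatially autocorrelated map on the parcel sphere
#'
#' White noise per parcel smoothed by a geodesic-distance exponential kernel
#' within each hemisphere's sphere, then z-scored across parcels (mean 0,
#' SD 1). As `smoothness` tends to 0 the map tends to white noise.
#'
#' With `homotopic = TRUE` (the default) the smoothed field is averaged with
#' its value at the mirrored parcel before z-scoring, so left/right mirror
#' pairs carry equal values. This emulates the strong bilateral symmetry of
#' normative annotation maps (cell densities, laminar thickness,
#' cytoarchitectural axes) and is the structure under which mirrored spin
#' rotations preserve exchangeability.
#'
#' @param sphere `parcel_sphere`.
#' @param smoothness kernel length scale in radians (> 0).
#' @param seed integer seed (NULL to use the current RNG stream).
#' @param homotopic mirror-symmetrise the field across hemispheres.
#' @return named numeric regional map.
#' @export
make_smooth_map <- function(sphere, smoothness = 0.6, seed = NULL,
                            homotopic = TRUE) {
  with_seed(seed, {
    v <- smooth_fields(sphere, smoothness, 1, homotopic)[, 1]
    stats::setNames(v, sphere$region_id)
  })
}

# draw n_draws smoothed (optionally homotopic) z-scored fields using the
# current RNG stream; the kernel is built once for all draws
smooth_fields <- function(sphere, smoothness, n_draws, homotopic = TRUE) {
  if (smoothness <= 0) stop("smoothness must be positive")
  X <- as.matrix(sphere[, c("x", "y", "z")])
  gd <- acos(pmin(pmax(tcrossprod(X), -1), 1))
  # hemispheres live on separate registration spheres: no smoothing across
  same_hemi <- outer(sphere$hemisphere, sphere$hemisphere, "==")
  W <- exp(-gd / smoothness) * same_hemi
  V <- W %*% matrix(stats::rnorm(nrow(X) * n_draws), nrow(X))
  if (homotopic) {
    Xm <- X
    Xm[, 1] <- -Xm[, 1]
    cross <- tcrossprod(X, Xm)
    cross[same_hemi] <- -Inf   # mirror partner is in the other hemisphere
    mirror <- max.col(cross, ties.method = "first")
    V <- (V + V[mirror, , drop = FALSE]) / 2
  }
  V <- sweep(V, 2, colMeans(V))
  sweep(V, 2, apply(V, 2, stats::sd), "/")
}

#' Synthetic region x gene expression table
#'
#' Each gene column is a spatially autocorrelated map; planted genes are
#' mixed with their target map at the stated effect size (`effect` in
#' \[0, 1\]: column = effect * z(target) + sqrt(1 - effect^2) * z(noise
#' map)), then squashed into \[0, 1\] by a sigmoid (emulating scaled
#' outlier-robust normalisation of expression values). Effect 1 yields a
#' monotone transform of the target map.
#'
#' @param sphere `parcel_sphere`.
#' @param n_genes number of genes (>= number of planted genes).
#' @param planted named list: for each planted gene symbol, a list with
#'   elements `map` (named regional map) and `effect` (in \[0, 1\]). Planted
#'   symbols take over the first columns of the table.
#' @param smoothness length scale of the per-gene noise maps; the default
#'   0.1 gives genes a mild spatial autocorrelation, well below that of
#'   macroscale annotation axes, so that unplanted genes are essentially
#'   uncorrelated with any target map.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return numeric matrix regions x genes in \[0, 1\], region ids as
#'   rownames, gene symbols as colnames.
#' @export
make_expression <- function(sphere, n_genes, planted = list(),
                            smoothness = 0.1, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(planted) > n_genes)
    stop("more planted genes than n_genes")
  n <- nrow(sphere)
  symbols <- sprintf("gene%04d", seq_len(n_genes))
  if (length(planted)) symbols[seq_along(planted)] <- names(planted)
  with_seed(seed, {
    Z <- smooth_fields(sphere, smoothness, n_genes)
    for (j in seq_along(planted)) {
      pl <- planted[[j]]
      tgt <- pl$map[sphere$region_id]
      tgt <- (tgt - mean(tgt)) / stats::sd(tgt)
      Z[, j] <- pl$effect * tgt + sqrt(1 - pl$effect^2) * Z[, j]
    }
    out <- 1 / (1 + exp(-Z))
    dimnames(out) <- list(sphere$region_id, symbols)
    out
  })
}
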