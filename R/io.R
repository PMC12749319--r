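# Tabular formats: tab-separated text with labelled rows/columns. Numeric
# values are written with 17 significant digits so that write -> read is
# bit-exact for doubles.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_body <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

read_tsv_body <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a connectivity matrix from labelled TSV
#'
#' Expects a header row of region labels and a first column of region labels,
#' with a square numeric body (rectangular allowed for `modality = "fused"`).
#' Within-tolerance asymmetries are removed by averaging with the transpose;
#' NaN entries, duplicate labels, a non-square body, or negative structural
#' weights are errors.
#'
#' @param path file path to a TSV written by [write_matrix()].
#' @param modality `"structural"`, `"functional"` or `"fused"`.
#' @return a `connectivity_matrix`.
#' @export
read_matrix <- function(path, modality = c("structural", "functional", "fused")) {
  modality <- match.arg(modality)
  df <- read_tsv_body(path)
  ids <- as.character(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(body) <- "double"
  if (modality != "fused" && nrow(body) != ncol(body))
    stop("non-square matrix body in ", path,
         " (", nrow(body), " x ", ncol(body), ")")
  connectivity_matrix(body, region_ids = ids, modality = modality)
}

#' Write a connectivity matrix as labelled TSV
#'
#' @param matrix a `connectivity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  vals <- matrix$values
  ids <- matrix$region_ids
  cols <- if (ncol(vals) == length(ids)) ids else
    c(paste0(ids, "|SC"), paste0(ids, "|FC"))
  body <- apply(vals, 2, fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(vals))
  df <- data.frame(region_id = ids, body, check.names = FALSE)
  names(df) <- c("region_id", cols)
  write_tsv_body(df, path)
  invisible(path)
}

#' Read a regional map (one scalar per parcel)
#'
#' @param path TSV with columns `region_id`, `value`.
#' @return named numeric vector (names are region ids).
#' @export
read_regional_map <- function(path) {
  df <- read_tsv_body(path)
  if (!all(c("region_id", "value") %in% names(df)))
    stop("regional map must have columns region_id, value: ", path)
  stats::setNames(as.numeric(df$value), as.character(df$region_id))
}

#' Write a regional map
#'
#' @param map named numeric vector (names are region ids).
#' @param path output file path.
#' @export
write_regional_map <- function(map, path) {
  df <- data.frame(region_id = names(map), value = fmt_num(unname(map)))
  write_tsv_body(df, path)
  invisible(path)
}

#' Read a cohort table
#'
#' Mandatory columns: `subject_id`, `group`, `age`, `sex`; any further
#' columns are treated as clinical scores. Group labels are restricted to
#' HC, PD-NC and LBD. Missing score cells are kept as NA (flagged, never
#' imputed).
#'
#' @param path TSV file path.
#' @return data.frame of class `cohort` with `group` as a factor with levels
#'   HC, PD-NC, LBD.
#' @export
read_cohort <- function(path) {
  df <- read_tsv_body(path)
  as_cohort(df)
}

#' Validate a data.frame as a cohort table
#'
#' @param df data.frame with columns `subject_id`, `group`, `age`, `sex`.
#' @return the validated data.frame, `group` coerced to factor.
#' @export
as_cohort <- function(df) {
  mandatory <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("cohort table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  allowed <- c("HC", "PD-NC", "LBD")
  bad <- setdiff(unique(as.character(df$group)), allowed)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are ", paste(allowed, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in cohort table")
  df$group <- factor(as.character(df$group), levels = allowed)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write a cohort table
#'
#' @param cohort cohort data.frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write_tsv_body(df, path)
  invisible(path)
}

#' Read parcel sphere coordinates
#'
#' @param path TSV with columns `region_id`, `hemisphere` (L/R), `x`, `y`,
#'   `z`; each centroid must lie on the unit sphere.
#' @return data.frame of class `parcel_sphere`.
#' @export
read_sphere <- function(path) {
  df <- read_tsv_body(path)
  need <- c("region_id", "hemisphere", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("parcel sphere must have columns ", paste(need, collapse = ", "))
  df[c("x", "y", "z")] <- lapply(df[c("x", "y", "z")], as.numeric)
  r <- sqrt(df$x^2 + df$y^2 + df$z^2)
  if (any(abs(r - 1) > 1e-6))
    stop("parcel centroids must lie on the unit sphere")
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be L or R")
  class(df) <- c("parcel_sphere", "data.frame")
  df
}

#' Write parcel sphere coordinates
#'
#' @param sphere `parcel_sphere` data.frame.
#' @param path output file path.
#' @export
write_sphere <- function(sphere, path) {
  df <- as.data.frame(sphere)
  df[c("x", "y", "z")] <- lapply(df[c("x", "y", "z")], fmt_num)
  write_tsv_body(df, path)
  invisible(path)
}

#' Read a region x gene expression table
#'
#' @param path TSV with a `region_id` column and one column per gene symbol.
#' @return numeric matrix regions x genes with region ids as rownames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_body(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a region x gene expression table
#'
#' @param expression numeric matrix regions x genes, region ids as rownames.
#' @param path output file path.
#' @export
write_expression <- function(expression, path) {
  body <- apply(expression, 2, fmt_num)
  df <- data.frame(region_id = rownames(expression), body, check.names = FALSE)
  write_tsv_body(df, path)
  invisible(path)
}

# generic labelled numeric matrix (e.g. subject x region score tables)
write_labelled_matrix <- function(m, path, label = "subject_id") {
  body <- apply(m, 2, fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  df <- data.frame(rownames(m), body, check.names = FALSE)
  names(df) <- c(label, colnames(m))
  write_tsv_body(df, path)
  invisible(path)
}

read_labelled_matrix <- function(path) {
  df <- read_tsv_body(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Analysis configuration
#'
#' Houses the tunable parameters of the gradient pipeline. Defaults follow
#' the main analysis: 10 gradients, row sparsity 0.9 (keep the top 10% of
#' weights), diffusion anisotropy alpha = 0.5, 1000 spatial permutations,
#' FDR level 0.05, age and sex as covariates. Sparsity 0.8 and 0.5 are the
#' replication settings.
#'
#' @param n_components number of gradients (>= 1).
#' @param sparsity fraction in \[0, 1) of weights zeroed per row.
#' @param alpha diffusion anisotropy exponent in \[0, 1\].
#' @param n_permutations number of spin permutations (>= 1).
#' @param seed integer seed for all randomised stages.
#' @param fdr_level FDR threshold in (0, 1).
#' @param covariates character vector of covariate column names.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(n_components = 10, sparsity = 0.9, alpha = 0.5,
                            n_permutations = 1000, seed = 0,
                            fdr_level = 0.05, covariates = c("age", "sex")) {
  stopifnot(n_components >= 1, sparsity >= 0, sparsity < 1,
            alpha >= 0, alpha <= 1, n_permutations >= 1,
            fdr_level > 0, fdr_level < 1)
  structure(list(n_components = as.integer(n_components), sparsity = sparsity,
                 alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), fdr_level = fdr_level,
                 covariates = covariates),
            class = "analysis_config")
}

#' Read an analysis configuration from a flat key-value YAML file
#'
#' Unknown keys are an error (guards against silent typos); absent keys fall
#' back to the defaults of [analysis_config()].
#'
#' @param path YAML file of flat `key: value` pairs.
#' @return `analysis_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Write a JSON run manifest
#'
#' Records every configuration field actually used by a stage, the seed, and
#' the package version, so any output directory is self-describing.
#'
#' @param config `analysis_config` used for the run.
#' @param path output JSON path.
#' @param extra named list of further fields (e.g. the subcommand, inputs).
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- c(unclass(config),
                list(package = "lbdgrad",
                     version = as.character(utils::packageVersion("lbdgrad"))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
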