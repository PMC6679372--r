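## TSV readers/writers for dH/dlambda and energy time series, the lambda
## manifest, and the affinity table. All writers round-trip at full float
## precision; display rounding happens only in report rendering. Lines
## starting with '#' are metadata/comments and are skipped on read.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' of %s (data row %d)",
                 raw[bad[1]], col, path, bad[1]))
  if (anyNA(val))
    stop(sprintf("missing value in column '%s' of %s (data row %d)",
                 col, path, which(is.na(val))[1]))
  val
}

#' Write a dH/dlambda series to TSV
#'
#' Two columns (\code{step}, \code{dhdl_kJ_per_mol}) with \code{#}-prefixed
#' header lines recording the lambda value and, when known, the seed.
#'
#' @param series A \code{\link{dhdl_series}}.
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return \code{path}, invisibly.
#' @export
write_dhdl <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "dhdl_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda = %.17g", series$lambda_value), con)
  if (!is.null(seed)) writeLines(sprintf("# seed = %d", as.integer(seed)), con)
  writeLines("step\tdhdl_kJ_per_mol", con)
  writeLines(sprintf("%d\t%.17g", seq_along(series$samples), series$samples), con)
  invisible(path)
}

#' Read a dH/dlambda series from TSV
#'
#' @param path TSV file with header columns \code{step} and
#'   \code{dhdl_kJ_per_mol}; a \code{# lambda = ...} comment line or the
#'   \code{lambda_value} argument supplies the coupling value.
#' @param lambda_value Coupling value; overrides the file header when given.
#' @return A \code{\link{dhdl_series}}.
#' @export
read_dhdl <- function(path, lambda_value = NULL) {
  if (is.null(lambda_value)) {
    hdr <- grep("^#\\s*lambda\\s*=", readLines(path, n = 10L), value = TRUE)
    if (length(hdr) == 0L)
      stop("no lambda recorded in ", path, " and none supplied")
    lambda_value <- as.numeric(sub("^#\\s*lambda\\s*=\\s*", "", hdr[1]))
  }
  if (is.na(lambda_value) || lambda_value < 0 || lambda_value > 1)
    stop(sprintf("lambda value %s outside [0, 1] in %s", lambda_value, path))
  df <- .read_tsv(path)
  if (!all(c("step", "dhdl_kJ_per_mol") %in% names(df)))
    stop("expected header columns 'step' and 'dhdl_kJ_per_mol' in ", path)
  if (nrow(df) == 0L) stop("empty data section in ", path)
  dhdl_series(.numeric_column(df, "dhdl_kJ_per_mol", path), lambda_value,
              source_label = path)
}

#' Write an energy series to TSV
#'
#' Columns \code{step} and \code{E_lig_surr_kJ_per_mol}, with state and
#' environment recorded in \code{#} header lines.
#'
#' @param series An \code{\link{energy_series}}.
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return \code{path}, invisibly.
#' @export
write_energy_series <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "energy_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state = %s", series$state_label), con)
  writeLines(sprintf("# environment = %s", series$environment), con)
  if (!is.null(seed)) writeLines(sprintf("# seed = %d", as.integer(seed)), con)
  writeLines("step\tE_lig_surr_kJ_per_mol", con)
  writeLines(sprintf("%d\t%.17g", seq_along(series$samples), series$samples), con)
  invisible(path)
}

#' Read an energy series from TSV
#'
#' @param path TSV file written by \code{\link{write_energy_series}} (or of
#'   the same dialect).
#' @param state_label,environment Override the file header when given.
#' @return An \code{\link{energy_series}}.
#' @export
read_energy_series <- function(path, state_label = NULL, environment = NULL) {
  hdr <- readLines(path, n = 10L)
  pick <- function(key, default) {
    h <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(h)) sub(sprintf("^#\\s*%s\\s*=\\s*", key), "", h[1]) else default
  }
  if (is.null(state_label)) state_label <- pick("state", "A")
  if (is.null(environment)) environment <- pick("environment", "water")
  df <- .read_tsv(path)
  if (!all(c("step", "E_lig_surr_kJ_per_mol") %in% names(df)))
    stop("expected header columns 'step' and 'E_lig_surr_kJ_per_mol' in ", path)
  if (nrow(df) == 0L) stop("empty data section in ", path)
  energy_series(.numeric_column(df, "E_lig_surr_kJ_per_mol", path),
                state_label = state_label, environment = environment)
}

#' Write / read a lambda manifest
#'
#' A manifest lists, in ascending lambda order, the per-lambda dH/dlambda
#' files of one transformation so that a TI profile can be reassembled from
#' individual series files.
#'
#' @param lambdas Numeric vector of lambda values.
#' @param files Character vector of series file names (same order).
#' @param path Manifest file path.
#' @return \code{path} invisibly (writer); data frame with columns
#'   \code{lambda} and \code{file} (reader).
#' @export
write_lambda_manifest <- function(lambdas, files, path) {
  stopifnot(length(lambdas) == length(files), !is.unsorted(lambdas))
  utils::write.table(data.frame(lambda = lambdas, file = files),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lambda_manifest
#' @export
read_lambda_manifest <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("lambda", "file") %in% names(df)))
  df$lambda <- .numeric_column(df, "lambda", path)
  if (any(df$lambda < 0 | df$lambda > 1))
    stop("manifest lambda values outside [0, 1] in ", path)
  if (is.unsorted(df$lambda, strictly = TRUE))
    stop("manifest lambda values must be strictly increasing in ", path)
  df
}

#' Read TI profile from a lambda manifest
#'
#' @param manifest_path Manifest file; series paths are resolved relative to
#'   its directory.
#' @return A \code{\link{ti_profile}}.
#' @export
read_ti_profile <- function(manifest_path) {
  man <- read_lambda_manifest(manifest_path)
  dir <- dirname(manifest_path)
  series <- lapply(seq_len(nrow(man)), function(i) {
    read_dhdl(file.path(dir, man$file[i]), lambda_value = man$lambda[i])
  })
  ti_profile(series)
}

#' Read an affinity table from TSV
#'
#' Expects columns \code{compound}, \code{pose}, \code{qualifier}
#' (\code{=} for measured values, \code{>} for censored lower bounds),
#' \code{exp_ddG}, and one numeric column per nitrogen charge named by the
#' charge value.
#'
#' @param path TSV file path.
#' @return An \code{\link{affinity_table}}.
#' @export
read_affinity_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("compound", "pose", "qualifier", "exp_ddG")
  if (!all(need %in% names(df)))
    stop("affinity table ", path, " needs columns: ", paste(need, collapse = ", "))
  df$exp_ddG <- .numeric_column(df, "exp_ddG", path)
  for (col in setdiff(names(df), need)) df[[col]] <- .numeric_column(df, col, path)
  affinity_table(df)
}

#' Packaged affinity comparison table
#'
#' The experimental relative binding free energies of the pyrimidine-to-
#' pyridine (2 > 3) transformations of the diarylacetamidopyridine series
#' (with the censored \code{>12.9} lower bounds of the j compound) together
#' with the calculated values for seven nitrogen partial charges between
#' -0.74 e and -0.34 e. Ships with the package so the statistics layer is
#' usable without any simulation.
#'
#' @return An \code{\link{affinity_table}} with 7 rows and 7 charge columns.
#' @export
a3_affinity_table <- function() {
  read_affinity_table(system.file("extdata", "a3_affinity_table.tsv",
                                  package = "alchemr", mustWork = TRUE))
}

#' Packaged energy--entropy decomposition table
#'
#' Per-environment ligand--surrounding energy differences (with
#' block-averaged errors) and entropic contributions of the 2 > 3
#' transformations, the relative binding free energies of the same
#' transformations, and the published bound-minus-unbound difference
#' columns for cross-checking.
#'
#' @return A data frame, one row per transformation.
#' @export
a3_decomposition_table <- function() {
  .read_tsv(system.file("extdata", "a3_decomposition_table.tsv",
                        package = "alchemr", mustWork = TRUE))
}

#' Write a free-energy result as JSON
#'
#' @param fe A \code{\link{free_energy}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_free_energy_json <- function(fe, path) {
  stopifnot(inherits(fe, "free_energy"))
  jsonlite::write_json(list(value = fe$value, sigma = fe$sigma,
                            method = fe$method, direction = fe$direction,
                            ess = fe$ess, low_overlap = fe$low_overlap),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_free_energy_json
#' @export
read_free_energy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  free_energy(x$value, x$sigma, x$method, x$direction,
              ess = if (is.null(x$ess)) NA_real_ else x$ess,
              low_overlap = isTRUE(x$low_overlap))
}
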