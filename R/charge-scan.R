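#' Affinity comparison table
#'
#' Holds, per compound/pose, the experimental relative binding free energy
#' (with an equality or lower-bound qualifier for censored measurements)
#' and the calculated value for each nitrogen partial charge on the
#' perturbed ring. The charge grid is carried as numeric column metadata.
#'
#' @param df Data frame with columns \code{compound}, \code{pose}
#'   (\code{"1"}, \code{"2"} or \code{"none"}), \code{qualifier}
#'   (\code{"="} or \code{">"}), \code{exp_ddG}, plus one numeric column per
#'   charge named by the charge value (e.g. \code{"-0.54"}).
#' @return An \code{affinity_table} (a data frame subclass with a
#'   \code{charges} attribute).
#' @seealso \code{\link{read_affinity_table}}, \code{\link{a3_affinity_table}}
#' @export
affinity_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("compound", "pose", "qualifier", "exp_ddG")
  if (!all(need %in% names(df)))
    stop("affinity table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$qualifier %in% c("=", ">")))
    stop("unknown qualifier(s): ",
         paste(unique(setdiff(df$qualifier, c("=", ">"))), collapse = ", "),
         " (use '=' for measured values, '>' for censored lower bounds)")
  key <- paste(df$compound, df$pose)
  if (anyDuplicated(key))
    stop("duplicate compound/pose rows: ", paste(key[duplicated(key)], collapse = ", "))
  charge_cols <- setdiff(names(df), need)
  charges <- suppressWarnings(as.numeric(charge_cols))
  if (length(charge_cols) == 0L || anyNA(charges))
    stop("charge columns must be named by their numeric charge value")
  df$compound <- as.character(df$compound)
  df$pose <- as.character(df$pose)
  structure(df, charges = charges, class = c("affinity_table", "data.frame"))
}

.charge_column <- function(table, charge) {
  charges <- attr(table, "charges")
  j <- which(abs(charges - charge) < 1e-9)
  if (length(j) != 1L)
    stop(sprintf("charge %g is not in the table grid (%s)", charge,
                 paste(format(charges), collapse = ", ")))
  cols <- setdiff(names(table), c("compound", "pose", "qualifier", "exp_ddG"))
  table[[cols[j]]]
}

#' Mean absolute error of calculated vs experimental affinities
#'
#' MAE between calculated and experimental relative binding free energies
#' over the non-censored compounds a, d, g and m, where the calculated
#' value for compound m is the arithmetic mean over its two binding poses.
#' Compounds whose experimental value is a censored lower bound (j) carry
#' no point estimate and are excluded.
#'
#' @param table An \code{\link{affinity_table}}.
#' @param charge Nitrogen partial charge (e), present in the table grid.
#' @return MAE in kJ/mol.
#' @export
scan_mae <- function(table, charge) {
  stopifnot(inherits(table, "affinity_table"))
  calc <- .charge_column(table, charge)
  err <- vapply(c("a", "d", "g", "m"), function(cmp) {
    i <- which(table$compound == cmp)
    if (length(i) == 0L)
      stop(sprintf("compound '%s' missing from the table; MAE is defined over a, d, g, m", cmp))
    abs(mean(calc[i]) - mean(table$exp_ddG[i]))
  }, numeric(1))
  mean(err)
}

## point set for correlation/regression: every row except the j pose-1
## outlier; censored rows enter at their bound value
.scan_points <- function(table, charge) {
  calc <- .charge_column(table, charge)
  keep <- !(table$compound == "j" & table$pose == "1")
  data.frame(exp = table$exp_ddG[keep], calc = calc[keep])
}

#' Squared correlation of calculated vs experimental affinities
#'
#' Squared Pearson correlation over all compound/pose rows except pose 1 of
#' compound j (whose computed value is known not to reflect the binding
#' mode). Censored lower-bound rows enter at their bound value; poses are
#' not averaged.
#'
#' @inheritParams scan_mae
#' @return \eqn{r^2} (dimensionless, in \[0, 1\]).
#' @export
scan_r2 <- function(table, charge) {
  stopifnot(inherits(table, "affinity_table"))
  pts <- .scan_points(table, charge)
  if (nrow(pts) < 3L)
    stop("need at least 3 points for a correlation coefficient")
  stats::cor(pts$calc, pts$exp)^2
}

#' Regression of calculated on experimental affinities
#'
#' Ordinary least-squares fit of the calculated values on the experimental
#' ones over the same point set as \code{\link{scan_r2}}. The slope tracks
#' how strongly the computed affinities respond to the experimental spread:
#' slopes below 1 indicate compressed predictions, and the slope decreases
#' monotonically as the nitrogen charge magnitude is reduced.
#'
#' @inheritParams scan_mae
#' @return List with \code{slope} and \code{intercept}.
#' @export
scan_regression <- function(table, charge) {
  stopifnot(inherits(table, "affinity_table"))
  pts <- .scan_points(table, charge)
  if (nrow(pts) < 2L)
    stop("need at least 2 points for a regression")
  fit <- stats::lm(calc ~ exp, data = pts)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Full charge-scan statistics
#'
#' Evaluates MAE, \eqn{r^2}, slope and intercept for every charge in the
#' table grid.
#'
#' @param table An \code{\link{affinity_table}}.
#' @return Data frame with one row per charge and columns \code{charge},
#'   \code{mae}, \code{r2}, \code{slope}, \code{intercept}.
#' @export
scan_statistics <- function(table) {
  stopifnot(inherits(table, "affinity_table"))
  charges <- attr(table, "charges")
  do.call(rbind, lapply(charges, function(q) {
    reg <- scan_regression(table, q)
    data.frame(charge = q, mae = scan_mae(table, q), r2 = scan_r2(table, q),
               slope = reg$slope, intercept = reg$intercept)
  }))
}

#' Scatter plot of calculated vs experimental affinities
#'
#' Experimental-vs-calculated scatter for one charge column, with the
#' identity diagonal, dotted bounds at +/- 4.2 kJ/mol (1 kcal/mol) and the
#' regression line over the non-outlier point set. Requires ggplot2.
#'
#' @inheritParams scan_mae
#' @return A ggplot object.
#' @export
plot_scan <- function(table, charge) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan requires the ggplot2 package")
  calc <- .charge_column(table, charge)
  df <- data.frame(exp = table$exp_ddG, calc = calc,
                   label = paste0(table$compound,
                                  ifelse(table$pose == "none", "", table$pose)),
                   censored = table$qualifier == ">")
  reg <- scan_regression(table, charge)
  ggplot2::ggplot(df, ggplot2::aes(x = exp, y = calc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-4.2, 4.2), linetype = "dotted") +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                         colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(shape = censored)) +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "experimental ddG (kJ/mol)",
                  y = sprintf("calculated ddG (kJ/mol), q = %g e", charge)) +
    ggplot2::theme_minimal()
}
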