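# Ordinary least squares fitting of correction coefficients with
# leave-one-out cross-validation: n molecules -> n fits, each omitting one
# molecule; the omitted molecule's corrected HFE is its out-of-sample
# prediction, and reported coefficients are the mean over folds.
#
# The response is the correction each molecule needs, y = dg_exp - dg_method,
# regressed on the design rows of the chosen model kind. This is
# algebraically identical to fitting the corrected-HFE equation for dg_exp,
# and lets one fitter serve PMVC, ECC and PMVECC.

#' Ordinary least squares via QR decomposition
#'
#' Solves `argmin ||y - X beta||^2` through a (pivoted) QR decomposition
#' rather than the normal equations. Rank-deficient designs are an error that
#' names the dependent columns (e.g. an element present in no training
#' molecule).
#'
#' @param X numeric design matrix, `nrow(X) >= ncol(X)`.
#' @param y numeric response, `length(y) == nrow(X)`.
#' @return named numeric coefficient vector.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < ncol(X)) stop("underdetermined system: fewer rows than columns")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("design matrix and response must be finite")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    if (is.null(dep)) dep <- as.character(qx$pivot[seq(qx$rank + 1L, ncol(X))])
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  stats::setNames(as.numeric(beta), colnames(X))
}

resolve_element_order <- function(kind, records, element_order) {
  if (kind == "PMVC") return(character(0))
  counts <- element_counts(records)
  observed <- colnames(counts)[colSums(counts) > 0]
  if (identical(element_order, "auto") || is.null(element_order)) {
    element_order_canonical(observed)
  } else {
    normalize_element(element_order)
  }
}

#' Fit a correction model with leave-one-out cross-validation
#'
#' Performs n ordinary least squares fits, each leaving out one molecule, and
#' aggregates them: reported coefficients are the per-parameter mean over
#' folds, with three dispersion measures (SD over folds, SEM = SD/sqrt(n),
#' and the jackknife standard error, which estimates the standard error of
#' the coefficients themselves). Each molecule's leave-out prediction is its
#' `dg_method` plus the correction term of the model fitted without it.
#'
#' @param records a [molecule_table()]; every row needs `dg_exp` and
#'   `dg_method`, plus `pmv` for PMV-kind models.
#' @param kind `"PMVC"`, `"ECC"` or `"PMVECC"`.
#' @param element_order `"auto"` (elements observed in the records, canonical
#'   atomic-number order) or an explicit symbol vector.
#' @param min_element_support minimum number of molecules that must contain
#'   each fitted element (default 1). Elements carried by fewer than 5
#'   molecules trigger a warning: their folds are unstable.
#' @return an object of class `hfe_fit` with components
#'   `per_fold_coefficients` (n x p matrix), `mean_model` and `full_model`
#'   ([correction_model()]s), `coeff_sd`, `coeff_sem`, `coeff_se_jack`,
#'   `loo_predictions` (named by id), and the input ids/energies.
#' @seealso [full_fit()] for a single fit on all records; [coef.hfe_fit()],
#'   [predict.hfe_fit()], [summary.hfe_fit()].
#' @export
loo_fit <- function(records, kind, element_order = "auto",
                    min_element_support = 1L) {
  kind <- match.arg(toupper(kind), c("PMVC", "ECC", "PMVECC"))
  stopifnot(inherits(records, "molecule_table"), min_element_support >= 1L)
  if (anyNA(records$dg_exp)) {
    stop("missing dg_exp for molecule ",
         paste(records$id[is.na(records$dg_exp)], collapse = ", "))
  }
  if (anyNA(records$dg_method)) {
    stop("missing dg_method for molecule ",
         paste(records$id[is.na(records$dg_method)], collapse = ", "))
  }
  element_order <- resolve_element_order(kind, records, element_order)
  check_element_support(records, element_order, min_element_support)
  X <- design_matrix(kind, records, element_order)
  y <- records$dg_exp - records$dg_method
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L) {
    stop("need at least ", p + 1L, " molecules to leave-one-out fit ", p,
         " parameters; got ", n)
  }
  folds <- matrix(NA_real_, n, p, dimnames = list(records$id, colnames(X)))
  loo_pred <- stats::setNames(numeric(n), records$id)
  for (i in seq_len(n)) {
    beta <- ols_fit(X[-i, , drop = FALSE], y[-i])
    folds[i, ] <- beta
    loo_pred[i] <- records$dg_method[i] + sum(X[i, ] * beta)
  }
  beta_full <- ols_fit(X, y)
  beta_mean <- colMeans(folds)
  dev <- sweep(folds, 2L, beta_mean)
  coeff_sd <- sqrt(colSums(dev^2) / (n - 1L))
  structure(list(
    kind = kind,
    element_order = element_order,
    n = n,
    per_fold_coefficients = folds,
    mean_model = model_from_coefficients(kind, beta_mean, element_order),
    full_model = model_from_coefficients(kind, beta_full, element_order),
    coeff_sd = coeff_sd,
    coeff_sem = coeff_sd / sqrt(n),
    coeff_se_jack = sqrt((n - 1L) / n * colSums(dev^2)),
    loo_predictions = loo_pred,
    ids = records$id,
    dg_exp = stats::setNames(records$dg_exp, records$id),
    dg_method = stats::setNames(records$dg_method, records$id),
    call = match.call()
  ), class = "hfe_fit")
}

check_element_support <- function(records, element_order, min_support) {
  if (length(element_order) == 0L) return(invisible())
  counts <- element_counts(records)
  support <- stats::setNames(integer(length(element_order)), element_order)
  shared <- intersect(element_order, colnames(counts))
  support[shared] <- colSums(counts[, shared, drop = FALSE] > 0)
  low <- support < min_support
  if (any(low)) {
    stop("element(s) below min_element_support (", min_support, "): ",
         paste(sprintf("%s (%d)", names(support)[low], support[low]),
               collapse = ", "))
  }
  weak <- support < 5L
  if (any(weak)) {
    warning("element(s) carried by fewer than 5 molecules: ",
            paste(sprintf("%s (%d)", names(support)[weak], support[weak]),
                  collapse = ", "),
            "; leave-one-out folds for these coefficients are unstable")
  }
  invisible(support)
}

#' Single OLS fit on all records
#'
#' Convenience fit of the correction coefficients on the full record set
#' (no cross-validation).
#'
#' @inheritParams loo_fit
#' @return a [correction_model()].
#' @export
full_fit <- function(records, kind, element_order = "auto",
                     min_element_support = 1L) {
  kind <- match.arg(toupper(kind), c("PMVC", "ECC", "PMVECC"))
  stopifnot(inherits(records, "molecule_table"))
  if (anyNA(records$dg_exp) || anyNA(records$dg_method)) {
    stop("full_fit requires dg_exp and dg_method for every molecule")
  }
  element_order <- resolve_element_order(kind, records, element_order)
  check_element_support(records, element_order, min_element_support)
  X <- design_matrix(kind, records, element_order)
  beta <- ols_fit(X, records$dg_exp - records$dg_method)
  model_from_coefficients(kind, beta, element_order)
}

#' @export
print.hfe_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("%s correction fitted by leave-one-out OLS on %d molecules\n",
              x$kind, x$n))
  cat("Mean coefficients over folds (SD over folds in brackets):\n")
  b <- model_coefficients(x$mean_model)
  for (nm in names(b)) {
    cat(sprintf("  %-3s %12s  [%s]\n", nm, format(b[[nm]], digits = digits),
                format(x$coeff_sd[[nm]], digits = 2L)))
  }
  invisible(x)
}

#' Summarize a leave-one-out correction fit
#'
#' Tabulates the aggregated coefficients with their dispersion measures and
#' computes benchmark error statistics ([error_stats()]) of the leave-out
#' predictions against experiment.
#'
#' @param object an `hfe_fit`.
#' @param ... unused.
#' @return an object of class `summary.hfe_fit`.
#' @export
summary.hfe_fit <- function(object, ...) {
  b <- model_coefficients(object$mean_model)
  tab <- data.frame(coefficient = names(b), mean = as.numeric(b),
                    sd_folds = as.numeric(object$coeff_sd),
                    sem = as.numeric(object$coeff_sem),
                    se_jackknife = as.numeric(object$coeff_se_jack),
                    stringsAsFactors = FALSE)
  stats <- error_stats(object$loo_predictions, object$dg_exp)
  structure(list(kind = object$kind, n = object$n, coefficients = tab,
                 loo_stats = stats), class = "summary.hfe_fit")
}

#' @export
print.summary.hfe_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("%s correction, leave-one-out OLS, n = %d molecules\n\n",
              x$kind, x$n))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("\nLeave-out prediction quality vs experiment (kcal/mol):\n")
  print(x$loo_stats)
  invisible(x)
}

#' @export
coef.hfe_fit <- function(object, ...) {
  model_coefficients(object$mean_model)
}

#' Predict corrected HFEs from a fitted correction
#'
#' Applies the aggregated (mean-over-folds) model to new molecules.
#'
#' @param object an `hfe_fit`.
#' @param newdata a [molecule_table()]; defaults to refitting molecules, for
#'   which the out-of-sample leave-out predictions are returned instead.
#' @param type `"corrected"` for `dg_method` + correction (default), or
#'   `"term"` for the bare correction term.
#' @param permissive passed to [apply_correction()].
#' @param ... unused.
#' @return named numeric vector, kcal/mol.
#' @export
predict.hfe_fit <- function(object, newdata = NULL,
                            type = c("corrected", "term"),
                            permissive = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "term") {
      return(object$loo_predictions - object$dg_method)
    }
    return(object$loo_predictions)
  }
  stopifnot(inherits(newdata, "molecule_table"))
  corrected <- apply_correction(object$mean_model, newdata,
                                permissive = permissive)
  if (type == "term") corrected - stats::setNames(newdata$dg_method,
                                                  newdata$id) else corrected
}

#' @export
residuals.hfe_fit <- function(object, ...) {
  object$loo_predictions - object$dg_exp
}

#' @export
fitted.hfe_fit <- function(object, ...) {
  object$loo_predictions
}

#' Scatter plot of leave-out predictions against experiment
#'
#' @param x an `hfe_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hfe_fit <- function(x, ...) {
  graphics::plot(x$dg_exp, x$loo_predictions,
                 xlab = expression(Delta * G[exp] ~ "(kcal/mol)"),
                 ylab = expression(Delta * G[pred] ~ "(kcal/mol)"),
                 main = sprintf("%s leave-out predictions", x$kind), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
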