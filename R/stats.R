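# Benchmark error statistics for predicted vs experimental HFEs: regression
# slope, mean unsigned / mean signed / root mean squared error, squared
# Pearson correlation, maximum absolute error, and a cutoff-filtered relative
# error; bootstrap resampling supplies the uncertainties.

#' Squared Pearson correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, both with positive
#'   variance).
#' @return the square of the sample Pearson correlation coefficient.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)^2
}

#' Benchmark error statistics
#'
#' Computes the standard quality-of-fit statistics for predicted vs
#' experimental HFEs. The slope is the OLS slope of `pred` regressed on `exp`
#' with an intercept (the convention of benchmark scatter plots); R2 is the
#' squared Pearson correlation.
#'
#' @param pred predicted (corrected) HFEs, kcal/mol.
#' @param exp experimental HFEs, kcal/mol; same length, length >= 2, with
#'   positive variance.
#' @return an object of class `error_stats`: a named list with `slope`,
#'   `mue`, `mse` (mean signed error), `rmse`, `r2`, `max_error`, `n`.
#' @export
error_stats <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("pred and exp must have equal length")
  if (length(pred) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(exp))) {
    stop("inputs must be finite")
  }
  if (stats::var(exp) == 0) {
    stop("zero variance in exp: slope and R2 undefined")
  }
  d <- pred - exp
  structure(list(
    slope = stats::cov(exp, pred) / stats::var(exp),
    mue = mean(abs(d)),
    mse = mean(d),
    rmse = sqrt(mean(d^2)),
    r2 = stats::cor(pred, exp)^2,
    max_error = max(abs(d)),
    n = length(pred)
  ), class = "error_stats")
}

#' @export
print.error_stats <- function(x, digits = 3L, ...) {
  cat(sprintf("  n = %d\n", x$n))
  line <- function(nm, v, unc = NULL) {
    cat(sprintf("  %-9s %8s%s\n", nm, format(v, digits = digits),
                if (is.null(unc)) "" else
                  sprintf(" +/- %s", format(unc, digits = 2L))))
  }
  u <- attr(x, "uncertainty")
  for (nm in c("slope", "mue", "mse", "rmse", "r2", "max_error")) {
    line(nm, x[[nm]], if (!is.null(u)) u[[nm]])
  }
  invisible(x)
}

#' Cutoff-filtered relative error
#'
#' Mean absolute relative error `|(pred - exp)/exp|` over the molecules whose
#' experimental HFE is below a cutoff; the cutoff (default -5 kcal/mol)
#' avoids dividing by small numbers.
#'
#' @inheritParams error_stats
#' @param cutoff kcal/mol; only pairs with `exp < cutoff` are used.
#' @return mean absolute relative error (dimensionless fraction).
#' @export
relative_error <- function(pred, exp, cutoff = -5) {
  if (length(pred) != length(exp)) stop("pred and exp must have equal length")
  keep <- exp < cutoff
  if (!any(keep)) {
    stop("no molecule with exp < ", cutoff, " kcal/mol; relative error undefined")
  }
  mean(abs((pred[keep] - exp[keep]) / exp[keep]))
}

#' Bootstrap uncertainties for the error statistics
#'
#' Resamples the (pred, exp) pairs with replacement `n_boot` times, computes
#' every statistic per resample, and reports the standard deviation of each
#' statistic's bootstrap distribution as its uncertainty. Point values come
#' from the unresampled data. Resamples with zero experimental variance are
#' redrawn (bounded retries).
#'
#' @inheritParams error_stats
#' @param n_boot number of bootstrap rounds (default 1000).
#' @param seed integer seed; the same seed reproduces the uncertainties
#'   bit-for-bit.
#' @return an `error_stats` object whose `"uncertainty"` attribute holds the
#'   per-statistic bootstrap SDs.
#' @export
bootstrap_stats <- function(pred, exp, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 2L)
  point <- error_stats(pred, exp)
  n <- length(pred)
  keys <- c("slope", "mue", "mse", "rmse", "r2", "max_error")
  boot <- matrix(NA_real_, n_boot, length(keys),
                 dimnames = list(NULL, keys))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::var(exp[idx]) > 0) break
        if (try == 100L) stop("could not draw a resample with exp variance > 0")
      }
      s <- error_stats(pred[idx], exp[idx])
      boot[b, ] <- unlist(s[keys])
    }
  })
  unc <- apply(boot, 2L, stats::sd)
  attr(point, "uncertainty") <- as.list(unc)
  attr(point, "boot_mean") <- as.list(colMeans(boot))
  attr(point, "n_boot") <- n_boot
  point
}

#' Evaluate predictions against experiment, optionally by group
#'
#' Convenience wrapper computing [bootstrap_stats()] (and [relative_error()])
#' for predicted vs experimental HFEs, pooled and per group (e.g. the
#' rigid/flexible flexibility labels). Records are sorted by id before
#' resampling so results do not depend on input order.
#'
#' @param records a [molecule_table()] with `dg_exp`.
#' @param predictions named vector of corrected HFEs (names = molecule ids).
#' @param group_by optional column of `records` to split on (e.g.
#'   `"flexibility"`).
#' @param n_boot,seed passed to [bootstrap_stats()].
#' @param rel_cutoff cutoff for [relative_error()]; groups with no molecule
#'   past the cutoff report `NA`.
#' @return named list of `error_stats` (entry `"total"` plus one per group),
#'   each with a `"relative_error"` attribute.
#' @export
evaluate_predictions <- function(records, predictions, group_by = NULL,
                                 n_boot = 1000L, seed = 1L, rel_cutoff = -5) {
  stopifnot(inherits(records, "molecule_table"))
  if (is.null(names(predictions))) stop("predictions must be named by id")
  missing <- setdiff(records$id, names(predictions))
  if (length(missing) > 0L) {
    stop("no prediction for molecule ", paste(missing, collapse = ", "))
  }
  if (anyNA(records$dg_exp)) {
    stop("missing dg_exp for molecule ",
         paste(records$id[is.na(records$dg_exp)], collapse = ", "))
  }
  records <- records[order(records$id), ]
  pred <- unname(predictions[records$id])
  groups <- list(total = rep(TRUE, nrow(records)))
  if (!is.null(group_by)) {
    g <- as.character(records[[group_by]])
    for (lv in sort(unique(g))) groups[[lv]] <- g == lv
  }
  out <- list()
  for (nm in names(groups)) {
    keep <- groups[[nm]]
    s <- bootstrap_stats(pred[keep], records$dg_exp[keep],
                         n_boot = n_boot, seed = seed)
    attr(s, "relative_error") <- tryCatch(
      relative_error(pred[keep], records$dg_exp[keep], cutoff = rel_cutoff),
      error = function(e) NA_real_)
    out[[nm]] <- s
  }
  out
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
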