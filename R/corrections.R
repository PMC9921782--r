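# Applying a correction model to molecule records, and building the design
# rows the fitter uses. The two paths share one coefficient layout
# ([a, b, elements...] in fit-time order), so correction_term() is exactly
# the dot product of design_row() with the coefficient vector.

#' Correction term for one molecule
#'
#' Evaluates the model's correction a*v + b + sum_i c_i*N_i (kcal/mol), with
#' the groups a model kind lacks contributing zero.
#'
#' By default an element present in the molecule but absent from the model's
#' coefficients is an error: a fitted correction is not transferable to
#' chemistry it has never seen. With `permissive = TRUE` such elements
#' contribute zero and a warning is emitted.
#'
#' @param model a [correction_model()].
#' @param record a single-row [molecule_table()] (or a named list with
#'   `pmv` and an integer `counts` vector).
#' @param permissive treat elements missing from the model as coefficient 0.
#' @return correction in kcal/mol.
#' @export
correction_term <- function(model, record, permissive = FALSE) {
  stopifnot(is.correction_model(model))
  if (inherits(record, "molecule_table")) {
    stopifnot(nrow(record) == 1L)
    cm <- element_counts(record)
    counts <- stats::setNames(as.integer(cm[1L, ]), colnames(cm))
    pmv <- record$pmv
    id <- record$id
  } else {
    counts <- record$counts
    pmv <- if (is.null(record$pmv)) NA_real_ else record$pmv
    id <- if (is.null(record$id)) "<record>" else record$id
  }
  # evaluate as the dot product of the design-row values with the
  # coefficient vector, in fit layout, so the application and fitting paths
  # agree bit-for-bit
  values <- numeric(0)
  if (model$kind %in% c("PMVC", "PMVECC")) {
    if (is.na(pmv)) {
      stop("molecule ", id, " has no PMV but model kind ", model$kind,
           " requires one")
    }
    values <- c(pmv, 1)
  }
  if (model$kind %in% c("ECC", "PMVECC")) {
    present <- names(counts)[counts > 0]
    unknown <- setdiff(present, model$element_order)
    if (length(unknown) > 0L) {
      if (!permissive) {
        stop("molecule ", id, " contains element(s) ",
             paste(unknown, collapse = ", "),
             " with no fitted coefficient; the correction is not",
             " transferable (use permissive = TRUE to treat them as 0)")
      }
      warning("treating unfitted element(s) ", paste(unknown, collapse = ", "),
              " as coefficient 0 for molecule ", id)
    }
    n_el <- stats::setNames(numeric(length(model$element_order)),
                            model$element_order)
    known <- intersect(names(counts), model$element_order)
    n_el[known] <- counts[known]
    values <- c(values, n_el)
  }
  sum(values * model_coefficients(model))
}

#' Apply a correction model to a molecule table
#'
#' Computes the corrected HFE `dg_method + correction_term` for every record.
#'
#' @inheritParams correction_term
#' @param records a [molecule_table()]; every row needs `dg_method`, plus
#'   `pmv` for PMV-kind models.
#' @return named numeric vector of corrected HFEs (kcal/mol), names = ids.
#' @export
apply_correction <- function(model, records, permissive = FALSE) {
  stopifnot(is.correction_model(model), inherits(records, "molecule_table"))
  if (anyNA(records$dg_method)) {
    stop("missing dg_method for molecule ",
         paste(records$id[is.na(records$dg_method)], collapse = ", "))
  }
  counts <- element_counts(records)
  terms <- vapply(seq_len(nrow(records)), function(i) {
    correction_term(model,
                    list(id = records$id[i], pmv = records$pmv[i],
                         counts = counts[i, ]),
                    permissive = permissive)
  }, numeric(1))
  stats::setNames(records$dg_method + terms, records$id)
}

#' Design row / design matrix for fitting
#'
#' Builds the regressor row(s) matching a model kind's coefficient layout:
#' `[v, 1]` for PMVC, per-element counts for ECC, `[v, 1, counts...]` for
#' PMVECC. Elements absent from a molecule contribute 0; an element present
#' in a molecule but missing from `element_order` is an error, since the
#' fitter must see the full element set.
#'
#' @param kind `"PMVC"`, `"ECC"` or `"PMVECC"`.
#' @param records a [molecule_table()].
#' @param element_order ordered element symbols fixing the count columns
#'   (ignored for PMVC).
#' @return numeric matrix, one row per record, with column names
#'   `c("a", "b", <elements>)` as the kind requires.
#' @export
design_matrix <- function(kind, records, element_order = NULL) {
  kind <- match.arg(toupper(kind), c("PMVC", "ECC", "PMVECC"))
  stopifnot(inherits(records, "molecule_table"))
  n <- nrow(records)
  blocks <- list()
  if (kind %in% c("PMVC", "PMVECC")) {
    if (anyNA(records$pmv)) {
      stop("missing pmv for molecule ",
           paste(records$id[is.na(records$pmv)], collapse = ", "),
           " but kind ", kind, " requires one")
    }
    blocks$pmv <- cbind(a = records$pmv, b = rep(1, n))
  }
  if (kind %in% c("ECC", "PMVECC")) {
    if (is.null(element_order)) stop(kind, " requires element_order")
    element_order <- normalize_element(element_order)
    counts <- element_counts(records)
    extra <- colnames(counts)[colSums(counts) > 0 &
                                !colnames(counts) %in% element_order]
    if (length(extra) > 0L) {
      stop("element(s) ", paste(extra, collapse = ", "),
           " present in records but not in element_order")
    }
    m <- matrix(0, n, length(element_order),
                dimnames = list(NULL, element_order))
    shared <- intersect(element_order, colnames(counts))
    m[, shared] <- counts[, shared]
    blocks$counts <- m
  }
  X <- do.call(cbind, unname(blocks))
  rownames(X) <- records$id
  X
}

#' @rdname design_matrix
#' @param record a single-row [molecule_table()].
#' @return `design_row()`: a named numeric vector (one design-matrix row).
#' @export
design_row <- function(kind, record, element_order = NULL) {
  stopifnot(inherits(record, "molecule_table"), nrow(record) == 1L)
  design_matrix(kind, record, element_order)[1L, ]
}
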