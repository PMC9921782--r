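# Correction models. Three kinds are supported, all linear in their
# parameters:
#   PMVC     dG + a*v + b            (pressure-like PMV correction)
#   ECC      dG + sum_i c_i * N_i    (per-element correction, no intercept)
#   PMVECC   dG + a*v + b + sum_i c_i * N_i
# with v the partial molar volume (A^3), N_i the count of atoms of element i,
# a in kcal/mol/A^3 and b, c_i in kcal/mol.

#' Construct a correction model
#'
#' @param kind one of `"PMVC"`, `"ECC"`, `"PMVECC"`.
#' @param a pressure-slope coefficient, kcal/mol/A^3 (PMVC/PMVECC; must be 0
#'   for ECC, which has no PMV term).
#' @param b intercept, kcal/mol (must be 0 for ECC, which has no intercept).
#' @param c named numeric vector of per-element coefficients, kcal/mol
#'   (ECC/PMVECC; must be empty for PMVC).
#' @param element_order fit-time column order of the element coefficients;
#'   defaults to the canonical (atomic number) order of `names(c)`.
#' @return an object of class `correction_model`.
#' @export
#' @examples
#' correction_model("PMVC", a = -0.15, b = -0.04)
#' correction_model("ECC", c = c(Cl = -4.695, H = -1.199))
correction_model <- function(kind, a = 0, b = 0, c = numeric(0),
                             element_order = NULL) {
  kind <- match.arg(toupper(kind), c("PMVC", "ECC", "PMVECC"))
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (length(c) > 0L) {
    if (is.null(names(c)) || any(!nzchar(names(c)))) {
      stop("element coefficients c must be named by element symbol")
    }
    names(c) <- normalize_element(names(c))
    if (anyDuplicated(names(c))) {
      stop("duplicate element in c: ",
           paste(unique(names(c)[duplicated(names(c))]), collapse = ", "))
    }
  }
  if (is.null(element_order)) {
    element_order <- element_order_canonical(names(c))
  } else {
    element_order <- normalize_element(element_order)
  }
  if (anyDuplicated(element_order)) stop("duplicate element in element_order")
  if (!setequal(element_order, names(c))) {
    stop("element_order must contain exactly the elements of c")
  }
  c <- as.numeric(c[element_order]); names(c) <- element_order
  if (kind == "PMVC" && length(c) > 0L) {
    stop("PMVC has no element coefficients")
  }
  if (kind == "ECC" && (a != 0 || b != 0)) {
    stop("ECC has no PMV term and no intercept: a and b must be 0")
  }
  if (kind %in% c("ECC", "PMVECC") && length(c) == 0L) {
    stop(kind, " requires element coefficients c")
  }
  if (any(!is.finite(c)) || !is.finite(a) || !is.finite(b)) {
    stop("model coefficients must be finite")
  }
  structure(list(kind = kind, a = a, b = b, c = c,
                 element_order = element_order),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, digits = 4L, ...) {
  cat(sprintf("%s correction model\n", x$kind))
  if (x$kind != "ECC") {
    cat(sprintf("  a = %s kcal/mol/A^3, b = %s kcal/mol\n",
                format(x$a, digits = digits), format(x$b, digits = digits)))
  }
  if (length(x$c) > 0L) {
    cat("  element coefficients (kcal/mol):\n")
    print(round(x$c, digits))
  }
  invisible(x)
}

#' @rdname correction_model
#' @param x object to test.
#' @export
is.correction_model <- function(x) inherits(x, "correction_model")

# Flat coefficient vector in fit layout: [a, b, elements...] for PMVECC,
# [a, b] for PMVC, elements only for ECC.
model_coefficients <- function(model) {
  switch(model$kind,
         PMVC = c(a = model$a, b = model$b),
         ECC = model$c,
         PMVECC = c(c(a = model$a, b = model$b), model$c))
}

model_from_coefficients <- function(kind, beta, element_order) {
  switch(kind,
         PMVC = correction_model("PMVC", a = beta[[1]], b = beta[[2]]),
         ECC = correction_model("ECC",
                                c = stats::setNames(beta, element_order),
                                element_order = element_order),
         PMVECC = correction_model("PMVECC", a = beta[[1]], b = beta[[2]],
                                   c = stats::setNames(beta[-(1:2)],
                                                       element_order),
                                   element_order = element_order))
}

#' Write a correction model to a JSON file
#'
#' The serialized form is a human-readable key-value document recording the
#' model kind, units, coefficients in fit-time element order, and provenance
#' metadata. Numbers are written with 17 significant digits so that
#' `read_model(write_model(m))` reproduces every coefficient bit-exactly.
#'
#' @param model a [correction_model()].
#' @param path output file path.
#' @param provenance optional named list merged into the `provenance` block
#'   (e.g. number of molecules fitted).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, provenance = list()) {
  if (!is.correction_model(model)) {
    # re-validate so hand-built lists cannot bypass the invariants
    model <- do.call(correction_model, model)
  }
  model <- correction_model(model$kind, model$a, model$b, model$c,
                            model$element_order)
  doc <- list(
    format = "hfecorr-correction-model",
    format_version = 1L,
    kind = model$kind,
    units = list(a = "kcal/mol/A^3", b = "kcal/mol", c = "kcal/mol"),
    a = model$a,
    b = model$b,
    element_order = model$element_order,
    c = as.list(model$c),
    provenance = utils::modifyList(
      list(package = "hfecorr",
           version = as.character(utils::packageVersion("hfecorr")),
           written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      provenance)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a correction model from a JSON file
#'
#' @param path path to a file written by [write_model()].
#' @return a [correction_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hfecorr-correction-model")) {
    stop("not a correction model file: ", path)
  }
  if (!doc$kind %in% c("PMVC", "ECC", "PMVECC")) {
    stop("unknown model kind: ", doc$kind)
  }
  c <- unlist(doc$c)
  if (is.null(c)) c <- numeric(0)
  order <- as.character(unlist(doc$element_order))
  if (length(c) > 0L || length(order) > 0L) {
    if (anyDuplicated(order)) {
      stop("duplicate element in element_order: ",
           paste(unique(order[duplicated(order)]), collapse = ", "))
    }
    if (!setequal(names(c), order)) {
      stop("element coefficients inconsistent with element_order in ", path)
    }
  }
  correction_model(doc$kind, a = doc$a, b = doc$b, c = c,
                   element_order = if (length(order)) order else NULL)
}
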