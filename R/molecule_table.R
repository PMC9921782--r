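# Molecule records: one row per solute, carrying per-element atom counts, the
# partial molar volume (PMV, A^3), the computed hydration free energy (HFE,
# kcal/mol) to be corrected, and the experimental HFE with its uncertainty.

#' Construct a molecule table
#'
#' Builds the tabular container used throughout the package: a data frame of
#' class `molecule_table` with one row per solute and one integer column per
#' chemical element, plus energy/volume columns in fixed units (kcal/mol,
#' A^3).
#'
#' @param id character vector of unique molecule ids.
#' @param counts integer matrix (rows = molecules) with element symbols as
#'   column names, or a named-vector list of per-molecule counts.
#' @param pmv partial molar volume, A^3 (`NA` when absent).
#' @param dg_method computed HFE to be corrected, kcal/mol.
#' @param dg_exp experimental HFE, kcal/mol (`NA` when absent).
#' @param dg_exp_unc experimental uncertainty, kcal/mol.
#' @param name optional molecule names.
#' @param flexibility one of `"rigid"`, `"flexible"`, `"unknown"` per row.
#' @return a `molecule_table` data frame; the element columns are recorded in
#'   `attr(, "elements")` in canonical (atomic number) order.
#' @export
molecule_table <- function(id, counts, pmv = NA_real_, dg_method = NA_real_,
                           dg_exp = NA_real_, dg_exp_unc = NA_real_,
                           name = NA_character_,
                           flexibility = "unknown") {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) {
    stop("duplicate molecule ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.list(counts) && !is.data.frame(counts)) {
    elements <- element_order_canonical(unique(unlist(lapply(counts, names))))
    m <- matrix(0L, n, length(elements), dimnames = list(NULL, elements))
    for (i in seq_len(n)) {
      ci <- counts[[i]]
      if (length(ci)) m[i, normalize_element(names(ci))] <- as.integer(ci)
    }
    counts <- m
  } else {
    counts <- as.matrix(counts)
    colnames(counts) <- normalize_element(colnames(counts))
    counts <- counts[, element_order_canonical(colnames(counts)), drop = FALSE]
  }
  if (nrow(counts) != n) stop("counts must have one row per molecule")
  validate_counts(counts, id)
  flexibility <- rep_len(as.character(flexibility), n)
  bad_flex <- !flexibility %in% c("rigid", "flexible", "unknown")
  if (any(bad_flex)) {
    stop("flexibility must be rigid/flexible/unknown; got: ",
         paste(unique(flexibility[bad_flex]), collapse = ", "))
  }
  df <- data.frame(id = id, name = rep_len(as.character(name), n),
                   pmv = check_finite(rep_len(as.numeric(pmv), n), "pmv", id),
                   dg_method = check_finite(rep_len(as.numeric(dg_method), n),
                                            "dg_method", id),
                   dg_exp = check_finite(rep_len(as.numeric(dg_exp), n),
                                         "dg_exp", id),
                   dg_exp_unc = rep_len(as.numeric(dg_exp_unc), n),
                   flexibility = flexibility,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts))
  attr(df, "elements") <- colnames(counts)
  class(df) <- c("molecule_table", "data.frame")
  df
}

validate_counts <- function(counts, id) {
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    i <- which(apply(counts, 1L, function(r) {
      any(!is.finite(r)) || any(r < 0) || any(r != round(r))
    }))
    stop("element counts must be non-negative integers (molecule ",
         paste(id[i], collapse = ", "), ")")
  }
  invisible(counts)
}

check_finite <- function(x, what, id) {
  bad <- !is.na(x) & !is.finite(x)
  if (any(bad)) {
    stop(what, " must be finite (molecule ", paste(id[bad], collapse = ", "), ")")
  }
  x
}

#' Extract the per-element count matrix
#'
#' @param records a `molecule_table`.
#' @return integer matrix, one row per molecule, element symbols as columns.
#' @export
element_counts <- function(records) {
  stopifnot(inherits(records, "molecule_table"))
  m <- as.matrix(records[, attr(records, "elements"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- records$id
  m
}

#' Read a molecule table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a [molecule_table()]. Element
#' counts are taken either from a molecular-formula column or from per-element
#' count columns; energies are kcal/mol, volumes A^3, decimal points only.
#'
#' @param source path to a delimited text file.
#' @param columns named list mapping the roles `id`, `name`, `formula`, `pmv`,
#'   `dg_method`, `dg_exp`, `dg_exp_unc`, `flexibility` to column names in the
#'   file. Roles absent from the file may be omitted; per-element count
#'   columns are any remaining columns whose names are element symbols.
#' @param sep field separator; `NULL` (default) chooses `","` or tab from the
#'   header line.
#' @return a [molecule_table()].
#' @export
read_molecule_table <- function(source,
                                columns = list(id = "id", name = "name",
                                               formula = "formula", pmv = "pmv",
                                               dg_method = "dg_method",
                                               dg_exp = "dg_exp",
                                               dg_exp_unc = "dg_exp_unc",
                                               flexibility = "flexibility"),
                                sep = NULL) {
  if (!file.exists(source)) stop("no such file: ", source)
  header <- readLines(source, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(source, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  defaults <- eval(formals(read_molecule_table)$columns)
  columns <- utils::modifyList(defaults, columns)
  get_col <- function(role, required = FALSE) {
    nm <- columns[[role]]
    if (!is.null(nm) && nm %in% names(df)) return(df[[nm]])
    if (required) stop("missing required column '", nm, "' (role: ", role, ")")
    NULL
  }
  id <- get_col("id", required = TRUE)
  num_col <- function(role) {
    x <- get_col(role)
    if (is.null(x)) return(NA_real_)
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
    if (any(bad)) {
      stop("non-numeric value in column '", columns[[role]], "' for molecule ",
           paste(id[bad], collapse = ", "))
    }
    out
  }
  role_cols <- unlist(columns[c("id", "name", "formula", "pmv", "dg_method",
                                "dg_exp", "dg_exp_unc", "flexibility")])
  rest <- setdiff(names(df), role_cols)
  elem_cols <- rest[grepl("^[A-Z][a-z]?$", rest) &
                      rest %in% .element_table$symbol]
  formula <- get_col("formula")
  if (!is.null(formula)) {
    counts <- lapply(as.character(formula), parse_formula)
  } else if (length(elem_cols) > 0L) {
    counts <- as.matrix(df[, elem_cols, drop = FALSE])
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts))) {
      bad <- which(apply(counts, 1L, function(r) {
        any(!is.finite(r)) || any(r < 0) || any(r != round(r))
      }))
      stop("invalid element count (must be non-negative integer) for molecule ",
           paste(id[bad], collapse = ", "))
    }
    storage.mode(counts) <- "integer"
  } else {
    stop("missing required column '", columns$formula,
         "' (role: formula) and no per-element count columns found")
  }
  flex <- get_col("flexibility")
  nm <- get_col("name")
  molecule_table(id = id, counts = counts,
                 pmv = num_col("pmv"),
                 dg_method = num_col("dg_method"),
                 dg_exp = num_col("dg_exp"),
                 dg_exp_unc = num_col("dg_exp_unc"),
                 name = if (is.null(nm)) NA_character_ else as.character(nm),
                 flexibility = if (is.null(flex)) "unknown" else flex)
}

#' Write a molecule table to CSV
#'
#' @param records a `molecule_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  stopifnot(inherits(records, "molecule_table"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
`[.molecule_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) && all(attr(x, "elements") %in% names(out))) {
    attr(out, "elements") <- attr(x, "elements")
    class(out) <- c("molecule_table", "data.frame")
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "elements") <- NULL
  }
  out
}

#' @export
print.molecule_table <- function(x, ...) {
  cat(sprintf("molecule_table: %d molecules, elements {%s}\n", nrow(x),
              paste(attr(x, "elements"), collapse = ", ")))
  cat(sprintf("  with pmv: %d; with dg_method: %d; with dg_exp: %d\n",
              sum(!is.na(x$pmv)), sum(!is.na(x$dg_method)),
              sum(!is.na(x$dg_exp))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
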