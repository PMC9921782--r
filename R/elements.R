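# Periodic-table data used for symbol normalization, canonical ordering and
# mass -> element inference from AMBER topologies.

# Symbols, atomic numbers and standard atomic weights (u) for the elements a
# small-molecule hydration set can plausibly contain.
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
             "Ga", "Ge", "As", "Se", "Br", "Kr", "I", "Xe"),
  z = c(1:36, 53, 54),
  weight = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
             18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
             35.45, 39.948, 39.098, 40.078, 44.956, 47.867, 50.942, 51.996,
             54.938, 55.845, 58.933, 58.693, 63.546, 65.38, 69.723, 72.630,
             74.922, 78.971, 79.904, 83.798, 126.90, 131.29),
  stringsAsFactors = FALSE
)

# The ten elements the correction models are fitted for by default: the
# chemistry spanned by the FreeSolv-scale benchmark sets. Other elements are
# counted but flagged, because a fitted model carries no coefficient for them.
.known_elements <- c("H", "C", "N", "O", "F", "Cl", "Br", "I", "P", "S")

#' Normalize an element symbol
#'
#' Case-normalizes element symbols (first letter upper, remainder lower), so
#' legacy all-caps files ("CL", "BR") map onto standard symbols.
#'
#' @param symbol character vector of element symbols.
#' @param strict if `TRUE` (default), unknown symbols are an error; otherwise
#'   they are returned normalized.
#' @return character vector of normalized symbols.
#' @export
normalize_element <- function(symbol, strict = TRUE) {
  s <- as.character(symbol)
  bad <- !grepl("^[A-Za-z]{1,2}$", s)
  if (any(bad)) {
    stop("not an element symbol: ", paste(unique(s[bad]), collapse = ", "))
  }
  out <- paste0(toupper(substr(s, 1L, 1L)), tolower(substr(s, 2L, 10L)))
  if (strict) {
    unknown <- setdiff(unique(out), .element_table$symbol)
    if (length(unknown) > 0L) {
      stop("unknown element symbol: ", paste(unknown, collapse = ", "))
    }
  }
  out
}

#' Order element symbols canonically
#'
#' Sorts element symbols by atomic number, giving a reproducible column order
#' for design matrices and serialized models.
#'
#' @param symbols character vector of element symbols.
#' @return the symbols sorted by atomic number.
#' @export
element_order_canonical <- function(symbols) {
  symbols <- normalize_element(unique(symbols))
  z <- .element_table$z[match(symbols, .element_table$symbol)]
  symbols[order(z)]
}

element_from_z <- function(z) {
  i <- match(z, .element_table$z)
  if (anyNA(i)) {
    stop("no element with atomic number ", paste(z[is.na(i)], collapse = ", "))
  }
  .element_table$symbol[i]
}

# Nearest standard atomic weight, rejecting matches further than `window` u.
element_from_mass <- function(mass, window = 0.5) {
  vapply(mass, function(m) {
    d <- abs(.element_table$weight - m)
    i <- which.min(d)
    if (d[i] > window) {
      stop(sprintf("no element within %.2f u of mass %.4f", window, m))
    }
    .element_table$symbol[i]
  }, character(1))
}

#' Parse a molecular formula into element counts
#'
#' Parses Hill-notation formulas ("C6H6", "CH3Cl", "H2O") with multi-letter
#' symbols and implicit count 1.
#'
#' @param formula a single formula string.
#' @return named integer vector of per-element counts.
#' @export
#' @examples
#' parse_formula("C6H5Cl") # C 6, H 5, Cl 1
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula)) {
    stop("formula must be a single non-empty string")
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(tokens))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  syms <- normalize_element(sub("[0-9]+$", "", parts))
  n <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(nzchar(n), suppressWarnings(as.integer(n)), 1L)
  if (anyNA(counts)) stop("cannot parse formula counts: ", formula)
  tapply_counts <- tapply(counts, syms, sum)
  out <- as.integer(tapply_counts)
  names(out) <- names(tapply_counts)
  out[element_order_canonical(names(out))]
}
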