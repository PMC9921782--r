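# Per-element atom counts from structure/topology files. Only atom identity
# is read - no bonds, aromaticity or coordinates - because the element count
# correction needs nothing else. Hydrogens are counted only when explicit in
# the file; nothing here infers them from valence.
#
# Format handling is delegated to ChemmineR (SDF V2000) and bio3d (PDB,
# MOL2, AMBER topology); this module implements the element-resolution rules
# on top: PDB element columns take precedence over atom-name fallback, MOL2
# elements come from the SYBYL type prefix, and AMBER topologies use the
# atomic-number section when present, else the nearest standard atomic
# weight within +/- 0.5 u.

#' Count atoms of each element in a structure file
#'
#' @param source path to a structure/topology file containing exactly one
#'   molecule (use [count_elements_batch()] for multi-record SDF files or
#'   directories).
#' @param format `"SDF"`, `"PDB"`, `"MOL2"` or `"AMBER_TOPOLOGY"`; `NULL`
#'   (default) detects from the file extension (`.sdf`/`.mol`, `.pdb`,
#'   `.mol2`, `.prmtop`/`.parm7`/`.top`).
#' @param known_only if `TRUE` (default), elements outside the ten the
#'   correction models are normally fitted for (H, C, N, O, F, Cl, Br, I, P,
#'   S) are still counted but flagged with a warning, since a downstream
#'   model cannot correct them.
#' @return named integer vector of counts, canonical element order; total
#'   equals the number of atom records in the file.
#' @export
count_elements <- function(source, format = NULL, known_only = TRUE) {
  if (!file.exists(source)) stop("no such file: ", source)
  format <- detect_format(source, format)
  symbols <- switch(format,
                    SDF = sdf_elements(source, single = TRUE)[[1]],
                    PDB = pdb_elements(source),
                    MOL2 = mol2_elements(source),
                    AMBER_TOPOLOGY = prmtop_elements(source))
  if (length(symbols) == 0L) stop("no atoms found in ", source)
  tally_elements(symbols, known_only = known_only)
}

tally_elements <- function(symbols, known_only = TRUE) {
  symbols <- normalize_element(symbols)
  if (known_only) {
    odd <- setdiff(unique(symbols), .known_elements)
    if (length(odd) > 0L) {
      warning("element(s) outside the default correction set: ",
              paste(odd, collapse = ", "))
    }
  }
  tab <- table(symbols)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[element_order_canonical(names(out))]
}

detect_format <- function(source, format) {
  if (!is.null(format)) {
    return(match.arg(toupper(format), c("SDF", "PDB", "MOL2", "AMBER_TOPOLOGY")))
  }
  ext <- tolower(sub(".*\\.", "", source))
  switch(ext,
         sdf = , mol = "SDF",
         pdb = "PDB",
         mol2 = "MOL2",
         prmtop = , parm7 = , top = "AMBER_TOPOLOGY",
         stop("cannot detect format from extension '.", ext,
              "'; pass format= explicitly"))
}

need_ns <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required to read this format")
  }
}

# --- SDF ------------------------------------------------------------------

# returns a named list (id -> element symbol vector), one entry per record
sdf_elements <- function(source, single = FALSE) {
  need_ns("ChemmineR")
  set <- suppressWarnings(ChemmineR::read.SDFset(source))
  if (length(set) == 0L) stop("no molecules in SDF file ", source)
  if (single && length(set) > 1L) {
    stop(source, " contains ", length(set),
         " records; use count_elements_batch()")
  }
  ids <- as.character(ChemmineR::sdfid(set))
  out <- lapply(seq_along(set), function(i) {
    ab <- ChemmineR::atomblock(set[[i]])
    sub("_[0-9]+$", "", rownames(ab))
  })
  names(out) <- ids
  out
}

# --- PDB ------------------------------------------------------------------

pdb_elements <- function(source) {
  need_ns("bio3d")
  pdb <- bio3d::read.pdb(source)
  atoms <- pdb$atom
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records in ", source)
  elesy <- trimws(as.character(atoms$elesy))
  name <- trimws(as.character(atoms$elety))
  vapply(seq_len(nrow(atoms)), function(i) {
    if (nzchar(elesy[i]) && !is.na(elesy[i])) {
      # element columns 77-78 take precedence
      normalize_element(elesy[i])
    } else {
      pdb_element_from_name(name[i], atoms$type[i])
    }
  }, character(1))
}

# Atom-name fallback. Leading alphabetic characters are the candidate; a
# two-letter symbol is accepted directly only for the halogen naming style
# (Cl/Br/I plus digits). Names like "CA" are ambiguous (calcium vs
# alpha-carbon): small organic solutes carry no metals, so these resolve to
# the one-letter element with a warning.
pdb_element_from_name <- function(name, rectype = "HETATM") {
  letters2 <- sub("[^A-Za-z].*$", "", name)
  if (!nzchar(letters2)) stop("cannot resolve element from atom name '",
                              name, "'")
  one <- toupper(substr(letters2, 1L, 1L))
  if (nchar(letters2) == 1L) return(normalize_element(one))
  two <- normalize_element(substr(letters2, 1L, 2L), strict = FALSE)
  two_valid <- two %in% .element_table$symbol
  halogen_style <- two %in% c("Cl", "Br") &&
    grepl("^[A-Za-z]{2}[0-9]*$", name)
  if (two_valid && halogen_style) return(two)
  if (one %in% .element_table$symbol) {
    if (two_valid) {
      warning("ambiguous atom name '", name, "' (", two, " vs ", one,
              "); resolving to ", one, " for small-molecule ", rectype)
    }
    return(normalize_element(one))
  }
  if (two_valid) return(two)
  stop("cannot resolve element from atom name '", name, "'")
}

# --- MOL2 -----------------------------------------------------------------

mol2_elements <- function(source) {
  need_ns("bio3d")
  mol <- bio3d::read.mol2(source)
  atoms <- mol$atom
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop("no @<TRIPOS>ATOM records in ", source)
  }
  # element = SYBYL atom-type prefix before the first dot ("C.3" -> C)
  normalize_element(sub("\\..*$", "", trimws(as.character(atoms$elety))))
}

# --- AMBER topology -------------------------------------------------------

prmtop_elements <- function(source) {
  need_ns("bio3d")
  top <- bio3d::read.prmtop(source)
  if (!is.null(top$ATOMIC_NUMBER)) {
    z <- as.integer(top$ATOMIC_NUMBER)
    if (length(z) == 0L) stop("empty ATOMIC_NUMBER section in ", source)
    element_from_z(z)
  } else if (!is.null(top$MASS)) {
    mass <- as.numeric(top$MASS)
    if (length(mass) == 0L) stop("empty MASS section in ", source)
    element_from_mass(mass, window = 0.5)
  } else {
    stop(source, " has neither ATOMIC_NUMBER nor MASS sections")
  }
}

# --- batch ----------------------------------------------------------------

#' Count elements for many molecules
#'
#' Accepts a multi-record SDF file, a directory of structure files, or a
#' vector of file paths. Ids are SDF title lines or file-name stems; input
#' order is preserved.
#'
#' @param source multi-record SDF path, directory path, or character vector
#'   of file paths.
#' @param format passed to [count_elements()] (per-file detection when
#'   `NULL`).
#' @param permissive if `FALSE` (default) any single-molecule failure aborts
#'   the whole batch, reporting every failing id; if `TRUE` failures are
#'   dropped with a warning.
#' @param known_only passed to [count_elements()].
#' @return named list of count vectors, one entry per molecule.
#' @export
count_elements_batch <- function(source, format = NULL, permissive = FALSE,
                                 known_only = TRUE) {
  if (length(source) == 1L && dir.exists(source)) {
    files <- list.files(source, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) {
      warning("no files in directory ", source)
      return(stats::setNames(list(), character(0)))
    }
    return(count_elements_batch(files, format = format,
                                permissive = permissive,
                                known_only = known_only))
  }
  if (length(source) == 1L &&
      identical(detect_format(source, format), "SDF")) {
    per_record <- sdf_elements(source, single = FALSE)
    check_duplicate_ids(names(per_record))
    return(lapply(per_record, tally_elements, known_only = known_only))
  }
  ids <- sub("\\.[^.]*$", "", basename(source))
  check_duplicate_ids(ids)
  results <- stats::setNames(vector("list", length(source)), ids)
  failures <- character(0)
  for (i in seq_along(source)) {
    res <- tryCatch(count_elements(source[i], format = format,
                                   known_only = known_only),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", ids[i], conditionMessage(res)))
    } else {
      results[[i]] <- res
    }
  }
  if (length(failures) > 0L) {
    msg <- paste(failures, collapse = "; ")
    if (!permissive) stop("batch failed for: ", msg)
    warning("dropped failing molecule(s): ", msg)
    results <- results[!vapply(results, is.null, logical(1))]
  }
  results
}

check_duplicate_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate molecule id(s): ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}
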