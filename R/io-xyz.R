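#' @include AllClasses.R
NULL

#' Read a molecule from an XYZ file
#'
#' Standard two-header-line XYZ: atom count, comment, then one
#' `element x y z` line per atom, coordinates in Angstrom.
#'
#' @param path path to the file.
#' @param charge,multiplicity charge state to attach (the XYZ format itself
#'   carries neither).
#' @return a [Molecule-class].
#' @export
readXYZ <- function(path, charge = 0L, multiplicity = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= 2L]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2L)
    stop(sprintf("malformed XYZ: expected %d atom lines, found %d",
                 n, length(lines) - 2L))
  fields <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  el <- vapply(fields, `[`, character(1L), 1L)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3L)))
  Molecule(el, xyz, charge = charge, multiplicity = multiplicity)
}

#' Write a molecule to an XYZ file
#'
#' @param molecule a [Molecule-class].
#' @param path output path.
#' @param comment second header line.
#' @return the path, invisibly.
#' @export
writeXYZ <- function(molecule, path, comment = "") {
  n <- nAtoms(molecule)
  body <- sprintf("%-2s %16.8f %16.8f %16.8f", elements(molecule),
                  coords(molecule)[, 1L], coords(molecule)[, 2L],
                  coords(molecule)[, 3L])
  writeLines(c(as.character(n), comment, body), path)
  invisible(path)
}

#' Read or write polarization / atomic charges as CSV
#'
#' Plain `x, y, z, q` tables (Angstrom, e) used to inspect and replay
#' polarization charges across runs.
#'
#' @param path file path.
#' @return `readChargesCSV`: a list with `positions` (m x 3 matrix) and
#'   `charges` (numeric).
#' @export
readChargesCSV <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z", "q") %in% names(df)))
  list(positions = as.matrix(df[, c("x", "y", "z")]), charges = df$q)
}

#' @param positions m x 3 matrix (Angstrom).
#' @param charges numeric vector (e).
#' @rdname readChargesCSV
#' @export
writeChargesCSV <- function(positions, charges, path) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  utils::write.csv(data.frame(x = positions[, 1L], y = positions[, 2L],
                              z = positions[, 3L], q = charges),
                   path, row.names = FALSE)
  invisible(path)
}
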