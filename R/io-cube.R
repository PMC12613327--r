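#' @include AllClasses.R
NULL

#' Read a Gaussian cube file into a DensityGrid
#'
#' Cube conventions: two comment lines; natoms + origin; three axis lines
#' (count + step vector); atom lines; then values with z fastest. Lengths are
#' Bohr on disk and converted to Angstrom in memory. Only orthogonal axes are
#' supported.
#'
#' @param path path to the cube file.
#' @return a list with `grid` (a [DensityGrid-class], values rescaled from
#'   Bohr^-3 to Angstrom^-3 for density-like cubes when `rescale = TRUE`) and
#'   `atoms` (data.frame: Z, x, y, z in Angstrom).
#' @param rescale logical; if `TRUE` (default) values are interpreted as
#'   densities per Bohr^3 and rescaled to per Angstrom^3. Use `FALSE` for
#'   orbital amplitudes.
#' @export
readCube <- function(path, rescale = TRUE) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
  hdr <- num(lines[3L])
  natoms <- as.integer(hdr[1L])
  origin <- hdr[2:4] * BOHR_ANG
  ax <- lapply(4:6, function(i) num(lines[i]))
  counts <- vapply(ax, function(a) as.integer(a[1L]), integer(1L))
  vecs <- t(vapply(ax, function(a) a[2:4], numeric(3L))) * BOHR_ANG
  if (any(abs(vecs[upper.tri(vecs) | lower.tri(vecs)]) > 1e-10))
    stop("only orthogonal cube axes are supported")
  step <- diag(vecs)
  atoms <- t(vapply(lines[7:(6 + natoms)], num, numeric(5L)))
  rownames(atoms) <- NULL
  vals <- as.numeric(unlist(strsplit(trimws(lines[-seq_len(6L + natoms)]),
                                     "\\s+")))
  vals <- vals[is.finite(vals) | !is.na(vals)]
  if (length(vals) != prod(counts))
    stop(sprintf("cube value count %d does not match grid %d",
                 length(vals), prod(counts)))
  if (rescale) vals <- vals / BOHR_ANG^3
  list(grid = DensityGrid(origin, step, counts, vals),
       atoms = data.frame(Z = as.integer(atoms[, 1L]),
                          x = atoms[, 3L] * BOHR_ANG,
                          y = atoms[, 4L] * BOHR_ANG,
                          z = atoms[, 5L] * BOHR_ANG))
}

#' Write a DensityGrid to a Gaussian cube file
#'
#' @param grid a [DensityGrid-class] (Angstrom in memory; written in Bohr).
#' @param path output path.
#' @param atoms optional data.frame with columns Z, x, y, z (Angstrom).
#' @param rescale logical; rescale values from Angstrom^-3 to Bohr^-3
#'   (default `TRUE`, matching [readCube()]).
#' @param comment first comment line.
#' @return the path, invisibly.
#' @export
writeCube <- function(grid, path, atoms = NULL, rescale = TRUE,
                      comment = "cube written by tuneRSH") {
  if (is.null(atoms))
    atoms <- data.frame(Z = integer(), x = numeric(), y = numeric(),
                        z = numeric())
  o <- grid@origin / BOHR_ANG
  s <- grid@step / BOHR_ANG
  vals <- grid@values
  if (rescale) vals <- vals * BOHR_ANG^3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "orthogonal grid"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(atoms),
                     o[1L], o[2L], o[3L]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid@counts[1L], s[1L], 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid@counts[2L], 0, s[2L], 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid@counts[3L], 0, 0, s[3L]), con)
  if (nrow(atoms) > 0L)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$Z,
                       as.numeric(atoms$Z), atoms$x / BOHR_ANG,
                       atoms$y / BOHR_ANG, atoms$z / BOHR_ANG), con)
  # 6 values per line, z fastest (native cube order; values are stored that way)
  idx <- seq(1L, length(vals), by = 6L)
  chunk <- vapply(idx, function(i) {
    paste(sprintf("%13.5e", vals[i:min(i + 5L, length(vals))]), collapse = " ")
  }, character(1L))
  writeLines(chunk, con)
  invisible(path)
}
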