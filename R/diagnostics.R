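#' Extract the membrane mid-surface as contour polylines
#'
#' The phi = 0 level set identifies the elastic surface. Contours are
#' extracted in the r-z half-plane by marching squares with linear edge
#' interpolation (grDevices::contourLines); each polyline is either
#' closed or terminates near the symmetry axis / domain boundary.
#'
#' @param phi phase field.
#' @param g grid.
#' @param level contour level (default 0).
#' @return list of data frames with columns `r` and `z`; empty list if
#'   the field does not attain both signs around `level`.
#' @export
extract_contour <- function(phi, g, level = 0) {
  .check_field(phi, g)
  if (min(phi) >= level || max(phi) <= level) return(list())
  cl <- grDevices::contourLines(x = g$r_centers, y = g$z_centers,
                                z = phi, levels = level)
  lapply(cl, function(li) data.frame(r = li$x, z = li$y))
}

# Number of connected components of the region f > level (4-neighbour
# flood fill).  Independent topology oracle for the contour extraction.
count_regions <- function(f, level = 0) {
  lab <- matrix(0L, nrow(f), ncol(f))
  mask <- f > level
  ncomp <- 0L
  for (j in seq_len(ncol(f))) for (i in seq_len(nrow(f))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      ncomp <- ncomp + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        ij <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- ij[1]; b <- ij[2]
        if (a < 1 || b < 1 || a > nrow(f) || b > ncol(f)) next
        if (!mask[a, b] || lab[a, b] != 0L) next
        lab[a, b] <- ncomp
        stack <- c(stack, list(c(a - 1, b), c(a + 1, b),
                               c(a, b - 1), c(a, b + 1)))
      }
    }
  }
  ncomp
}

#' Geometric shape diagnostics of a configuration
#'
#' Computes the area and volume functionals plus the derived descriptors:
#' characteristic length `D_ve = sqrt(A / pi)`, reduced volume
#' `v = V / (pi D_ve^3 / 6)` (1 for a sphere, 1/sqrt(2) for two equal
#' spheres) and the width-to-size ratio `lambda = eps / D_ve` controlling
#' the sharp-interface limit.
#'
#' @param phi phase field.
#' @param p,g model parameters and grid.
#' @return list with `A`, `V`, `D_ve`, `v`, `lambda`.
#' @export
shape_metrics <- function(phi, p, g) {
  A <- area_functional(phi, p, g)
  if (A <= 0) stop("zero membrane area")
  V <- volume_functional(phi, g)
  D_ve <- sqrt(A / pi)
  list(A = A, V = V, D_ve = D_ve,
       v = V / (pi * D_ve^3 / 6),
       lambda = p$eps / D_ve)
}

#' Write fields to a snapshot container
#'
#' Named-array container with a one-line JSON metadata header (grid spec,
#' parameters, arc-length position) followed by the arrays as IEEE
#' doubles. Round-trips bit-identically.
#'
#' @param path output file.
#' @param fields named list of numeric matrices.
#' @param meta named list of metadata (must be JSON-representable).
#' @export
write_snapshot <- function(path, fields, meta = list()) {
  stopifnot(is.list(fields), length(names(fields)) == length(fields))
  meta$arrays <- lapply(fields, dim)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(hdr, "\n")), con)
  for (f in fields) writeBin(as.vector(f), con, size = 8)
  invisible(path)
}

#' Read a snapshot container
#'
#' @param path file written by [write_snapshot()].
#' @return list with `fields` (named matrices) and `meta`.
#' @export
read_snapshot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated snapshot header")
    if (b == charToRaw("\n")) break
    hdr <- c(hdr, b)
  }
  meta <- jsonlite::fromJSON(rawToChar(hdr))
  fields <- list()
  for (nm in names(meta$arrays)) {
    d <- as.integer(meta$arrays[[nm]])
    v <- readBin(con, "double", prod(d), size = 8)
    fields[[nm]] <- matrix(v, d[1], d[2])
  }
  meta$arrays <- NULL
  list(fields = fields, meta = meta)
}

#' Export fields on the axisymmetric grid as a legacy VTK file
#'
#' Rectilinear-grid ASCII VTK (version 3.0) with one scalar dataset per
#' field, suitable for standard scientific visualization tools.
#'
#' @param path output `.vtk` file.
#' @param fields named list of matrices on grid `g`.
#' @param g grid.
#' @export
write_vtk <- function(path, fields, g) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric field snapshot", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", g$nr, g$nz)), con)
  writeLines(sprintf("X_COORDINATES %d double", g$nr), con)
  writeLines(paste(format(g$r_centers, digits = 12), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", g$nz), con)
  writeLines(paste(format(g$z_centers, digits = 12), collapse = " "), con)
  writeLines(c("Z_COORDINATES 1 double", "0"), con)
  writeLines(sprintf("POINT_DATA %d", g$nr * g$nz), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 9),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write an MEP profile as CSV
#'
#' One row per image with index, alpha, the energy components and the
#' profile `dE` (zero by construction at the first image).
#'
#' @param mep [mep_profile()] result.
#' @param path output CSV path.
#' @export
write_mep_csv <- function(mep, path) {
  df <- mep$reports
  df$dE <- mep$dE
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
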