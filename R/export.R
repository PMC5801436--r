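# Plain-text export: VTK legacy unstructured grids for visualization and
# CSV tables for interchange.

#' Write a hexahedral mesh as a legacy VTK unstructured grid
#'
#' Cell data always includes the compartment label and conductivity;
#' additional per-element or per-vertex scalar fields may be supplied.
#'
#' @param mesh a `hex_mesh`.
#' @param file output path (`.vtk`).
#' @param cell_data named list of numeric vectors (one value per element).
#' @param point_data named list of numeric vectors (one value per vertex).
#' @return the file path, invisibly.
#' @export
write_vtk_mesh <- function(mesh, file, cell_data = list(),
                           point_data = list()) {
  nv <- nrow(mesh$vertices)
  ne <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "hexahedral volume conductor mesh",
     "ASCII", "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", nv))
  writeLines(apply(format(mesh$vertices, digits = 12, trim = TRUE,
                          scientific = TRUE), 1, paste, collapse = " "), con)
  # VTK_HEXAHEDRON ordering: bottom ring counter-clockwise, then top ring
  vtk_order <- c(1L, 2L, 4L, 3L, 5L, 6L, 8L, 7L)
  cells <- cbind(8L, mesh$elements[, vtk_order] - 1L)
  wl(sprintf("CELLS %d %d", ne, ne * 9L))
  writeLines(apply(cells, 1, paste, collapse = " "), con)
  wl(sprintf("CELL_TYPES %d", ne))
  writeLines(rep("12", ne), con)
  cd <- c(list(label = mesh$labels, conductivity = mesh$sigma), cell_data)
  wl(sprintf("CELL_DATA %d", ne))
  for (nm in names(cd)) {
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    writeLines(format(cd[[nm]], digits = 12, trim = TRUE), con)
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", nv))
    for (nm in names(point_data)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      writeLines(format(point_data[[nm]], digits = 12, trim = TRUE), con)
    }
  }
  invisible(file)
}

#' Write study summary statistics to CSV
#'
#' @param study a `meg_study`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_study_csv <- function(study, file) {
  write.csv(study$summary, file, row.names = FALSE)
  invisible(file)
}
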