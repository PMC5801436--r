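# Voxelized multi-layer sphere models and regular hexahedral meshes.
#
# Geometry is stored in meters; user-facing radii and resolutions are given
# in millimeters, the customary unit for head models. The voxel grid is
# symmetric about the sphere center with voxel centers at (i + 1/2) h, and a
# voxel is assigned to the innermost compartment whose outer radius is >= the
# distance of the voxel center from the origin (closed outer boundary). This
# convention reproduces the element/vertex bookkeeping of the reference
# 4-layer sphere models exactly and is recorded in the mesh metadata.

MM <- 1e-3

key_base <- 4096L
key_off <- 2048

lattice_key <- function(ix, iy, iz) {
  (ix + key_off) + key_base * (iy + key_off) +
    key_base * key_base * (iz + key_off)
}

#' Compartment table for a multi-layer sphere model
#'
#' The default is the four-layer head approximation with brain, CSF, skull
#' and skin shells of outer radii 78, 80, 86 and 92 mm and conductivities
#' 0.33, 1.79, 0.01 and 0.43 S/m.
#'
#' @param names compartment labels, innermost first.
#' @param outer_radius_mm strictly increasing outer radii in millimeters.
#' @param conductivity conductivities in S/m.
#' @return data.frame of class `compartment_table`.
#' @export
compartment_table <- function(names = c("brain", "csf", "skull", "skin"),
                              outer_radius_mm = c(78, 80, 86, 92),
                              conductivity = c(0.33, 1.79, 0.01, 0.43)) {
  stopifnot(length(names) == length(outer_radius_mm),
            length(names) == length(conductivity))
  if (any(outer_radius_mm <= 0) || any(diff(outer_radius_mm) <= 0))
    stop("outer radii must be positive and strictly increasing")
  if (any(conductivity <= 0))
    stop("conductivities must be positive")
  out <- data.frame(name = names, outer_radius_mm = outer_radius_mm,
                    conductivity = conductivity,
                    stringsAsFactors = FALSE)
  class(out) <- c("compartment_table", "data.frame")
  out
}

#' Leaky-skull variant of the default sphere model
#'
#' Thins the skull shell by moving its outer radius inwards (default
#' 82 mm instead of 86 mm) while keeping all conductivities; meshing such a
#' model at coarse resolution produces skull leakages, i.e. vertices shared
#' by skin and CSF/brain elements.
#'
#' @param skull_radius_mm outer radius of the skull compartment in mm.
#' @return a `compartment_table`.
#' @export
leaky_compartment_table <- function(skull_radius_mm = 82) {
  compartment_table(outer_radius_mm = c(78, 80, skull_radius_mm, 92))
}

#' Voxelize a multi-layer sphere
#'
#' Builds a cubic label grid covering the outermost sphere. Each voxel is
#' labeled with the innermost compartment whose outer radius is at least the
#' distance of the voxel center from the sphere center; voxels with centers
#' outside the outermost radius get label 0.
#'
#' @param compartments a [compartment_table()].
#' @param resolution_mm voxel edge length in millimeters.
#' @return object of class `voxel_segmentation` with fields `labels`
#'   (3D integer array), `voxel_size` and `origin` (meters), and metadata.
#' @export
voxelize_sphere <- function(compartments, resolution_mm) {
  radii <- compartments$outer_radius_mm
  if (resolution_mm <= 0)
    stop("resolution must be positive")
  if (resolution_mm >= max(radii))
    stop("invalid resolution: voxel size must be smaller than the outer radius")
  h <- resolution_mm
  n <- ceiling(max(radii) / h)
  centers <- (seq(-n, n - 1) + 0.5) * h
  nd <- length(centers)
  d2 <- outer(outer(centers^2, centers^2, "+"), centers^2, "+")
  labels <- array(0L, dim = c(nd, nd, nd))
  for (k in rev(seq_along(radii)))
    labels[d2 <= radii[k]^2] <- k
  if (!any(labels > 0L))
    stop("empty model: no voxel center falls inside the outermost radius")
  structure(list(
    labels = labels,
    dims = dim(labels),
    voxel_size = h * MM,
    origin = rep(-n * h * MM, 3),  # low corner of voxel (1,1,1)
    index0 = -n,                   # integer lattice coordinate of first voxel
    compartments = compartments,
    convention = "symmetric-even-grid/center-in-closed-ball"
  ), class = "voxel_segmentation")
}

#' @export
print.voxel_segmentation <- function(x, ...) {
  cat("voxel segmentation:", paste(x$dims, collapse = " x "),
      sprintf("voxels of %.3g mm\n", x$voxel_size / MM))
  tab <- table(factor(x$labels, levels = 0:nrow(x$compartments),
                      labels = c("outside", x$compartments$name)))
  print(tab)
  invisible(x)
}

#' Build a regular hexahedral mesh from a voxel segmentation
#'
#' One hexahedral element per nonzero voxel; shared vertices are deduplicated
#' exactly through integer lattice indexing (no floating point comparisons).
#' Element conductivities are taken from the compartment table.
#'
#' @param seg a `voxel_segmentation`.
#' @param compartments optional compartment table (defaults to the one stored
#'   in `seg`).
#' @return object of class `hex_mesh` with vertices (meters), element
#'   connectivity (corner order j = 1 + dx + 2 dy + 4 dz), per-element label
#'   and conductivity, face-neighbor table and grid metadata.
#' @export
build_hex_mesh <- function(seg, compartments = seg$compartments) {
  stopifnot(inherits(seg, "voxel_segmentation"))
  h <- seg$voxel_size
  sel <- which(seg$labels > 0L)
  if (length(sel) == 0L) stop("segmentation has no labeled voxels")
  ai <- arrayInd(sel, dim(seg$labels))
  iv <- ai - 1L + seg$index0           # voxel low-corner lattice coords
  labels <- as.integer(seg$labels[sel])
  nelem <- nrow(iv)

  off <- corner_offsets()
  corner_keys <- matrix(0, nelem, 8)
  for (j in 1:8)
    corner_keys[, j] <- lattice_key(iv[, 1] + off[j, 1], iv[, 2] + off[j, 2],
                                    iv[, 3] + off[j, 3])
  vkeys <- sort(unique(as.vector(corner_keys)))
  elements <- matrix(match(corner_keys, vkeys), nelem, 8)

  kz <- floor((vkeys) / (key_base * key_base))
  rem <- vkeys - kz * key_base * key_base
  ky <- floor(rem / key_base)
  kx <- rem - ky * key_base
  vertices <- cbind(kx - key_off, ky - key_off, kz - key_off) * h

  ekeys <- lattice_key(iv[, 1], iv[, 2], iv[, 3])
  neighbors <- matrix(0L, nelem, 6)
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (d in 1:6) {
    nk <- lattice_key(iv[, 1] + dirs[d, 1], iv[, 2] + dirs[d, 2],
                      iv[, 3] + dirs[d, 3])
    m <- match(nk, ekeys)
    neighbors[, d] <- ifelse(is.na(m), 0L, m)
  }

  structure(list(
    vertices = vertices,
    elements = elements,
    labels = labels,
    sigma = compartments$conductivity[labels],
    h = h,
    neighbors = neighbors,
    elem_origin = iv * h,
    vox_index = iv,
    elem_keys = ekeys,
    compartments = compartments,
    convention = seg$convention
  ), class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hexahedral mesh: %d elements, %d vertices, h = %.3g mm\n",
              nrow(x$elements), nrow(x$vertices), x$h / MM))
  tab <- table(factor(x$labels, levels = seq_len(nrow(x$compartments)),
                      labels = x$compartments$name))
  print(tab)
  invisible(x)
}

#' Convenience constructor for the reference sphere meshes
#'
#' @param resolution_mm mesh width in millimeters (4, 2 or 1 for the
#'   reference models).
#' @param compartments compartment table, default the 4-layer head model.
#' @return a `hex_mesh`.
#' @export
sphere_mesh <- function(resolution_mm,
                        compartments = compartment_table()) {
  build_hex_mesh(voxelize_sphere(compartments, resolution_mm))
}

#' Internal skeleton of a hexahedral mesh
#'
#' Lists every internal face once, oriented from the lower- to the
#' higher-index element (on the meshes built here the +axis neighbor always
#' has the higher index, so internal normals are +x, +y or +z), and every
#' boundary face with its outward normal. Face areas are h^2.
#'
#' @param mesh a `hex_mesh`.
#' @return object of class `skeleton` with `ifaces` (columns e, f, axis),
#'   `bfaces` (columns e, axis, sign) and a per-element face index table
#'   `face_of` (internal faces 1..n_int, boundary faces n_int + 1..).
#' @export
build_skeleton <- function(mesh) {
  nelem <- nrow(mesh$elements)
  nb <- mesh$neighbors
  ifaces <- NULL
  for (a in 1:3) {
    e <- which(nb[, 2 * a] > 0L)
    if (!length(e)) next
    ifaces <- rbind(ifaces, cbind(e = e, f = nb[e, 2 * a], axis = rep(a, length(e))))
  }
  if (is.null(ifaces)) ifaces <- matrix(integer(0), 0, 3,
                                        dimnames = list(NULL, c("e", "f", "axis")))
  storage.mode(ifaces) <- "integer"
  bl <- which(nb == 0L, arr.ind = TRUE)
  d <- bl[, 2]
  bfaces <- cbind(e = bl[, 1], axis = as.integer((d + 1) %/% 2),
                  sign = ifelse(d %% 2 == 0L, 1L, -1L))
  storage.mode(bfaces) <- "integer"
  ord <- order(bfaces[, 1], bfaces[, 2], bfaces[, 3])
  bfaces <- bfaces[ord, , drop = FALSE]

  nint <- nrow(ifaces)
  face_of <- matrix(0L, nelem, 6)
  # direction column for (axis, sign): 2 axis for +, 2 axis - 1 for -
  face_of[cbind(ifaces[, 1], 2L * ifaces[, 3])] <- seq_len(nint)
  face_of[cbind(ifaces[, 2], 2L * ifaces[, 3] - 1L)] <- seq_len(nint)
  face_of[cbind(bfaces[, 1], 2L * bfaces[, 2] - (bfaces[, 3] < 0))] <-
    nint + seq_len(nrow(bfaces))

  structure(list(ifaces = ifaces, bfaces = bfaces, face_of = face_of,
                 n_int = nint, n_bnd = nrow(bfaces), h = mesh$h,
                 area = mesh$h^2),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("mesh skeleton: %d internal faces, %d boundary faces\n",
              x$n_int, x$n_bnd))
  invisible(x)
}

#' Centroids of skeleton faces
#'
#' @param mesh a `hex_mesh`; @param skeleton its `skeleton`.
#' @param which `"internal"` or `"boundary"`.
#' @return n x 3 matrix of face centroids in meters.
#' @export
face_centroids <- function(mesh, skeleton, which = c("internal", "boundary")) {
  which <- match.arg(which)
  h <- mesh$h
  if (which == "internal") {
    fc <- mesh$elem_origin[skeleton$ifaces[, 1], , drop = FALSE] + h / 2
    a <- skeleton$ifaces[, 3]
    fc[cbind(seq_len(nrow(fc)), a)] <-
      mesh$elem_origin[cbind(skeleton$ifaces[, 1], a)] + h
  } else {
    fc <- mesh$elem_origin[skeleton$bfaces[, 1], , drop = FALSE] + h / 2
    a <- skeleton$bfaces[, 2]
    s <- skeleton$bfaces[, 3]
    fc[cbind(seq_len(nrow(fc)), a)] <-
      mesh$elem_origin[cbind(skeleton$bfaces[, 1], a)] + ifelse(s > 0, h, 0)
  }
  fc
}

# outward unit normals of boundary faces (n_bnd x 3)
boundary_normals <- function(skeleton) {
  n <- matrix(0, skeleton$n_bnd, 3)
  n[cbind(seq_len(skeleton$n_bnd), skeleton$bfaces[, 2])] <-
    skeleton$bfaces[, 3]
  n
}

#' Locate the elements containing given points
#'
#' Element ownership is half-open, `[x, x + h)` along each axis, so a point
#' on a shared face belongs to the element on its positive side.
#'
#' @param mesh a `hex_mesh`.
#' @param points n x 3 matrix (meters).
#' @return integer vector of element ids (0 when outside the mesh).
#' @export
locate_element <- function(mesh, points) {
  points <- rbind(points)
  iv <- floor(points / mesh$h)
  keys <- lattice_key(iv[, 1], iv[, 2], iv[, 3])
  m <- match(keys, mesh$elem_keys)
  ifelse(is.na(m), 0L, m)
}

#' Find skull-leakage vertices
#'
#' A leaky point is a mesh vertex incident to at least one element of the
#' outer compartment (skin) and at least one element of an inner conductive
#' compartment (CSF or brain); such vertices short-circuit the skull when it
#' is meshed too coarsely.
#'
#' @param mesh a `hex_mesh`.
#' @param outer compartment name of the outer conductor (default "skin").
#' @param inner compartment names of the inner conductors.
#' @return sorted integer vector of leaky vertex indices.
#' @export
find_leaky_points <- function(mesh, outer = "skin",
                              inner = c("brain", "csf")) {
  nm <- mesh$compartments$name
  oid <- match(outer, nm)
  iid <- match(inner, nm)
  if (anyNA(oid) || all(is.na(iid)))
    stop("compartment names not found in mesh")
  iid <- iid[!is.na(iid)]
  vo <- unique(as.vector(mesh$elements[mesh$labels == oid, ]))
  vi <- unique(as.vector(mesh$elements[mesh$labels %in% iid, ]))
  sort(intersect(vo, vi))
}
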