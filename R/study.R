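# Validation harness: dipole/sensor generation, RDM%/MAG% error metrics
# against the Sarvas solution, and config-driven accuracy studies in
# multi-layer sphere models.

#' Source eccentricities of the sphere studies
#'
#' The eight logarithmically scaled eccentricities used for the statistical
#' validation, with the corresponding distance to the brain/CSF conductivity
#' jump for the 78 mm brain compartment. (The shallowest set sits 0.99 mm
#' from the interface; numerical errors of the subtraction approach grow as
#' sources approach a conductivity jump.)
#'
#' @param brain_radius_mm brain compartment radius (default 78).
#' @return data.frame with `eccentricity` and `distance_mm`.
#' @export
eccentricity_table <- function(brain_radius_mm = 78) {
  ecc <- c(0.01, 0.5025, 0.7487, 0.8718, 0.9334, 0.9642, 0.9796, 0.9873)
  data.frame(eccentricity = ecc,
             distance_mm = round((1 - ecc) * brain_radius_mm, 2))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate tangential unit dipoles on spherical shells
#'
#' Positions are sampled area-uniformly on each shell (radius = eccentricity
#' times brain radius); each dipole gets one uniformly random unit tangent
#' orientation (tangential sources are the ones visible to MEG in spherical
#' conductors). Sampling is deterministic under the seed.
#'
#' @param n_per_shell dipoles per eccentricity shell.
#' @param eccentricities vector of eccentricities in (0, 1).
#' @param brain_radius_mm brain compartment radius in mm (default 78).
#' @param seed integer RNG seed.
#' @return object of class `dipole_ensemble` with `positions` (n x 3,
#'   meters), `moments` (n x 3, unit A m), `eccentricity` per dipole.
#' @export
generate_dipoles <- function(n_per_shell, eccentricities,
                             brain_radius_mm = 78, seed = 1) {
  if (any(eccentricities <= 0 | eccentricities >= 1))
    stop("eccentricities must lie strictly between 0 and 1")
  n <- n_per_shell * length(eccentricities)
  with_seed(seed, {
    ecc <- rep(eccentricities, each = n_per_shell)
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    u <- cbind(s * cos(phi), s * sin(phi), z)      # unit radial directions
    pos <- u * ecc * brain_radius_mm * MM
    # orthonormal tangent frame at each position
    ref <- ifelse(abs(u[, 3]) < 0.9, 3L, 1L)
    rvec <- matrix(0, n, 3); rvec[cbind(seq_len(n), ref)] <- 1
    e1 <- cross3(rvec, u)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cross3(u, e1)
    th <- runif(n, 0, 2 * pi)
    mom <- cos(th) * e1 + sin(th) * e2
    structure(list(positions = pos, moments = mom, eccentricity = ecc,
                   brain_radius_mm = brain_radius_mm, seed = seed,
                   n_excluded = 0L),
              class = "dipole_ensemble")
  })
}

#' @export
print.dipole_ensemble <- function(x, ...) {
  cat(sprintf("dipole ensemble: %d tangential unit dipoles on %d shells (seed %d)\n",
              nrow(x$positions), length(unique(x$eccentricity)), x$seed))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d dipoles excluded outside the brain compartment)\n",
                x$n_excluded))
  invisible(x)
}

#' Keep only dipoles whose containing element is labeled brain
#'
#' Sources falling into elements of other compartments (possible near the
#' staircase brain boundary of a voxel mesh) are excluded from the error
#' statistics; the exclusion count is recorded on the ensemble.
#'
#' @param ensemble a `dipole_ensemble`; @param mesh a labeled `hex_mesh`.
#' @return filtered `dipole_ensemble`.
#' @export
filter_brain_dipoles <- function(ensemble, mesh) {
  el <- locate_element(mesh, ensemble$positions)
  bid <- match("brain", mesh$compartments$name)
  keep <- el != 0L & mesh$labels[pmax(el, 1L)] == bid
  out <- ensemble
  out$positions <- ensemble$positions[keep, , drop = FALSE]
  out$moments <- ensemble$moments[keep, , drop = FALSE]
  out$eccentricity <- ensemble$eccentricity[keep]
  out$n_excluded <- ensemble$n_excluded + sum(!keep)
  out
}

#' Generate a point-magnetometer array on a sphere
#'
#' Quasi-uniform sensor positions on a sphere of the given radius via a
#' deterministic spherical Fibonacci lattice, with radial and tangential
#' unit frames attached. Point magnetometers measure the field vector at a
#' point (no coil-surface integration).
#'
#' @param n number of magnetometers (default 256).
#' @param radius_mm sensor sphere radius in mm (default 110, outside the
#'   92 mm head model).
#' @return object of class `sensor_array` with `positions` (n x 3, meters),
#'   `normal` (radial unit vectors) and tangential frame `t1`, `t2`.
#' @export
generate_magnetometers <- function(n = 256, radius_mm = 110) {
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  s <- sqrt(1 - z^2)
  phi <- golden * (seq_len(n) - 1)
  u <- cbind(s * cos(phi), s * sin(phi), z)
  ref <- ifelse(abs(u[, 3]) < 0.9, 3L, 1L)
  rvec <- matrix(0, n, 3); rvec[cbind(seq_len(n), ref)] <- 1
  t1 <- cross3(rvec, u)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cross3(u, t1)
  structure(list(positions = u * radius_mm * MM, normal = u, t1 = t1, t2 = t2,
                 radius_mm = radius_mm),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor array: %d point magnetometers at %.4g mm radius\n",
              nrow(x$positions), x$radius_mm))
  invisible(x)
}

#' Relative difference measure (topography error), percent
#'
#' RDM% = 50 ||f_num/||f_num|| - f_ana/||f_ana|| ||_2, in \[0, 100\]:
#' 0 for proportional fields, 100 for anti-proportional ones. Fields are
#' stacked over all sensors and all three Cartesian components, without
#' projection onto sensor orientations.
#'
#' @param f_num,f_ana numeric vectors or matrices of identical shape.
#' @return scalar percentage.
#' @export
rdm_percent <- function(f_num, f_ana) {
  fn <- as.vector(f_num); fa <- as.vector(f_ana)
  nn <- sqrt(sum(fn^2)); na <- sqrt(sum(fa^2))
  if (na == 0)
    stop("analytic field is zero (radial source?): RDM% undefined")
  if (nn == 0)
    stop("numerical field is identically zero: RDM% undefined")
  50 * sqrt(sum((fn / nn - fa / na)^2))
}

#' Magnitude error, percent
#'
#' MAG% = 100 (||f_num|| / ||f_ana|| - 1): 0 for equal magnitudes, positive
#' when the numerical field is too strong.
#'
#' @inheritParams rdm_percent
#' @return scalar percentage.
#' @export
mag_percent <- function(f_num, f_ana) {
  fn <- as.vector(f_num); fa <- as.vector(f_ana)
  na <- sqrt(sum(fa^2))
  if (na == 0)
    stop("analytic field is zero (radial source?): MAG% undefined")
  100 * (sqrt(sum(fn^2)) / na - 1)
}

#' Boxplot statistics of an error sample
#'
#' Mean, median, quartiles (linear interpolation between order statistics,
#' the type-7 convention), interquartile range and total range
#' (maximum - minimum, the whisker convention used for the boxplots).
#'
#' @param x numeric vector of error samples.
#' @return one-row data.frame with n, mean, median, q1, q3, iqr, min, max,
#'   total_range.
#' @export
summarize_errors <- function(x) {
  if (length(x) == 0) stop("empty error sample")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  data.frame(n = length(x), mean = mean(x), median = q[2], q1 = q[1],
             q3 = q[3], iqr = q[3] - q[1], min = min(x), max = max(x),
             total_range = max(x) - min(x))
}

# --------------------------------------------------------------------------
# forward-error engine
# --------------------------------------------------------------------------

#' Forward-model error samples for an ensemble of dipoles
#'
#' Assembles the chosen discretization once, solves the subtraction EEG
#' problem per dipole, integrates the secondary magnetic field with the
#' requested flux representations, and scores RDM%/MAG% against the Sarvas
#' solution, for the secondary field B^s and (optionally) the full field B.
#' Integration matrices are precomputed and reused across dipoles when the
#' memory estimate allows, otherwise fields are integrated directly.
#'
#' @param mesh a `hex_mesh` of a sphere model.
#' @param sensors a `sensor_array` (or position matrix).
#' @param dipoles a `dipole_ensemble` (filtered to the brain compartment).
#' @param method `"cg"` or `"dg"`.
#' @param fluxes character vector from `"nodal"`, `"conservative"`
#'   (conservative requires DG); both may be given to compare integrators on
#'   identical potentials.
#' @param fields which fields to score: subset of `c("Bs", "B")`.
#' @param eta SIPG penalty (DG only); the default 1.085 is the calibrated
#'   near-threshold study value (see the methods vignette).
#' @param tol solver tolerance.
#' @param quad_order Biot-Savart quadrature per axis.
#' @param matrix_budget maximal bytes for a precomputed dense integration
#'   matrix (default 8e8).
#' @param skeleton optional precomputed skeleton.
#' @param verbose print per-dipole progress.
#' @return data.frame of samples: dipole index, eccentricity, method, flux,
#'   field, rdm, mag, solver iterations.
#' @export
forward_error_samples <- function(mesh, sensors, dipoles, method = c("dg", "cg"),
                                  fluxes = "conservative",
                                  fields = "Bs", eta = 1.085, tol = 1e-8,
                                  quad_order = 3, matrix_budget = 8e8,
                                  skeleton = NULL, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(all(fluxes %in% c("nodal", "conservative")),
            all(fields %in% c("Bs", "B")))
  if (method == "cg" && any(fluxes == "conservative"))
    stop("conservative flux integration requires the DG discretization")
  pos <- sensor_positions(sensors)
  ns <- nrow(pos)
  if (is.null(skeleton)) skeleton <- build_skeleton(mesh)

  if (method == "cg") {
    system <- assemble_cg_stiffness(mesh)
    ndof <- nrow(mesh$vertices)
  } else {
    system <- assemble_dg_stiffness(mesh, eta = eta)
    ndof <- 8L * nrow(mesh$elements)
  }

  use_Snodal <- 3 * ns * ndof * 8 <= matrix_budget
  S_nodal <- if (use_Snodal)
    assemble_S_nodal(mesh, pos, basis = method, quad_order = quad_order)
  use_moments <- "conservative" %in% fluxes &&
    3 * ns * (skeleton$n_int + skeleton$n_bnd) * 8 <= matrix_budget
  moments <- if (use_moments)
    assemble_rt0_moments(mesh, skeleton, pos, quad_order = quad_order)

  out <- vector("list", nrow(dipoles$positions) * length(fluxes) *
                  length(fields))
  oi <- 0L
  for (d in seq_len(nrow(dipoles$positions))) {
    dip0 <- dipole(dipoles$positions[d, ], dipoles$moments[d, ])
    se <- source_environment(mesh, dip0)
    dip <- se$dipole
    if (method == "cg") {
      rhs <- assemble_cg_rhs(mesh, dip, se$sigma_inf)
      sol <- solve_neumann(system, rhs, tol)
    } else {
      rhs <- assemble_dg_rhs(mesh, skeleton, dip, se$sigma_inf)
      sol <- solve_dg(system, rhs, tol)
    }
    B_ana <- sarvas_b_field(dip, pos)
    Bp <- primary_b_field(dip, pos)
    Bs_ana <- B_ana - Bp
    for (fx in fluxes) {
      bf <- full_b_field(dip, pos, sol, skeleton = skeleton, flux = fx,
                         sigma_inf = se$sigma_inf, eta = eta,
                         S_infty = S_nodal,
                         S_corr = if (fx == "nodal") S_nodal,
                         rt0_moments = if (fx == "conservative") moments,
                         quad_order = quad_order)
      for (fd in fields) {
        num <- if (fd == "Bs") bf$Bs else bf$B
        ana <- if (fd == "Bs") Bs_ana else B_ana
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          dipole = d, eccentricity = dipoles$eccentricity[d],
          method = method, flux = fx, field = fd,
          rdm = rdm_percent(num, ana), mag = mag_percent(num, ana),
          iterations = if (!is.null(sol$info$iterations))
            sol$info$iterations else NA_integer_)
      }
    }
    if (verbose)
      message(sprintf("dipole %d/%d done (ecc %.4f)", d,
                      nrow(dipoles$positions), dipoles$eccentricity[d]))
    if (ndof > 2e6 || d %% 8L == 0L)
      invisible(gc(FALSE))  # cap allocation churn on big meshes
  }
  do.call(rbind, out[seq_len(oi)])
}

# --------------------------------------------------------------------------
# study driver
# --------------------------------------------------------------------------

#' Run a sphere-model validation study
#'
#' Reproduces the four statistical studies at configurable scale:
#' \describe{
#'   \item{`"flux"`}{conservative vs non-conservative flux integrators
#'     applied to identical DG potentials on one mesh;}
#'   \item{`"convergence"`}{conservative DG across mesh resolutions;}
#'   \item{`"cg-vs-dg"`}{CG vs conservative DG across resolutions, scoring
#'     both the secondary and the full field;}
#'   \item{`"leaky"`}{CG and conservative DG on a sphere model vs its
#'     thinned-skull (leaky) variant.}
#' }
#' Dipoles are regenerated per study from the seed and filtered to the brain
#' compartment of each mesh; radial sources are never generated (tangential
#' orientations only).
#'
#' @param study one of `"flux"`, `"convergence"`, `"cg-vs-dg"`, `"leaky"`.
#' @param resolutions_mm mesh width(s) in mm.
#' @param eccentricities dipole shell eccentricities.
#' @param n_per_shell dipoles per shell before brain filtering.
#' @param n_sensors number of point magnetometers.
#' @param sensor_radius_mm sensor sphere radius (default 110).
#' @param seed RNG seed for the dipole ensemble.
#' @param eta SIPG penalty.
#' @param tol solver tolerance.
#' @param quad_order Biot-Savart quadrature order.
#' @param leaky_skull_mm outer skull radius of the leaky variant (study
#'   `"leaky"`, default 82).
#' @param matrix_budget see [forward_error_samples()].
#' @param verbose progress output.
#' @return object of class `meg_study`: list with `samples`, per-cell
#'   `summary` (statistics per eccentricity/method/flux/mesh/field) and the
#'   configuration.
#' @export
run_study <- function(study = c("flux", "convergence", "cg-vs-dg", "leaky"),
                      resolutions_mm = 4,
                      eccentricities = eccentricity_table()$eccentricity,
                      n_per_shell = 50, n_sensors = 64,
                      sensor_radius_mm = 110, seed = 1, eta = 1.085,
                      tol = 1e-8,
                      quad_order = 3, leaky_skull_mm = 82,
                      matrix_budget = 8e8, verbose = FALSE) {
  study <- match.arg(study)
  sensors <- generate_magnetometers(n_sensors, sensor_radius_mm)
  ens0 <- generate_dipoles(n_per_shell, eccentricities, seed = seed)

  runs <- list()
  add_run <- function(mesh_name, compartments, resolution, method, fluxes,
                      fields)
    runs[[length(runs) + 1]] <<- list(mesh_name = mesh_name,
                                      compartments = compartments,
                                      resolution = resolution,
                                      method = method, fluxes = fluxes,
                                      fields = fields)
  std <- compartment_table()
  mesh_tag <- function(res) sprintf("seg_%g_res_%g", res, res)
  if (study == "flux") {
    add_run(mesh_tag(resolutions_mm[1]), std, resolutions_mm[1], "dg",
            c("conservative", "nodal"), "Bs")
  } else if (study == "convergence") {
    for (r in resolutions_mm)
      add_run(mesh_tag(r), std, r, "dg", "conservative", "Bs")
  } else if (study == "cg-vs-dg") {
    for (r in resolutions_mm) {
      add_run(mesh_tag(r), std, r, "cg", "nodal", c("Bs", "B"))
      add_run(mesh_tag(r), std, r, "dg", "conservative", c("Bs", "B"))
    }
  } else {
    leaky <- leaky_compartment_table(leaky_skull_mm)
    r <- resolutions_mm[1]
    for (method in c("cg", "dg")) {
      fx <- if (method == "cg") "nodal" else "conservative"
      add_run(mesh_tag(r), std, r, method, fx, "Bs")
      add_run(sprintf("seg_%g_res_%g_r%g", r, r, leaky_skull_mm), leaky, r,
              method, fx, "Bs")
    }
  }

  samples <- NULL
  meshes <- list()
  for (run in runs) {
    key <- run$mesh_name
    if (is.null(meshes[[key]])) {
      mesh <- build_hex_mesh(voxelize_sphere(run$compartments,
                                             run$resolution))
      meshes[[key]] <- list(mesh = mesh, skeleton = build_skeleton(mesh))
    }
    m <- meshes[[key]]
    ens <- filter_brain_dipoles(ens0, m$mesh)
    if (nrow(ens$positions) == 0)
      stop("infeasible configuration: no dipole inside the brain compartment")
    s <- forward_error_samples(m$mesh, sensors, ens, method = run$method,
                               fluxes = run$fluxes, fields = run$fields,
                               eta = eta, tol = tol, quad_order = quad_order,
                               matrix_budget = matrix_budget,
                               skeleton = m$skeleton, verbose = verbose)
    s$mesh <- key
    s$excluded <- ens$n_excluded
    samples <- rbind(samples, s)
  }

  cells <- unique(samples[, c("eccentricity", "method", "flux", "mesh",
                              "field")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- samples$eccentricity == cells$eccentricity[i] &
      samples$method == cells$method[i] & samples$flux == cells$flux[i] &
      samples$mesh == cells$mesh[i] & samples$field == cells$field[i]
    cbind(cells[i, , drop = FALSE],
          metric = c("rdm", "mag"),
          rbind(summarize_errors(samples$rdm[sel]),
                summarize_errors(samples$mag[sel])),
          row.names = NULL)
  }))

  structure(list(samples = samples, summary = summ,
                 config = list(study = study, resolutions_mm = resolutions_mm,
                               eccentricities = eccentricities,
                               n_per_shell = n_per_shell,
                               n_sensors = n_sensors,
                               sensor_radius_mm = sensor_radius_mm,
                               seed = seed, eta = eta, tol = tol,
                               quad_order = quad_order)),
            class = "meg_study")
}

#' @export
print.meg_study <- function(x, ...) {
  cat(sprintf("MEG validation study '%s': %d error samples\n",
              x$config$study, nrow(x$samples)))
  cat("mean RDM% of the secondary field by eccentricity:\n")
  s <- x$summary[x$summary$metric == "rdm" & x$summary$field == "Bs", ]
  print(s[, c("eccentricity", "method", "flux", "mesh", "mean", "median",
              "iqr")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.meg_study <- function(x, metric = c("rdm", "mag"), field = "Bs", ...) {
  metric <- match.arg(metric)
  s <- x$samples[x$samples$field == field, ]
  grp <- interaction(s$eccentricity, s$method, s$flux, s$mesh, drop = TRUE)
  graphics::boxplot(s[[metric]] ~ grp, las = 2,
                    ylab = if (metric == "rdm") "RDM%" else "MAG%",
                    xlab = "", ...)
  invisible(x)
}
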