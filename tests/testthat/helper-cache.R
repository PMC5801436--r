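# Lazily computed heavyweight fixtures shared across acceptance-test blocks
# (built once per test run; the 4 mm sphere pipeline dominates the cost).

acceptance_cache <- new.env(parent = emptyenv())

acc_mesh4 <- function() {
  if (is.null(acceptance_cache$mesh4)) {
    mesh <- sphere_mesh(4)
    acceptance_cache$mesh4 <- list(mesh = mesh,
                                   skeleton = build_skeleton(mesh))
  }
  acceptance_cache$mesh4
}

acc_sensors <- function() {
  if (is.null(acceptance_cache$sensors))
    acceptance_cache$sensors <- generate_magnetometers(64, 110)
  acceptance_cache$sensors
}

# study-1 style run: conservative vs nodal DG flux on identical potentials,
# 4 mm sphere, eccentricity 0.9796, seeded tangential dipoles
acc_flux_study <- function() {
  if (is.null(acceptance_cache$flux_study)) {
    m <- acc_mesh4()
    ens <- filter_brain_dipoles(generate_dipoles(64, 0.9796, seed = 1),
                                m$mesh)
    acceptance_cache$flux_study <- forward_error_samples(
      m$mesh, acc_sensors(), ens, method = "dg",
      fluxes = c("conservative", "nodal"), fields = "Bs",
      eta = acc_eta(), tol = 1e-6, skeleton = m$skeleton)
  }
  acceptance_cache$flux_study
}

# single high-eccentricity DG solve at tight tolerance (conservation check)
acc_conservation_solve <- function() {
  if (is.null(acceptance_cache$conservation)) {
    m <- acc_mesh4()
    ens <- generate_dipoles(1, 0.9796, seed = 2)
    dip <- dipole(ens$positions[1, ], ens$moments[1, ])
    se <- source_environment(m$mesh, dip)
    sys <- assemble_dg_stiffness(m$mesh, eta = acc_eta())
    rhs <- assemble_dg_rhs(m$mesh, m$skeleton, se$dipole, se$sigma_inf)
    sol <- solve_dg(sys, rhs, tol = 1e-8)
    acceptance_cache$conservation <- list(system = sys, solution = sol,
                                          se = se, rhs = rhs)
  }
  acceptance_cache$conservation
}

acc_free_4mm <- function() {
  rm(list = ls(acceptance_cache), envir = acceptance_cache)
  invisible(gc())
}

# SIPG penalty used in all acceptance-scale studies (the calibrated
# near-threshold study value; see the methods vignette)
acc_eta <- function() 1.085
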