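# Nonlinear Poisson-Boltzmann solver driver: grid construction, dielectric
# and ion-accessibility maps, two-level focusing, and the diffusive-ion
# enthalpy/entropy functionals.

# Node lattice centered on the atom bounding box so that symmetric inputs
# produce symmetric grids.
make_grid <- function(xyzr, spacing, pad) {
  lo <- apply(xyzr[, 1:3, drop = FALSE], 2, min) - max(xyzr[, 4]) - pad
  hi <- apply(xyzr[, 1:3, drop = FALSE], 2, max) + max(xyzr[, 4]) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  center <- (lo + hi) / 2
  origin <- center - (dims - 1L) * spacing / 2
  list(origin = origin, h = spacing, dims = dims,
       n = prod(dims))
}

grid_coords_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$h
}

# maps for one grid level: signed surface distance, smoothed dielectric,
# per-species accessibility (Stern exclusion by hydrated radius)
grid_maps <- function(s, grid, cond, species, config) {
  reach <- max(c(species$excl, config$ion_radius[["Mg"]])) + 2 * grid$h
  dmin <- cpp_surface_distance(atoms_xyzr(s), grid$origin, grid$h, grid$dims,
                               reach)
  frac <- pmin(pmax((grid$h / 2 - dmin) / grid$h, 0), 1) # solute volume frac
  eps <- cond$eps_w - (cond$eps_w - cond$eps_in) * frac
  if (nrow(species)) {
    acc <- vapply(seq_len(nrow(species)),
                  function(a) as.numeric(dmin > species$excl[a]),
                  numeric(length(dmin)))
    if (!is.matrix(acc)) acc <- matrix(acc, ncol = nrow(species))
  } else {
    acc <- matrix(0, length(dmin), 1) # placeholder column for the kernels
  }
  list(dmin = dmin, eps = eps, acc = acc, solute_frac = frac)
}

face_index <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- rep(seq_len(nx), times = ny * nz)
  j <- rep(rep(seq_len(ny), each = nx), times = nz)
  k <- rep(seq_len(nz), each = nx * ny)
  which(i == 1 | i == nx | j == 1 | j == ny | k == 1 | k == nz)
}

node_coords <- function(grid, ids) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  ids0 <- ids - 1L
  i <- ids0 %% nx
  j <- (ids0 %/% nx) %% ny
  k <- ids0 %/% (nx * ny)
  cbind(grid$origin[1] + i * grid$h,
        grid$origin[2] + j * grid$h,
        grid$origin[3] + k * grid$h)
}

interp_trilinear <- function(u, grid, pts) {
  f <- sweep(pts, 2, grid$origin) / grid$h
  i0 <- pmin(pmax(floor(f[, 1]), 0), grid$dims[1] - 2)
  j0 <- pmin(pmax(floor(f[, 2]), 0), grid$dims[2] - 2)
  k0 <- pmin(pmax(floor(f[, 3]), 0), grid$dims[3] - 2)
  wx <- f[, 1] - i0; wy <- f[, 2] - j0; wz <- f[, 3] - k0
  nx <- grid$dims[1]; ny <- grid$dims[2]
  out <- numeric(nrow(pts))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
         (if (dk) wz else 1 - wz)
    id <- (i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk)) + 1
    out <- out + w * u[id]
  }
  out
}

solve_level <- function(charges, grid, maps, cond, species, config,
                        bc_u, bc_uprime, label) {
  fourpiC <- 4 * pi * coulomb_kbt(cond$temperature_celsius)
  rho <- cpp_spread_charges(charges, grid$origin, grid$h, grid$dims)
  zero_c <- rep(0, max(1, nrow(species)))
  zv <- if (nrow(species)) species$z else 0
  cv <- if (nrow(species)) species$c_a3 else 0
  res <- cpp_solve_pb(maps$eps, rho, maps$acc, zv, cv, bc_u,
                      grid$dims, grid$h, fourpiC, config$tol,
                      config$max_outer, config$max_inner, config$omega)
  if (!res$converged)
    tbion_error(sprintf("PB solver did not converge on %s grid (max step %.3g)",
                        label, res$max_step),
                "tbion_pb_convergence", residual = res$max_step)
  resp <- cpp_solve_pb(maps$eps, rho, maps$acc, zv, zero_c[seq_along(zv)],
                       bc_uprime, grid$dims, grid$h, fourpiC, config$tol,
                       config$max_outer, config$max_inner, config$omega)
  if (!resp$converged)
    tbion_error(sprintf("Poisson (no-ion) solve did not converge on %s grid",
                        label),
                "tbion_pb_convergence", residual = resp$max_step)
  list(grid = grid, maps = maps, u = res$u, uprime = resp$u,
       outer = res$outer, max_step = res$max_step)
}

#' Solve the nonlinear Poisson-Boltzmann equation around an RNA
#'
#' Finite-difference solution of the full (nonlinear, mixed-valence) PB
#' equation with the RNA phosphates plus any tightly bound ions as fixed
#' sources. The dielectric is `eps_in` inside the smoothed atom-sphere union
#' and `eps_w` outside; each mobile species is Boltzmann-weighted only on
#' nodes beyond its hydrated-radius Stern exclusion. A two-level focusing
#' scheme is used by default: a coarse solve with Debye-Hueckel boundary
#' values supplies Dirichlet conditions for a fine solve around the RNA.
#' Alongside the potential `psi`, the same fixed-charge problem is solved
#' with all mobile terms switched off (`psi_prime`, plain-Coulomb boundary
#' values), as required by the diffusive-ion enthalpy functional.
#'
#' @param s an [rna_structure()].
#' @param bound_ions optional matrix/data.frame with columns x, y, z, q of
#'   tightly bound ion point charges (Angstrom, elementary charges).
#' @param cond a [solution_condition()].
#' @param config a [tbi_config()].
#' @return an object of class `pb_field` with elements `fine` (and `coarse`
#'   when focusing), each carrying the grid, potentials `u`/`uprime` in
#'   kBT/e, dielectric and accessibility maps; plus the species table and
#'   screening constant `kappa`.
#' @export
solve_nlpb <- function(s, bound_ions = NULL, cond = solution_condition(),
                       config = tbi_config()) {
  config <- as_tbi_config(config)
  species <- condition_species(cond, config)
  kappa <- debye_kappa(cond, config)
  C <- coulomb_kbt(cond$temperature_celsius)
  charges <- phosphate_xyzq(s)
  if (!is.null(bound_ions) && NROW(bound_ions) > 0) {
    bi <- as.matrix(as.data.frame(bound_ions)[, c("x", "y", "z", "q")])
    charges <- rbind(charges, bi)
  }
  # grids must enclose every fixed charge (bound ions can sit beyond the
  # atom bounding box, in the tightly bound shell)
  xyzr <- rbind(atoms_xyzr(s),
                cbind(charges[, 1:3, drop = FALSE],
                      max(atoms_xyzr(s)[, 4])))

  pad_coarse <- config$pad_coarse
  if (is.null(pad_coarse))
    pad_coarse <- max(if (kappa > 0) 4 / kappa else 0, 15)

  if (config$focusing) {
    hc <- config$spacing * config$coarse_factor
    gc_ <- make_grid(xyzr, hc, pad_coarse)
    mc <- grid_maps(s, gc_, cond, species, config)
    bc_u <- cpp_face_potential(numeric(gc_$n), charges, gc_$origin, hc,
                               gc_$dims, kappa, cond$eps_w, C)
    bc_up <- cpp_face_potential(numeric(gc_$n), charges, gc_$origin, hc,
                                gc_$dims, 0, cond$eps_w, C)
    coarse <- solve_level(charges, gc_, mc, cond, species, config,
                          bc_u, bc_up, "coarse")
    gf <- make_grid(xyzr, config$spacing, config$pad_fine)
    mf <- grid_maps(s, gf, cond, species, config)
    faces <- face_index(gf$dims)
    fpts <- node_coords(gf, faces)
    bu <- numeric(gf$n); bu[faces] <- interp_trilinear(coarse$u, gc_, fpts)
    bp <- numeric(gf$n); bp[faces] <- interp_trilinear(coarse$uprime, gc_, fpts)
    fine <- solve_level(charges, gf, mf, cond, species, config, bu, bp, "fine")
  } else {
    gf <- make_grid(xyzr, config$spacing, pad_coarse)
    mf <- grid_maps(s, gf, cond, species, config)
    bc_u <- cpp_face_potential(numeric(gf$n), charges, gf$origin, gf$h,
                               gf$dims, kappa, cond$eps_w, C)
    bc_up <- cpp_face_potential(numeric(gf$n), charges, gf$origin, gf$h,
                                gf$dims, 0, cond$eps_w, C)
    fine <- solve_level(charges, gf, mf, cond, species, config,
                        bc_u, bc_up, "single")
    coarse <- NULL
  }
  structure(list(fine = fine, coarse = coarse, cond = cond, config = config,
                 species = species, kappa = kappa, charges = charges),
            class = "pb_field")
}

#' @export
print.pb_field <- function(x, ...) {
  g <- x$fine$grid
  cat(sprintf("PB field: fine grid %d x %d x %d @ %.2f A%s\n",
              g$dims[1], g$dims[2], g$dims[3], g$h,
              if (!is.null(x$coarse)) " (focused)" else ""))
  cat(sprintf("  kappa = %.4f 1/A, %d mobile species, %d fixed charges\n",
              x$kappa, nrow(x$species), nrow(x$charges)))
  invisible(x)
}

#' Local mobile-ion concentrations of a PB field
#'
#' @param field a `pb_field` from [solve_nlpb()].
#' @param level `"fine"` or `"coarse"`.
#' @return matrix (nodes x species, mol/L): `c0 * exp(-z u)` on accessible
#'   nodes, 0 on excluded nodes. Column names are the species.
#' @export
pb_concentrations <- function(field, level = "fine") {
  lv <- field[[level]]
  sp <- field$species
  out <- vapply(seq_len(nrow(sp)), function(a) {
    x <- pmin(pmax(-sp$z[a] * lv$u, -40), 40)
    sp$c_molar[a] * exp(x) * lv$maps$acc[, a]
  }, numeric(length(lv$u)))
  colnames(out) <- sp$name
  out
}

# which coarse nodes fall inside the fine box (they are excluded from the
# coarse share of the volume integrals)
coarse_outside_fine <- function(field) {
  gc_ <- field$coarse$grid; gf <- field$fine$grid
  lo <- gf$origin; hi <- gf$origin + (gf$dims - 1L) * gf$h
  pts <- node_coords(gc_, seq_len(gc_$n))
  !(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
}

#' Diffusive-ion free energy functionals
#'
#' Grid quadrature of the diffusive-ion enthalpy and entropy:
#' `dU_d = 1/2 integral sum_a c_a z_a q (psi + psi') dV` and
#' `dS_d = -kB integral sum_a [c_a ln(c_a/c0_a) - c_a + c0_a] dV`,
#' with concentrations converted from mol/L to number densities. With
#' focusing, the fine grid integrates its own box and the coarse grid the
#' remainder. Also returns the diffusive excess ion counts
#' `integral (c_a - c0_a) dV` used by the binding-fraction layer.
#'
#' @param field a `pb_field` from [solve_nlpb()].
#' @param cond the [solution_condition()] (defaults to the one in `field`).
#' @return list with `du_d` (kBT), `ds_d` (kB; non-positive), `ts_d`
#'   (= T dS_d in kBT), `dg_d` (= du_d - ts_d, kBT) and `excess` (named, ions
#'   per species).
#' @export
diffusive_free_energy <- function(field, cond = field$cond) {
  sp <- field$species
  if (!nrow(sp))
    return(list(du_d = 0, ds_d = 0, ts_d = 0, dg_d = 0,
                excess = numeric(0)))
  lv <- field$fine
  ff <- cpp_pb_functionals(lv$u, lv$uprime, lv$maps$acc,
                           rep(TRUE, lv$grid$n), sp$z, sp$c_a3, lv$grid$h)
  du <- ff$du_d; sint <- ff$s_integral; exc <- ff$excess
  if (!is.null(field$coarse)) {
    lc <- field$coarse
    inc <- coarse_outside_fine(field)
    fc <- cpp_pb_functionals(lc$u, lc$uprime, lc$maps$acc, inc,
                             sp$z, sp$c_a3, lc$grid$h)
    du <- du + fc$du_d; sint <- sint + fc$s_integral
    exc <- exc + fc$excess
  }
  names(exc) <- sp$name
  # sint = integral of c ln(c/c0) - c + c0  (>= 0 pointwise), in kB
  list(du_d = du, ds_d = -sint, ts_d = -sint, dg_d = du + sint,
       excess = exc)
}
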