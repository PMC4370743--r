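# Generalized Born treatment of the tightly bound region: effective Born
# radii by the Coulomb-field approximation, and the self / polarization /
# Coulomb energy terms for a configuration of phosphates and bound ions.

# Solute volume representation for the Born integral: grid nodes carrying a
# low-dielectric volume fraction, from the same smoothed atom-sphere union
# used for the PB dielectric map. `atoms` allows restricting the solute body
# to a subset (e.g. a single residue for reference radii).
born_context <- function(s, config = tbi_config(), atoms = NULL) {
  config <- as_tbi_config(config)
  h <- config$born_spacing
  if (is.null(atoms)) atoms <- atoms_xyzr(s)
  grid <- make_grid(atoms, h, 2 * h)
  dmin <- cpp_surface_distance(atoms, grid$origin, h, grid$dims, 2 * h)
  w <- pmin(pmax((h / 2 - dmin) / h, 0), 1)
  keep <- which(w > 0)
  nodes <- cbind(node_coords(grid, keep), w[keep])
  list(nodes = nodes, h = h)
}

# Reference Born radius of each phosphate in its isolated nucleotide: the
# same Coulomb-field integral restricted to the atoms of the phosphate's own
# residue. The self-energy then measures only the burial caused by the rest
# of the structure, so the total free energy is the assembly free energy
# relative to separated nucleotides (quadrature bias cancels between B and
# B0 because both use the same integrator).
phosphate_reference_radii <- function(s, config = tbi_config()) {
  config <- as_tbi_config(config)
  vapply(seq_len(nrow(s$phosphates)), function(i) {
    nt <- s$phosphates$nt[i]
    sub <- s$atoms[s$atoms$nt == nt, , drop = FALSE]
    ctx <- born_context(s, config,
                        atoms = as.matrix(sub[, c("x", "y", "z", "radius")]))
    born_radii_points(ctx,
                      as.matrix(s$phosphates[i, c("x", "y", "z"), drop = FALSE]),
                      s$phosphates$radius[i])
  }, numeric(1))
}

# Born radii at arbitrary points with intrinsic radii a, using a prepared
# context (exposed for oracle testing at other resolutions).
born_radii_points <- function(ctx, pts, a) {
  pts <- as.matrix(pts)
  if (nrow(pts) >= 2) {
    dd <- as.matrix(stats::dist(pts))
    diag(dd) <- Inf
    if (any(dd < 1e-9))
      tbion_error("two charges at identical coordinates", "tbion_bad_argument")
  }
  cpp_born_integral(pts, as.numeric(a), ctx$nodes, ctx$h)
}

#' Effective Born radii by the Coulomb-field approximation
#'
#' For each charge (phosphates of the structure, then any bound ions) the
#' effective Born radius is computed as
#' `1/B = 1/a - (1/4 pi) * integral over the low-dielectric region outside
#' the charge's own sphere of dV/r^4`, by volume quadrature on a grid
#' (`born_spacing` in the config). `a` is the intrinsic radius: the atom
#' radius for a phosphate, the hydrated radius for an ion. An isolated ion
#' recovers `B = a`; a charge buried at the center of a low-dielectric
#' sphere of radius R recovers `B = R`.
#'
#' @param s an [rna_structure()].
#' @param bound_ions optional data.frame/matrix with columns x, y, z (and
#'   optionally q, radius) of tightly bound ions.
#' @param config a [tbi_config()].
#' @return numeric vector of Born radii (Angstrom), phosphates first then
#'   ions, with attribute `kind`.
#' @export
born_radii <- function(s, bound_ions = NULL, config = tbi_config()) {
  config <- as_tbi_config(config)
  ctx <- born_context(s, config)
  pts <- as.matrix(s$phosphates[, c("x", "y", "z")])
  a <- s$phosphates$radius
  kind <- rep("phosphate", nrow(pts))
  if (!is.null(bound_ions) && NROW(bound_ions) > 0) {
    bi <- as.data.frame(bound_ions)
    ra <- if ("radius" %in% names(bi)) bi$radius
          else rep(config$ion_radius[["Mg"]], nrow(bi))
    pts <- rbind(pts, as.matrix(bi[, c("x", "y", "z")]))
    a <- c(a, ra)
    kind <- c(kind, rep("bound_ion", nrow(bi)))
  }
  B <- born_radii_points(ctx, pts, a)
  attr(B, "kind") <- kind
  B
}

#' Charge configuration for the tightly-bound-region energy terms
#'
#' Assembles positions, charges, Born radii `B` and intrinsic/hydrated
#' reference radii `B0` for the phosphates plus any tightly bound ions, as
#' consumed by [u_self()], [u_pol()] and [u_ele()].
#'
#' @inheritParams born_radii
#' @param ctx optional precomputed Born context (reused across Monte-Carlo
#'   placements).
#' @details The reference radius `B0` is the radius against which burial is
#'   measured: for a phosphate, its Born radius in the isolated nucleotide
#'   (own-residue atoms only), so the self energy counts only inter-residue
#'   burial; for a bound ion, its hydrated radius.
#' @return data.frame with columns x, y, z, q, B, B0, kind.
#' @export
charge_config <- function(s, bound_ions = NULL, config = tbi_config(),
                          ctx = NULL) {
  config <- as_tbi_config(config)
  if (is.null(ctx)) ctx <- born_context(s, config)
  pts <- as.matrix(s$phosphates[, c("x", "y", "z")])
  q <- s$phosphates$charge
  a <- s$phosphates$radius
  b0 <- phosphate_reference_radii(s, config)
  kind <- rep("phosphate", nrow(pts))
  if (!is.null(bound_ions) && NROW(bound_ions) > 0) {
    bi <- as.data.frame(bound_ions)
    if (!"q" %in% names(bi)) bi$q <- 2
    if (!"radius" %in% names(bi)) bi$radius <- config$ion_radius[["Mg"]]
    pts <- rbind(pts, as.matrix(bi[, c("x", "y", "z")]))
    q <- c(q, bi$q)
    a <- c(a, bi$radius)
    b0 <- c(b0, bi$radius)
    kind <- c(kind, rep("bound_ion", nrow(bi)))
  }
  B <- born_radii_points(ctx, pts, a)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], q = q,
             B = as.numeric(B), B0 = b0, kind = kind,
             stringsAsFactors = FALSE)
}

eps_prefactor <- function(cond) 1 / cond$eps_w - 1 / cond$eps_in # negative

#' Self (Born) energy of the tightly bound region
#'
#' `u_self` is the solvation self-energy of the charge set in the
#' two-dielectric medium. Two references are available. The default,
#' `"isolated"`, measures every charge against its isolated solvated state:
#' `(1/eps_w - 1/eps_in) * sum_x q_x^2/2 * (1/B_x - 1/B0_x)`,
#' where `B0` is the intrinsic radius for a phosphate and the hydrated
#' radius for an ion; the total free energy is then the charging free energy
#' relative to infinitely separated solvated groups, which is the convention
#' behind the reported totals. `"uniform"` uses the no-subtraction form for
#' phosphates, `1/2 (1/eps_w - 1/eps_in) sum_p q_p^2/B_p` (reference: the
#' same charges in a uniform `eps_in` medium); ions carry the `(1/B - 1/B0)`
#' correction in both conventions. Both vanish when `eps_in = eps_w`.
#'
#' @param cfg a [charge_config()].
#' @param cond a [solution_condition()].
#' @param reference `"isolated"` (default) or `"uniform"`; see Details.
#' @return energy in kBT at the condition's temperature.
#' @export
u_self <- function(cfg, cond, reference = c("isolated", "uniform")) {
  reference <- match.arg(reference)
  pre <- eps_prefactor(cond)
  if (reference == "isolated") {
    e_kcal <- COULOMB_KCAL * pre * sum(cfg$q^2 / 2 * (1 / cfg$B - 1 / cfg$B0))
  } else {
    ph <- cfg$kind == "phosphate"
    e_kcal <- COULOMB_KCAL * pre *
      (0.5 * sum(cfg$q[ph]^2 / cfg$B[ph]) +
       sum(cfg$q[!ph]^2 / 2 * (1 / cfg$B[!ph] - 1 / cfg$B0[!ph])))
  }
  kcal_to_kbt(e_kcal, cond$temperature_celsius)
}

pair_terms <- function(cfg) {
  n <- nrow(cfg)
  if (n < 2) return(NULL)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- ij[, 1]; nn <- ij[, 2]
  d <- sqrt((cfg$x[m] - cfg$x[nn])^2 + (cfg$y[m] - cfg$y[nn])^2 +
            (cfg$z[m] - cfg$z[nn])^2)
  list(m = m, n = nn, r = d, qq = cfg$q[m] * cfg$q[nn],
       BB = cfg$B[m] * cfg$B[nn])
}

#' Polarization (cross reaction-field) energy
#'
#' `(1/eps_w - 1/eps_in) * sum_{m<n} q_m q_n / f_GB(r_mn)` with the Still
#' kernel `f_GB = sqrt(r^2 + B_m B_n exp(-r^2 / (4 B_m B_n)))`. Together
#' with [u_ele()] this interpolates between fully water-screened Coulomb
#' interaction at large separation and interior-dielectric interaction at
#' contact.
#'
#' @inheritParams u_self
#' @return energy in kBT.
#' @export
u_pol <- function(cfg, cond) {
  pt <- pair_terms(cfg)
  if (is.null(pt)) return(0)
  fgb <- sqrt(pt$r^2 + pt$BB * exp(-pt$r^2 / (4 * pt$BB)))
  e_kcal <- COULOMB_KCAL * eps_prefactor(cond) * sum(pt$qq / fgb)
  kcal_to_kbt(e_kcal, cond$temperature_celsius)
}

#' Direct Coulomb energy at the interior dielectric
#'
#' `sum_{m<n} q_m q_n / (eps_in r_mn)`.
#'
#' @inheritParams u_self
#' @return energy in kBT.
#' @export
u_ele <- function(cfg, cond) {
  pt <- pair_terms(cfg)
  if (is.null(pt)) return(0)
  if (any(pt$r < 1e-8))
    tbion_error("coincident charges in Coulomb sum", "tbion_bad_argument")
  e_kcal <- COULOMB_KCAL * sum(pt$qq / pt$r) / cond$eps_in
  kcal_to_kbt(e_kcal, cond$temperature_celsius)
}
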