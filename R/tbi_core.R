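# Core of the tightly bound ion model: the per-phosphate cells of the
# tightly bound layer, discrete Mg2+ binding modes, Monte-Carlo position
# averaging of each mode's free energy, and the partition-function assembly
# of the total free energy and its components.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the tightly bound region and its per-phosphate cells
#'
#' The tightly bound region is a thin layer around the RNA surface: all
#' points whose distance beyond the molecular surface lies between the Mg2+
#' contact distance (hydrated Mg radius) and that distance plus `t_shell`.
#' The layer is partitioned into one cell per phosphate by nearest-phosphate
#' assignment, on a grid of the configured spacing; cell volumes are node
#' counts times the voxel volume. Deterministic for fixed inputs.
#'
#' @param s an [rna_structure()].
#' @param cond a [solution_condition()] (the region itself only depends on
#'   geometry; kept in the signature for interface symmetry).
#' @param config a [tbi_config()].
#' @return an object of class `tb_region`: `cells` (list of node-coordinate
#'   matrices), `volumes` (A^3), `h`, `n_cells`, `r_contact`, `t_shell`.
#' @export
build_tb_region <- function(s, cond = solution_condition(), config = tbi_config()) {
  config <- as_tbi_config(config)
  if (nrow(s$phosphates) < 1)
    tbion_error("structure has no phosphates", "tbion_bad_argument")
  h <- config$spacing
  r_contact <- config$ion_radius[["Mg"]]
  reach <- r_contact + config$t_shell + 2 * h
  grid <- make_grid(atoms_xyzr(s), h, reach)
  dmin <- cpp_surface_distance(atoms_xyzr(s), grid$origin, h, grid$dims, reach)
  shell <- which(dmin >= r_contact & dmin <= r_contact + config$t_shell)
  pts <- node_coords(grid, shell)
  P <- as.matrix(s$phosphates[, c("x", "y", "z")])
  best <- rep(1L, nrow(pts)); bestd <- rep(Inf, nrow(pts))
  for (p in seq_len(nrow(P))) {
    d2 <- (pts[, 1] - P[p, 1])^2 + (pts[, 2] - P[p, 2])^2 +
          (pts[, 3] - P[p, 3])^2
    upd <- d2 < bestd
    best[upd] <- p; bestd[upd] <- d2[upd]
  }
  cells <- lapply(seq_len(nrow(P)), function(p) pts[best == p, , drop = FALSE])
  volumes <- vapply(cells, nrow, integer(1)) * h^3
  structure(list(cells = cells, volumes = volumes, h = h,
                 n_cells = nrow(P), r_contact = r_contact,
                 t_shell = config$t_shell),
            class = "tb_region")
}

#' @export
print.tb_region <- function(x, ...) {
  cat(sprintf("Tightly bound region: %d cells, shell %.1f A beyond contact (%.1f A)\n",
              x$n_cells, x$t_shell, x$r_contact))
  cat(sprintf("  cell volumes: %.0f .. %.0f A^3 (%d empty)\n",
              min(x$volumes), max(x$volumes), sum(x$volumes == 0)))
  invisible(x)
}

mode_key <- function(mode) paste0("m", paste(which(mode == 1L), collapse = ","))

#' Enumerate discrete ion binding modes
#'
#' All distinct assignments of at most one Mg2+ per cell with at most
#' `max_bound` ions in total: `sum_k C(N, k)` modes. Cells of zero volume
#' (fully buried phosphates) cannot hold an ion and are left unoccupied.
#'
#' @param region a `tb_region`.
#' @param max_bound maximum number of simultaneously bound ions.
#' @param cap combinatorial guard: if the mode count exceeds `cap`, a
#'   `tbion_mode_overflow` error signals that [sample_modes()] must be used.
#' @return list of 0/1 integer vectors of length `n_cells`.
#' @export
enumerate_modes <- function(region, max_bound, cap = 20000) {
  N <- region$n_cells
  if (max_bound > N)
    tbion_error("max_bound exceeds the number of cells", "tbion_bad_argument")
  occ <- which(region$volumes > 0)
  kmax <- min(max_bound, length(occ))
  total <- sum(choose(length(occ), 0:kmax))
  if (total > cap)
    tbion_error(sprintf("%d modes exceeds the enumeration cap (%d); use sample_modes()",
                        total, cap),
                "tbion_mode_overflow", n_modes = total)
  out <- list(integer(N))
  for (k in seq_len(kmax)) {
    cmb <- combn(occ, k)
    for (cc in seq_len(ncol(cmb))) {
      m <- integer(N); m[cmb[, cc]] <- 1L
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Sample ion binding modes guided by single-site energies
#'
#' Reproducible, seeded generation of a set of distinct binding modes biased
#' toward cells with low single-ion energies. The empty mode and every
#' single-ion mode are always included; multi-ion modes are built up by
#' extending the lowest-(estimated)-energy modes with the best-ranked cells,
#' plus a seeded random remainder for diversity. If the budget covers the
#' full mode count, enumeration is returned instead.
#'
#' @param region a `tb_region`.
#' @param site_energies per-cell single-ion mode free energies (kBT); `NA`
#'   marks unoccupiable cells. Used only for ranking.
#' @param budget maximum number of modes to return (>= 1).
#' @param seed integer seed for the random remainder.
#' @param max_bound cap on ions per mode (default: number of occupiable
#'   cells).
#' @return list of 0/1 integer vectors.
#' @export
sample_modes <- function(region, site_energies, budget, seed = 1,
                         max_bound = NULL) {
  if (budget < 1) tbion_error("budget must be >= 1", "tbion_bad_argument")
  N <- region$n_cells
  occ <- which(region$volumes > 0 & !is.na(site_energies))
  if (is.null(max_bound)) max_bound <- length(occ)
  max_bound <- min(max_bound, length(occ))
  total <- sum(choose(length(occ), 0:max_bound))
  if (budget >= total)
    return(enumerate_modes(region, max_bound, cap = Inf))

  ranked <- occ[order(site_energies[occ])]
  modes <- list(integer(N))
  for (p in occ) { m <- integer(N); m[p] <- 1L; modes[[length(modes) + 1L]] <- m }
  seen <- new.env(parent = emptyenv())
  for (m in modes) assign(mode_key(m), TRUE, envir = seen)
  est <- function(m) sum(site_energies[m == 1L])

  with_seed(seed, {
    frontier <- modes[-1]
    k <- 1L
    while (length(modes) < budget && k < max_bound && length(frontier)) {
      frontier <- frontier[order(vapply(frontier, est, numeric(1)))]
      frontier <- frontier[seq_len(min(length(frontier), 25L))]
      nxt <- list()
      for (m in frontier) {
        for (p in ranked) {
          if (m[p] == 1L) next
          m2 <- m; m2[p] <- 1L
          key <- mode_key(m2)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- m2
            modes[[length(modes) + 1L]] <- m2
            if (length(modes) >= budget) break
          }
        }
        if (length(modes) >= budget) break
      }
      frontier <- nxt
      k <- k + 1L
    }
    # seeded random diversity within any remaining budget
    tries <- 0L
    while (length(modes) < budget && tries < 50L * budget) {
      k <- sample.int(max_bound, 1)
      m <- integer(N); m[sample(occ, k)] <- 1L
      key <- mode_key(m)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        modes[[length(modes) + 1L]] <- m
      }
      tries <- tries + 1L
    }
  })
  modes
}

# Shared evaluation context: Born solute nodes, the phosphate-only charge
# configuration, the empty-mode PB result, and a cache of PB evaluations
# keyed by bound-ion positions.
tbi_context <- function(s, cond, config) {
  config <- as_tbi_config(config)
  ctx <- born_context(s, config)
  cfg0 <- charge_config(s, NULL, config, ctx = ctx)
  env <- new.env(parent = emptyenv())
  list(s = s, cond = cond, config = config, born = ctx, cfg0 = cfg0,
       cache = env)
}

context_diffusive <- function(context, ions = NULL) {
  cond <- context$cond; config <- context$config
  if (!config$include_diffusive ||
      (cond$c_na == 0 && cond$c_mg == 0))
    return(list(du_d = 0, ts_d = 0, excess = c(Na = 0, Mg = 0, Cl = 0)))
  key <- if (is.null(ions)) "empty"
         else paste(round(as.numeric(t(as.matrix(ions[, c("x", "y", "z")]))), 3),
                    collapse = ",")
  hit <- context$cache[[key]]
  if (!is.null(hit)) return(hit)
  field <- solve_nlpb(context$s, ions, cond, config)
  d <- diffusive_free_energy(field)
  out <- list(du_d = d$du_d, ts_d = d$ts_d, excess = d$excess)
  assign(key, out, envir = context$cache)
  out
}

ion_charge_config <- function(context, ions) {
  cfg0 <- context$cfg0
  if (is.null(ions) || !NROW(ions)) return(cfg0)
  a <- ions$radius
  B <- born_radii_points(context$born, as.matrix(ions[, c("x", "y", "z")]), a)
  rbind(cfg0, data.frame(x = ions$x, y = ions$y, z = ions$z, q = ions$q,
                         B = as.numeric(B), B0 = a, kind = "bound_ion",
                         stringsAsFactors = FALSE))
}

#' Position-averaged free energy of one binding mode
#'
#' For a mode with bound ions, the ions are placed uniformly at random
#' inside their cells `n_samples` times; each placement is scored with the
#' Generalized Born terms ([u_self()], [u_pol()], [u_ele()]) plus the
#' diffusive-ion terms from a nonlinear PB solve with the ions as fixed
#' charges. The mode free energy uses the exponential (partition-function)
#' average together with the fugacity prefactor: each bound ion contributes
#' a factor of bulk Mg2+ number density times its cell-volume integral of
#' `exp(-dG/kBT)`, making the mode weight dimensionless:
#' `dG_M = -ln( c0_Mg v_cell <exp(-E)> ... ) ` in kBT. The reported energy
#' components are the correspondingly Boltzmann-weighted placement averages.
#' The empty mode reduces to a single evaluation of the bare RNA.
#'
#' @param s an [rna_structure()].
#' @param region a `tb_region`.
#' @param mode 0/1 integer vector over cells.
#' @param cond a [solution_condition()].
#' @param n_samples placements to average (default from config).
#' @param seed integer seed controlling the placements (bit-reproducible).
#' @param config a [tbi_config()].
#' @param context optional shared context from repeated calls (built
#'   internally when `NULL`).
#' @return an object of class `mode_evaluation`: `mode`, `n_bound`, `dG_M`
#'   (kBT), `comps` (u_self, u_pol, u_ele, du_d, ts_d averages, kBT),
#'   `prefactor`, `excess` (diffusive excess ion counts), `n_samples`.
#' @export
mode_free_energy <- function(s, region, mode, cond = solution_condition(),
                             n_samples = NULL, seed = 1,
                             config = tbi_config(), context = NULL) {
  config <- as_tbi_config(config)
  if (is.null(n_samples)) n_samples <- config$n_samples
  if (is.null(context)) context <- tbi_context(s, cond, config)
  nb <- sum(mode == 1L)
  if (length(mode) != region$n_cells)
    tbion_error("mode length does not match region cells", "tbion_bad_argument")

  if (nb == 0L) {
    cfg0 <- context$cfg0
    d <- context_diffusive(context, NULL)
    comps <- c(u_self = u_self(cfg0, cond), u_pol = u_pol(cfg0, cond),
               u_ele = u_ele(cfg0, cond), du_d = d$du_d, ts_d = d$ts_d)
    return(structure(list(mode = as.integer(mode), n_bound = 0L,
                          dG_M = unname(sum(comps[1:4]) - comps[5]),
                          comps = comps,
                          prefactor = 0, excess = d$excess,
                          n_samples = 1L),
                     class = "mode_evaluation"))
  }
  cells_occ <- which(mode == 1L)
  if (any(region$volumes[cells_occ] <= 0))
    tbion_error("mode occupies an empty cell", "tbion_bad_argument")
  if (cond$c_mg <= 0)
    return(structure(list(mode = as.integer(mode), n_bound = nb, dG_M = Inf,
                          comps = c(u_self = NA, u_pol = NA, u_ele = NA,
                                    du_d = NA, ts_d = NA),
                          prefactor = Inf,
                          excess = c(Na = 0, Mg = 0, Cl = 0),
                          n_samples = 0L),
                     class = "mode_evaluation"))

  h <- region$h
  r_mg <- config$ion_radius[["Mg"]]
  E <- numeric(0)
  comp_list <- list()
  exc_list <- list()
  with_seed(seed, {
    for (sidx in seq_len(n_samples)) {
      pos <- t(vapply(cells_occ, function(p) {
        nodes <- region$cells[[p]]
        i <- sample.int(nrow(nodes), 1)
        nodes[i, ] + runif(3, -h / 2, h / 2)
      }, numeric(3)))
      ions <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         q = 2, radius = r_mg)
      ok <- TRUE
      d <- tryCatch(context_diffusive(context, ions),
                    tbion_pb_convergence = function(e) { ok <<- FALSE; NULL })
      if (!ok) { warning("PB failed for a placement; excluded"); next }
      cfg <- ion_charge_config(context, ions)
      cm <- c(u_self = u_self(cfg, cond), u_pol = u_pol(cfg, cond),
              u_ele = u_ele(cfg, cond), du_d = d$du_d, ts_d = d$ts_d)
      E <- c(E, sum(cm[1:4]) - cm[5])
      comp_list[[length(comp_list) + 1L]] <- cm
      exc_list[[length(exc_list) + 1L]] <- d$excess
    }
  })
  if (!length(E))
    tbion_error("all placements failed for this mode", "tbion_mode_failure")
  Emin <- min(E)
  w <- exp(-(E - Emin))
  dG_pos <- Emin - log(mean(w))
  c0 <- cond$c_mg * MOLAR_TO_A3
  prefactor <- -sum(log(c0 * region$volumes[cells_occ]))
  wn <- w / sum(w)
  comps <- Reduce(`+`, Map(`*`, comp_list, wn))
  excess <- Reduce(`+`, Map(`*`, exc_list, wn))
  structure(list(mode = as.integer(mode), n_bound = nb,
                 dG_M = dG_pos + prefactor, comps = comps,
                 prefactor = prefactor, excess = excess,
                 n_samples = length(E)),
            class = "mode_evaluation")
}

#' Assemble the total free energy from mode evaluations
#'
#' Log-sum-exp over the mode weights:
#' `dG_tot = -kBT ln sum_M exp(-dG_M/kBT)`; mode probabilities
#' `P_M = exp(-(dG_M - dG_tot)/kBT)` sum to one by construction. The
#' probability-weighted component sums are reported as the Coulomb
#' (`dE_ele`), polarization (`dG_pol`) and self (`dG_self`) free energies;
#' the entropic component is the remainder
#' `dG_s = dG_tot - (dE_ele + dG_pol + dG_self)` and contains the diffusive
#' ion terms and the combinatorial/positional entropy of the tightly bound
#' ions.
#'
#' @param evaluations list of `mode_evaluation` objects including the empty
#'   mode.
#' @param cond a [solution_condition()].
#' @return an object of class `tbi_result`: `dG_tot` (kBT), `components`
#'   (dE_ele, dG_pol, dG_self, dG_s in kBT), `P` (mode probabilities),
#'   `evaluations`, `cond`.
#' @export
total_free_energy <- function(evaluations, cond) {
  if (!length(evaluations))
    tbion_error("no mode evaluations", "tbion_bad_argument")
  nb <- vapply(evaluations, function(e) e$n_bound, integer(1))
  if (!any(nb == 0L))
    tbion_error("the empty mode must be among the evaluations",
                "tbion_bad_argument")
  g <- vapply(evaluations, function(e) e$dG_M, numeric(1))
  if (all(!is.finite(g)))
    tbion_error("no finite mode free energies", "tbion_bad_argument")
  m <- min(g[is.finite(g)])
  w <- exp(-(g - m)); w[!is.finite(g)] <- 0
  dG_tot <- m - log(sum(w))
  P <- w / sum(w)
  comp <- function(name) {
    v <- vapply(evaluations, function(e) e$comps[[name]], numeric(1))
    sum(ifelse(P > 0, v * P, 0), na.rm = TRUE)
  }
  dE_ele <- comp("u_ele"); dG_pol <- comp("u_pol"); dG_self <- comp("u_self")
  components <- c(dE_ele = dE_ele, dG_pol = dG_pol, dG_self = dG_self,
                  dG_s = dG_tot - (dE_ele + dG_pol + dG_self))
  structure(list(dG_tot = dG_tot, components = components, P = P,
                 evaluations = evaluations, cond = cond, units = "kBT"),
            class = "tbi_result")
}

#' @export
print.tbi_result <- function(x, ...) {
  tc <- x$cond$temperature_celsius
  cat(sprintf("TBI result (%d modes): dG_tot = %.3f kBT = %.3f kcal/mol\n",
              length(x$evaluations), x$dG_tot, kbt_to_kcal(x$dG_tot, tc)))
  cn <- c("dE_ele", "dG_pol", "dG_self", "dG_s")
  for (nm in cn)
    cat(sprintf("  %-8s %10.3f kBT  (%8.3f kcal/mol)\n", nm,
                x$components[[nm]], kbt_to_kcal(x$components[[nm]], tc)))
  invisible(x)
}
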