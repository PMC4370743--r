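# End-user pipelines: full TBI runs on a structure, the .dat text output,
# Mg2+ concentration sweeps, folding stability (thermodynamic cycle) and
# ion uptake.

#' Reference Mg2+ concentration grid
#'
#' The default grid for stability/uptake sweeps: 0 to 10 mM.
#' @export
tbi_mg_grid <- c(0, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2)

auto_max_bound <- function(N, config) {
  if (!is.null(config$max_bound)) return(min(config$max_bound, N))
  min(N, ceiling(N / 2) + 2) # up to full charge neutralization and change
}

#' Run the full TBI calculation on one structure
#'
#' Orchestrates the pipeline: build the tightly bound region, choose the
#' mode set (full enumeration when it fits the budget, guided sampling
#' otherwise), Monte-Carlo average each mode's free energy, assemble the
#' total free energy and components, and compute the binding profile. With
#' no Mg2+ the calculation reduces to a single nonlinear PB evaluation of
#' the bare RNA in the monovalent atmosphere.
#'
#' @param s an [rna_structure()].
#' @param cond a [solution_condition()].
#' @param config a [tbi_config()].
#' @param seed integer seed controlling mode sampling and ion placements.
#' @param out_prefix if non-NULL, writes `<prefix>.dat` and `<prefix>.csv`.
#' @return an object of class `tbi_run`: `result` ([total_free_energy()]
#'   output), `profile` ([binding_fractions()] output), `region`, `cond`.
#' @examples
#' \donttest{
#' h <- generate_aform_helix(3)
#' cfg <- tbi_config(spacing = 1.4, pad_fine = 6, tol = 1e-5)
#' run <- run_tbi(h, solution_condition(37, na = 0.1, mg = 0), cfg)
#' run$result$dG_tot
#' }
#' @export
run_tbi <- function(s, cond = solution_condition(), config = tbi_config(),
                    seed = 1, out_prefix = NULL) {
  config <- as_tbi_config(config)
  region <- build_tb_region(s, cond, config)
  context <- tbi_context(s, cond, config)
  N <- region$n_cells

  empty <- mode_free_energy(s, region, integer(N), cond,
                            config = config, context = context, seed = seed)
  evals <- list(empty)
  if (cond$c_mg > 0) {
    occ <- which(region$volumes > 0)
    singles <- lapply(occ, function(p) { m <- integer(N); m[p] <- 1L; m })
    single_evals <- lapply(seq_along(singles), function(i)
      mode_free_energy(s, region, singles[[i]], cond, config = config,
                       context = context, seed = seed + i))
    site_dG <- rep(NA_real_, N)
    site_dG[occ] <- vapply(single_evals, function(e) e$dG_M, numeric(1))

    mb <- auto_max_bound(N, config)
    total <- sum(choose(length(occ), 0:min(mb, length(occ))))
    modes <- if (total <= config$mode_budget)
      enumerate_modes(region, mb, cap = config$enumeration_cap)
    else
      sample_modes(region, site_dG, config$mode_budget, seed = seed,
                   max_bound = mb)
    # singles and the empty mode are already evaluated
    done <- c(mode_key(integer(N)), vapply(singles, mode_key, character(1)))
    todo <- Filter(function(m) !(mode_key(m) %in% done), modes)
    more <- lapply(seq_along(todo), function(i)
      mode_free_energy(s, region, todo[[i]], cond, config = config,
                       context = context, seed = seed + N + i))
    evals <- c(list(empty), single_evals, more)
  }
  result <- total_free_energy(evals, cond)
  profile <- binding_fractions(result, s)
  run <- structure(list(result = result, profile = profile, region = region,
                        cond = cond, config = config, structure = s),
                   class = "tbi_run")
  if (!is.null(out_prefix)) {
    write_dat(run, paste0(out_prefix, ".dat"))
    write_dat_csv(run, paste0(out_prefix, ".csv"))
  }
  run
}

#' @export
print.tbi_run <- function(x, ...) {
  print(x$cond)
  print(x$result)
  print(x$profile)
  invisible(x)
}

#' Write the TBI result text file
#'
#' Plain-text report mirroring the classic server output: a header with the
#' solution condition, one row per nucleotide (index, residue, mean Mg2+
#' binding fraction, mean Na+ fraction, most-probable-mode occupancy 0/1),
#' then the totals block with `dG_tot`, `dG_self`, `dG_pol`, `dE_ele`,
#' `dG_s`. Energies are in kBT by default; `units = "kcal"` converts.
#'
#' @param run a `tbi_run` from [run_tbi()].
#' @param path output file.
#' @param units `"kBT"` (default) or `"kcal"`.
#' @return the path, invisibly.
#' @export
write_dat <- function(run, path, units = c("kBT", "kcal")) {
  units <- match.arg(units)
  cond <- run$cond
  conv <- if (units == "kcal")
    function(x) kbt_to_kcal(x, cond$temperature_celsius) else identity
  res <- run$result; prof <- run$profile
  s <- run$structure
  mp <- numeric(s$n_nucleotides)
  mp[s$phosphates$nt] <- prof$most_probable_mode
  lines <- c(
    "# TBI electrostatics result",
    sprintf("# [Na+] = %.6g M   [Mg2+] = %.6g M   T = %.2f C", cond$c_na,
            cond$c_mg, cond$temperature_celsius),
    sprintf("# energies in %s", if (units == "kBT") "kB*T" else "kcal/mol"),
    "#   nt  res      f_Mg        f_Na   mode",
    sprintf("%6d  %3s  %10.6f  %10.6f  %3d",
            seq_len(s$n_nucleotides), s$resnames, prof$f_mg_per_nt,
            rep(prof$f_na, s$n_nucleotides), as.integer(mp)),
    sprintf("# dG_tot  = %14.6f", conv(res$dG_tot)),
    sprintf("# dG_self = %14.6f", conv(res$components[["dG_self"]])),
    sprintf("# dG_pol  = %14.6f", conv(res$components[["dG_pol"]])),
    sprintf("# dE_ele  = %14.6f", conv(res$components[["dE_ele"]])),
    sprintf("# dG_s    = %14.6f", conv(res$components[["dG_s"]]))
  )
  writeLines(lines, path)
  invisible(path)
}

write_dat_csv <- function(run, path) {
  prof <- run$profile; s <- run$structure
  mp <- numeric(s$n_nucleotides)
  mp[s$phosphates$nt] <- prof$most_probable_mode
  df <- data.frame(nt = seq_len(s$n_nucleotides), res = s$resnames,
                   f_mg = prof$f_mg_per_nt, f_na = prof$f_na,
                   mode = as.integer(mp))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a TBI result text file back
#'
#' @param path a file written by [write_dat()].
#' @return list with `conditions` (na, mg, temperature), `table`
#'   (per-nucleotide data.frame) and `totals` (named energies).
#' @export
read_dat <- function(path) {
  lines <- readLines(path)
  cl <- grep("^# \\[Na\\+\\]", lines, value = TRUE)
  toks <- regmatches(cl, gregexpr("[0-9.eE+-]+", cl))[[1]]
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[!is.na(nums)]  # drops the ion-name charge signs
  conditions <- c(na = nums[1], mg = nums[2], temperature = nums[3])
  rows <- grep("^[ ]*[0-9]", lines, value = TRUE)
  tab <- utils::read.table(text = rows,
                           col.names = c("nt", "res", "f_mg", "f_na", "mode"),
                           stringsAsFactors = FALSE)
  tl <- grep("^# d[GE]", lines, value = TRUE)
  totals <- vapply(tl, function(l) as.numeric(sub(".*= *", "", l)), numeric(1))
  names(totals) <- sub("^# *([A-Za-z_]+) .*", "\\1", tl)
  list(conditions = conditions, table = tab, totals = totals)
}

#' Scale a helix free energy to an intermediate of different length
#'
#' Per-nucleotide proportional scaling used to approximate the hairpin
#' intermediate by an effective helix:
#' `dG_I = dG_helix * n_I / n_helix`.
#'
#' @param dG_helix helix electrostatic free energy (any unit).
#' @param n_I number of nucleotides of the intermediate.
#' @param n_helix number of nucleotides of the helix proxy.
#' @return the scaled free energy.
#' @examples
#' scale_intermediate(30.30, 36, 24) # 45.45
#' @export
scale_intermediate <- function(dG_helix, n_I, n_helix) {
  if (n_helix < 1 || n_I < 1)
    tbion_error("lengths must be positive", "tbion_bad_argument")
  dG_helix * n_I / n_helix
}

#' Mg2+-induced folding stability from the thermodynamic cycle
#'
#' Double free-energy difference between the folded (F) and intermediate (I)
#' states, with and without Mg2+:
#' `ddG_Mg = [dG_F(c) - dG_F(0)] - [dG_I(c) - dG_I(0)]` at each Mg2+
#' concentration of the shared grid. Zero at c = 0 by construction.
#'
#' @param c_mg Mg2+ concentration grid (mol/L); must include 0.
#' @param dG_F folded-state free energies on that grid.
#' @param dG_I intermediate-state free energies on that grid.
#' @return data.frame with class `stability_result`: `c_mg`, `dG_F`, `dG_I`,
#'   `ddG_mg` (same units as the inputs).
#' @examples
#' folding_stability(c(0, 0.01), c(59.52, 47.28), c(45.45, 39.82))
#' @export
folding_stability <- function(c_mg, dG_F, dG_I) {
  if (length(dG_F) != length(c_mg) || length(dG_I) != length(c_mg))
    tbion_error("curves must share the concentration grid", "tbion_bad_argument")
  i0 <- which(c_mg == 0)
  if (!length(i0))
    tbion_error("the zero-Mg2+ reference point is required", "tbion_bad_argument")
  i0 <- i0[1]
  ddG <- (dG_F - dG_F[i0]) - (dG_I - dG_I[i0])
  structure(data.frame(c_mg = c_mg, dG_F = dG_F, dG_I = dG_I, ddG_mg = ddG),
            class = c("stability_result", "data.frame"))
}

#' Mg2+ uptake from folded/intermediate binding fractions
#'
#' Per-nucleotide ion uptake upon folding: the difference of the mean Mg2+
#' binding fractions of the folded and intermediate states at each
#' concentration.
#'
#' @param c_mg Mg2+ concentration grid (mol/L).
#' @param f_F folded-state binding fraction per nucleotide on that grid.
#' @param f_I intermediate-state binding fraction on the same grid.
#' @return data.frame with class `uptake_result`: `c_mg`, `f_F`, `f_I`,
#'   `uptake`.
#' @examples
#' ion_uptake(c(0, 0.005), c(0, 0.211), c(0, 0.177))
#' @export
ion_uptake <- function(c_mg, f_F, f_I) {
  if (length(f_F) != length(c_mg) || length(f_I) != length(c_mg))
    tbion_error("curves must share the concentration grid", "tbion_bad_argument")
  structure(data.frame(c_mg = c_mg, f_F = f_F, f_I = f_I,
                       uptake = f_F - f_I),
            class = c("uptake_result", "data.frame"))
}

#' Sweep a structure over a Mg2+ concentration grid
#'
#' Runs [run_tbi()] at each Mg2+ concentration (fixed Na+ and temperature)
#' and collects the total free energy and mean binding fractions — the raw
#' material for [folding_stability()] and [ion_uptake()].
#'
#' @param s an [rna_structure()].
#' @param c_mg Mg2+ concentrations, mol/L (default [tbi_mg_grid]).
#' @param na Na+ concentration, mol/L.
#' @param temperature_celsius temperature.
#' @param config a [tbi_config()].
#' @param seed integer seed.
#' @return data.frame: `c_mg`, `dG_kbt`, `dG_kcal`, `f_mg` (mean per
#'   nucleotide), `f_na`, `mean_bound`.
#' @export
run_mg_sweep <- function(s, c_mg = tbi_mg_grid, na = 0.1,
                         temperature_celsius = 37, config = tbi_config(),
                         seed = 1) {
  # one seed for the whole sweep: common random numbers keep the sampled
  # mode set and ion placements identical across concentrations, so the
  # monotone fugacity dependence is not masked by sampling noise
  rows <- lapply(seq_along(c_mg), function(i) {
    cond <- solution_condition(temperature_celsius, na = na, mg = c_mg[i])
    run <- run_tbi(s, cond, config, seed = seed)
    data.frame(c_mg = c_mg[i], dG_kbt = run$result$dG_tot,
               dG_kcal = kbt_to_kcal(run$result$dG_tot, temperature_celsius),
               f_mg = mean(run$profile$f_mg_per_nt),
               f_na = run$profile$f_na,
               mean_bound = run$profile$mean_bound)
  })
  do.call(rbind, rows)
}
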