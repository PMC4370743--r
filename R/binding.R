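# Per-nucleotide ion binding fractions and the most probable binding mode.

#' Per-nucleotide ion binding fractions
#'
#' Combines the tightly bound and diffusive contributions:
#' the tightly bound fraction on nucleotide i is the probability-weighted
#' occupancy `fbar_b(i) = sum_M N_b(i) P_M`; the Mg2+ fraction adds the
#' diffusive excess shared uniformly over nucleotides,
#' `f_Mg(i) = fbar_b(i) + (1/N) integral (c_Mg - c0_Mg) dV`; the Na+
#' fraction is purely diffusive, `f_Na = (1/N) integral (c_Na - c0_Na) dV`.
#' The diffusive-excess integrals are evaluated per mode (from each mode's
#' PB fields) and probability-averaged.
#'
#' @param result a `tbi_result` from [total_free_energy()] (its evaluations
#'   carry the per-mode diffusive excess integrals).
#' @param s the [rna_structure()] the evaluations refer to.
#' @return an object of class `binding_profile`: `f_mg_per_nt`, `f_na`,
#'   `fbar_b_per_nt`, `most_probable_mode`, `mean_bound` (mean tightly
#'   bound ion count).
#' @export
binding_fractions <- function(result, s) {
  if (!inherits(result, "tbi_result"))
    tbion_error("need a tbi_result", "tbion_bad_argument")
  P <- result$P
  if (abs(sum(P) - 1) > 1e-8)
    tbion_error("mode probabilities are not normalized", "tbion_bad_argument")
  evals <- result$evaluations
  N <- s$n_nucleotides
  ncell <- length(evals[[1]]$mode)
  fbar_cells <- Reduce(`+`, Map(function(e, p) e$mode * p, evals, P))
  # cells are in phosphate order; map onto nucleotide indices
  fbar <- numeric(N)
  fbar[s$phosphates$nt] <- fbar_cells
  exc <- function(name) {
    v <- vapply(evals, function(e) {
      x <- e$excess[name]
      if (is.null(x) || is.na(x)) 0 else as.numeric(x)
    }, numeric(1))
    sum(v * P)
  }
  mg_diff <- exc("Mg") / N
  f_na <- exc("Na") / N
  f_mg <- fbar + mg_diff
  structure(list(f_mg_per_nt = f_mg, f_na = f_na, fbar_b_per_nt = fbar,
                 most_probable_mode = most_probable_mode(evals),
                 mean_bound = sum(fbar_cells)),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("Binding profile: mean tightly bound Mg2+ = %.3f ions\n",
              x$mean_bound))
  cat(sprintf("  mean f_Mg per nt = %.4f, f_Na = %.4f\n",
              mean(x$f_mg_per_nt), x$f_na))
  cat(sprintf("  most probable mode: %d bound (%s)\n",
              sum(x$most_probable_mode),
              if (sum(x$most_probable_mode)) paste(which(x$most_probable_mode == 1L),
                                                   collapse = ",") else "-"))
  invisible(x)
}

#' Most probable binding mode
#'
#' The evaluated mode with the lowest mode free energy `dG_M`. Ties are
#' broken in favour of fewer bound ions, then lexicographic cell order.
#'
#' @param evaluations list of `mode_evaluation` objects (or a `tbi_result`).
#' @return the winning 0/1 mode vector.
#' @export
most_probable_mode <- function(evaluations) {
  if (inherits(evaluations, "tbi_result")) evaluations <- evaluations$evaluations
  if (!length(evaluations))
    tbion_error("no evaluations", "tbion_bad_argument")
  g <- vapply(evaluations, function(e) e$dG_M, numeric(1))
  nb <- vapply(evaluations, function(e) e$n_bound, integer(1))
  keys <- vapply(evaluations, function(e) mode_key(e$mode), character(1))
  ord <- order(g, nb, keys)
  evaluations[[ord[1]]]$mode
}
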