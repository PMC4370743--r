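test_that("tightly bound region forms per-phosphate shell cells", {
  cfg <- tbi_config(spacing = 0.6)
  # single isolated phosphate: one cell whose volume is the spherical shell
  # between contact (atom + hydrated Mg) and contact + t_shell
  s <- sphere_structure(atom_radius = 2)
  reg <- build_tb_region(s, solution_condition(), cfg)
  expect_equal(reg$n_cells, 1)
  r0 <- 2 + 4.5; r1 <- r0 + 3
  v_shell <- 4 / 3 * pi * (r1^3 - r0^3)
  expect_equal(reg$volumes, v_shell, tolerance = 0.05)

  # two far-separated phosphates: two cells of equal volume (symmetry)
  s2 <- two_phos_structure(d = 40)
  reg2 <- build_tb_region(s2, solution_condition(), tbi_config(spacing = 1.0))
  expect_equal(reg2$n_cells, 2)
  expect_equal(reg2$volumes[1], reg2$volumes[2], tolerance = 1e-9)

  # helix: one cell per phosphate, all with positive volume
  reg3 <- build_tb_region(generate_aform_helix(12), solution_condition(),
                          tbi_config(spacing = 1.2))
  expect_equal(reg3$n_cells, 24)
  expect_true(all(reg3$volumes > 0))
})

test_that("mode enumeration is exhaustive with at most one ion per cell", {
  reg <- build_tb_region(two_phos_structure(d = 20), solution_condition(),
                         tbi_config(spacing = 1.5))
  m2 <- enumerate_modes(reg, 2)
  expect_length(m2, 4)
  keys <- sort(vapply(m2, function(m) paste(m, collapse = ""), character(1)))
  expect_equal(keys, c("00", "01", "10", "11"))
  expect_length(enumerate_modes(reg, 0), 1)

  # binomial count: N = 4, up to 2 ions -> 1 + 4 + 6 = 11
  s4 <- rna_structure(
    atoms = data.frame(element = "P", elety = "P", nt = 1:4,
                       x = c(0, 20, 40, 60), y = 0, z = 0, radius = 2,
                       stringsAsFactors = FALSE),
    phosphates = data.frame(nt = 1:4, x = c(0, 20, 40, 60), y = 0, z = 0,
                            charge = -1, radius = 2),
    resnames = rep("G", 4), source = "toy")
  reg4 <- build_tb_region(s4, solution_condition(), tbi_config(spacing = 1.5))
  expect_length(enumerate_modes(reg4, 2), 1 + 4 + 6)

  expect_error(enumerate_modes(reg4, 4, cap = 10),
               class = "tbion_mode_overflow")
})

test_that("guided mode sampling is reproducible and keeps key modes", {
  s6 <- rna_structure(
    atoms = data.frame(element = "P", elety = "P", nt = 1:6,
                       x = 20 * (0:5), y = 0, z = 0, radius = 2,
                       stringsAsFactors = FALSE),
    phosphates = data.frame(nt = 1:6, x = 20 * (0:5), y = 0, z = 0,
                            charge = -1, radius = 2),
    resnames = rep("G", 6), source = "toy")
  reg <- build_tb_region(s6, solution_condition(), tbi_config(spacing = 1.5))
  site <- c(2, 1, -50, 3, 2.5, 1.5)   # cell 3 deeply favourable

  sm <- sample_modes(reg, site, budget = 20, seed = 5)
  sm_again <- sample_modes(reg, site, budget = 20, seed = 5)
  expect_identical(sm, sm_again)
  expect_lte(length(sm), 20)

  keys <- vapply(sm, mode_key, character(1))
  expect_true(mode_key(integer(6)) %in% keys)              # empty mode
  for (p in 1:6) {                                          # all singles
    m <- integer(6); m[p] <- 1L
    expect_true(mode_key(m) %in% keys)
  }
  # the favourable cell appears in sampled multi-ion modes
  multi <- sm[vapply(sm, sum, integer(1)) > 1]
  expect_true(length(multi) > 0)
  expect_true(any(vapply(multi, function(m) m[3] == 1L, logical(1))))

  # budget >= total mode count falls back to full enumeration
  all_modes <- sample_modes(reg, site, budget = 1000, seed = 5)
  expect_length(all_modes, 2^6)
})

test_that("mode free energies reduce and reproduce as specified", {
  s <- two_phos_structure(d = 8)
  cond <- solution_condition(37, na = 0.1, mg = 0.005)
  cfg <- tbi_config(spacing = 1.2, born_spacing = 0.5,
                    include_diffusive = FALSE)
  reg <- build_tb_region(s, cond, cfg)

  # empty mode: a single evaluation of the bare RNA, no averaging
  e0 <- mode_free_energy(s, reg, c(0L, 0L), cond, config = cfg)
  cfg0 <- charge_config(s, NULL, cfg)
  expect_equal(e0$dG_M, u_self(cfg0, cond) + u_pol(cfg0, cond) +
                 u_ele(cfg0, cond), tolerance = 1e-10)
  expect_equal(e0$n_bound, 0L)

  # fixed seed -> bit-reproducible
  e1a <- mode_free_energy(s, reg, c(1L, 0L), cond, n_samples = 3, seed = 42,
                          config = cfg)
  e1b <- mode_free_energy(s, reg, c(1L, 0L), cond, n_samples = 3, seed = 42,
                          config = cfg)
  expect_identical(e1a$dG_M, e1b$dG_M)
  expect_identical(e1a$comps, e1b$comps)

  # no Mg2+ in the bulk: occupied modes carry zero weight
  e_inf <- mode_free_energy(s, reg, c(1L, 0L),
                            solution_condition(37, na = 0.1, mg = 0),
                            config = cfg)
  expect_identical(e_inf$dG_M, Inf)
})

test_that("partition-function assembly obeys its closed-form identities", {
  cond <- solution_condition()
  e0 <- fake_eval(c(0L, 0L), 3.0)
  # single mode: dG_tot is that mode's free energy, P = 1
  r1 <- total_free_energy(list(e0), cond)
  expect_equal(r1$dG_tot, 3.0)
  expect_equal(r1$P, 1)

  # two modes of equal free energy: dG_tot = dG - ln 2, each P = 1/2
  r2 <- total_free_energy(list(e0, fake_eval(c(1L, 0L), 3.0)), cond)
  expect_equal(r2$dG_tot, 3.0 - log(2), tolerance = 1e-12)
  expect_equal(r2$P, c(0.5, 0.5))

  # probabilities always normalize; adding a mode never raises dG_tot;
  # dG_tot lower-bounds every mode free energy
  set.seed(11)
  evs <- list(e0)
  for (i in 1:6) {
    m <- c(1L, as.integer(i %% 2)); g <- runif(1, -2, 8)
    prev <- total_free_energy(evs, cond)$dG_tot
    evs <- c(evs, list(fake_eval(m, g)))
    cur <- total_free_energy(evs, cond)
    expect_equal(sum(cur$P), 1, tolerance = 1e-12)
    expect_lte(cur$dG_tot, prev + 1e-12)
    expect_lte(cur$dG_tot, min(vapply(evs, function(e) e$dG_M, numeric(1))))
  }

  # the entropic component is the exact remainder of the decomposition
  comp <- total_free_energy(evs, cond)
  expect_equal(comp$components[["dG_s"]],
               comp$dG_tot - sum(comp$components[c("dE_ele", "dG_pol",
                                                   "dG_self")]),
               tolerance = 1e-12)

  expect_error(total_free_energy(list(fake_eval(c(1L, 0L), 1)), cond),
               class = "tbion_bad_argument")  # empty mode required
  expect_error(total_free_energy(list(), cond), class = "tbion_bad_argument")
})

test_that("two-cell system matches a brute-force partition function", {
  # Generalized-Born-only toy (diffusive terms off) so the oracle can
  # enumerate cell nodes densely; checks the Eq-level mode weighting:
  # each bound ion contributes bulk density x cell volume integral of
  # exp(-E), and the total is the log-sum over modes
  s <- two_phos_structure(d = 8)
  cond <- solution_condition(37, na = 0.1, mg = 0.005)
  cfg <- tbi_config(spacing = 1.2, born_spacing = 0.5,
                    include_diffusive = FALSE)
  reg <- build_tb_region(s, cond, cfg)
  modes <- enumerate_modes(reg, 2)
  evals <- lapply(seq_along(modes), function(i)
    mode_free_energy(s, reg, modes[[i]], cond, n_samples = 2000,
                     seed = 100 + i, config = cfg))
  res <- total_free_energy(evals, cond)

  # independent assembly by node quadrature
  ctx <- born_context(s, cfg)
  pre <- 1 / cond$eps_w - 1 / cond$eps_in
  toKT <- function(kcal) kcal_to_kbt(kcal, 37)
  P <- as.matrix(s$phosphates[, c("x", "y", "z")])
  qp <- s$phosphates$charge
  Bp <- born_radii_points(ctx, P, s$phosphates$radius)
  B0p <- phosphate_reference_radii(s, cfg)
  fgb <- function(r, BB) sqrt(r^2 + BB * exp(-r^2 / (4 * BB)))
  rpp <- 8
  E0 <- toKT(332.0637 * (pre * sum(qp^2 / 2 * (1 / Bp - 1 / B0p)) +
        pre * qp[1] * qp[2] / fgb(rpp, Bp[1] * Bp[2]) +
        qp[1] * qp[2] / (cond$eps_in * rpp)))
  surplus <- function(nodes) {
    Bi <- born_radii_points(ctx, nodes, rep(4.5, nrow(nodes)))
    d1 <- sqrt(rowSums(sweep(nodes, 2, P[1, ])^2))
    d2 <- sqrt(rowSums(sweep(nodes, 2, P[2, ])^2))
    toKT(332.0637 * (pre * 4 / 2 * (1 / Bi - 1 / 4.5) +
         pre * (2 * qp[1] / fgb(d1, Bi * Bp[1]) +
                2 * qp[2] / fgb(d2, Bi * Bp[2])) +
         (2 * qp[1] / d1 + 2 * qp[2] / d2) / cond$eps_in))
  }
  n1 <- reg$cells[[1]]; n2 <- reg$cells[[2]]
  e1 <- surplus(n1); e2 <- surplus(n2)
  B1 <- born_radii_points(ctx, n1, rep(4.5, nrow(n1)))
  B2 <- born_radii_points(ctx, n2, rep(4.5, nrow(n2)))
  dd <- sqrt(outer(rowSums(n1^2), rowSums(n2^2), "+") - 2 * (n1 %*% t(n2)))
  ii <- toKT(332.0637 * (pre * 4 / fgb(dd, outer(B1, B2)) +
                         4 / (cond$eps_in * dd)))
  h3 <- reg$h^3; c0 <- cond$c_mg * 6.02214076e-4
  w0 <- exp(-E0)
  w1 <- c0 * h3 * sum(exp(-(E0 + e1)))
  w2 <- c0 * h3 * sum(exp(-(E0 + e2)))
  w12 <- (c0 * h3)^2 * sum(exp(-(E0 + outer(e1, e2, "+") + ii)))

  g_pkg <- vapply(evals, function(e) e$dG_M, numeric(1))
  expect_equal(g_pkg, c(E0, -log(w1), -log(w2), -log(w12)), tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(res$dG_tot, -log(w0 + w1 + w2 + w12), tolerance = 0.05)
})
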