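test_that("Born radii recover the isolated and buried sphere limits", {
  # isolated ion: no low-dielectric neighbours, B = intrinsic radius
  iso <- sphere_structure(atom_radius = 2)
  B <- born_radii(iso, config = tbi_config(born_spacing = 0.4))
  expect_equal(as.numeric(B), 2, tolerance = 0.04)

  # charge buried at the center of a large low-dielectric sphere: B -> R
  buried <- rna_structure(
    atoms = data.frame(element = "C", elety = "C1", nt = 1L,
                       x = 0, y = 0, z = 0, radius = 8,
                       stringsAsFactors = FALSE),
    phosphates = data.frame(nt = 1L, x = 0, y = 0, z = 0, charge = -1,
                            radius = 2),
    resnames = "G", source = "toy")
  B2 <- born_radii(buried, config = tbi_config(born_spacing = 0.4))
  expect_equal(as.numeric(B2), 8, tolerance = 0.02)

  # degenerate geometry: coincident charges are refused
  expect_error(born_radii(two_phos_structure(d = 0)),
               class = "tbion_bad_argument")
})

test_that("two-sphere Born radius matches a fine-grid quadrature oracle", {
  s <- rna_structure(
    atoms = data.frame(element = c("C", "C"), elety = c("C1", "C2"),
                       nt = c(1L, 1L), x = c(0, 3), y = 0, z = 0, radius = 2,
                       stringsAsFactors = FALSE),
    phosphates = data.frame(nt = 1L, x = 0, y = 0, z = 0, charge = -1,
                            radius = 2),
    resnames = "G", source = "toy")
  B_pkg <- born_radii(s, config = tbi_config(born_spacing = 0.3))

  # brute-force Coulomb-field integral at 0.08 A over the second sphere's
  # volume outside the charge's own 2 A sphere
  hh <- 0.08
  gx <- seq(-4.5, 7.5, by = hh); gy <- seq(-4.5, 4.5, by = hh)
  I <- 0
  for (z in gy) {
    g <- expand.grid(x = gx, y = gy)
    d1 <- sqrt(g$x^2 + g$y^2 + z^2)
    d2 <- sqrt((g$x - 3)^2 + g$y^2 + z^2)
    sol <- (d1 < 2 | d2 < 2) & d1 >= 2
    I <- I + sum(1 / d1[sol]^4) * hh^3
  }
  B_or <- 1 / (1 / 2 - I / (4 * pi))
  expect_equal(as.numeric(B_pkg[1]), B_or, tolerance = 0.02)
})

test_that("self energy follows the Born expressions in both references", {
  cond <- solution_condition(25, na = 0.1, mg = 0)
  cfg1 <- data.frame(x = 0, y = 0, z = 0, q = -1, B = 2, B0 = 2,
                     kind = "phosphate", stringsAsFactors = FALSE)
  # printed no-subtraction form: 1/2 (1/eps_w - 1/eps_in) q^2/B
  # = -5.86 kcal/mol for B = 2 A (the prefactor is negative)
  expect_equal(kbt_to_kcal(u_self(cfg1, cond, reference = "uniform"), 25),
               0.5 * (1 / 78.28534 - 1 / 12) * 332.0637 / 2,
               tolerance = 1e-6)
  expect_equal(abs(kbt_to_kcal(u_self(cfg1, cond, reference = "uniform"), 25)),
               5.86, tolerance = 0.005)
  # assembly reference: B = B0 for an isolated group means zero self energy
  expect_equal(u_self(cfg1, cond, reference = "isolated"), 0)

  # uniform-dielectric limit kills both self and polarization energies
  cond_u <- solution_condition(25, na = 0.1, mg = 0, eps_in = 78,
                               eps_w = 78 + 1e-9)
  cfg2 <- data.frame(x = c(0, 6), y = 0, z = 0, q = c(-1, 2),
                     B = c(2, 3), B0 = c(1.8, 4.5),
                     kind = c("phosphate", "bound_ion"),
                     stringsAsFactors = FALSE)
  expect_lt(abs(u_self(cfg2, cond_u, "uniform")), 1e-6)
  expect_lt(abs(u_self(cfg2, cond_u, "isolated")), 1e-6)
  expect_lt(abs(u_pol(cfg2, cond_u)), 1e-6)

  # quadratic charge scaling
  cfg4 <- cfg1; cfg4$q <- -2
  expect_equal(u_self(cfg4, cond, "uniform"),
               4 * u_self(cfg1, cond, "uniform"), tolerance = 1e-12)
})

test_that("polarization kernel has the printed limits and bounds", {
  cond <- solution_condition(25, na = 0.1, mg = 0)
  one <- data.frame(x = 0, y = 0, z = 0, q = -1, B = 2, B0 = 2,
                    kind = "phosphate", stringsAsFactors = FALSE)
  expect_equal(u_pol(one, cond), 0)
  expect_equal(u_ele(one, cond), 0)

  # r = 0, B_m = B_n = B: kernel collapses to 1/B
  co <- rbind(one, one)
  expect_equal(u_pol(co, cond),
               kcal_to_kbt(332.0637 * (1 / cond$eps_w - 1 / cond$eps_in) / 2,
                           25),
               tolerance = 1e-12)

  # large separation: exp factor vanishes, f_GB -> r, and the pair obeys
  # the full water-screening identity u_pol + u_ele = q q / (eps_w r)
  far <- data.frame(x = c(0, 200), y = 0, z = 0, q = c(-1, -1),
                    B = 2, B0 = 2, kind = "phosphate",
                    stringsAsFactors = FALSE)
  expect_equal(u_pol(far, cond) + u_ele(far, cond),
               kcal_to_kbt(332.0637 / (cond$eps_w * 200), 25),
               tolerance = 1e-10)

  # kernel bounds: 1/sqrt(r^2 + Bm Bn) <= 1/f_GB <= 1/r for r > 0
  set.seed(7)
  for (i in 1:50) {
    r <- runif(1, 0.5, 30); Bm <- runif(1, 1, 6); Bn <- runif(1, 1, 6)
    fgb <- sqrt(r^2 + Bm * Bn * exp(-r^2 / (4 * Bm * Bn)))
    expect_gte(1 / fgb, 1 / sqrt(r^2 + Bm * Bn))
    expect_lte(1 / fgb, 1 / r)
  }
})

test_that("Coulomb term is a plain pair sum at the interior dielectric", {
  cond <- solution_condition(25, na = 0.1, mg = 0)
  pair <- data.frame(x = c(0, 10), y = 0, z = 0, q = -1, B = 2, B0 = 2,
                     kind = "phosphate", stringsAsFactors = FALSE)
  expect_equal(kbt_to_kcal(u_ele(pair, cond), 25), 332.0637 / (12 * 10),
               tolerance = 1e-9)
  far <- pair; far$x <- c(0, 1e6)
  expect_lt(abs(u_ele(far, cond)), 1e-4)

  # three charges: sum of the three pair terms via a brute-force loop
  set.seed(3)
  tri <- data.frame(x = runif(3, 0, 10), y = runif(3, 0, 10),
                    z = runif(3, 0, 10), q = c(-1, -1, 2),
                    B = c(2, 2, 4.5), B0 = c(2, 2, 4.5),
                    kind = c("phosphate", "phosphate", "bound_ion"),
                    stringsAsFactors = FALSE)
  acc <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    r <- sqrt(sum((tri[i, 1:3] - tri[j, 1:3])^2))
    acc <- acc + tri$q[i] * tri$q[j] / r
  }
  expect_equal(kbt_to_kcal(u_ele(tri, cond), 25), 332.0637 * acc / 12,
               tolerance = 1e-9)

  # energies are permutation invariant
  perm <- tri[c(3, 1, 2), ]
  expect_equal(u_ele(perm, cond), u_ele(tri, cond), tolerance = 1e-12)
  expect_equal(u_pol(perm, cond), u_pol(tri, cond), tolerance = 1e-12)
  expect_equal(u_self(perm, cond), u_self(tri, cond), tolerance = 1e-12)

  co <- pair; co$x <- c(0, 0)
  expect_error(u_ele(co, cond), class = "tbion_bad_argument")
})
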