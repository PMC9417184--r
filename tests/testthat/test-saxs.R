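# A single-atom "scatterer" helper: hydrogen atoms give unit form factors at
# atom granularity, making the closed-form Debye checks exact.
unit_scatterers <- function(xyz) {
  xyz <- rbind(xyz)
  assembly(tibble::tibble(
    chain = "A", seq_id = seq_len(nrow(xyz)), ins = "", resname = "GLY",
    aa = "G", atom = "H", element = "H",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

test_that("Debye profile matches its closed forms", {
  q <- seq(0, 0.5, length.out = 11)
  # single scatterer: I(q) = f^2, flat
  one <- unit_scatterers(c(1, 2, 3))
  p1 <- debye_profile(one, q, granularity = "atom")
  expect_equal(p1$intensity, rep(1, length(q)))
  # one glycine residue at residue granularity: f = 30 electrons
  g1 <- assembly(atom_row("A", 1, "GLY", "CA", 0, 0, 0))
  expect_equal(debye_profile(g1, q)$intensity, rep(30^2, length(q)))
  # two unit scatterers distance d apart: I(q) = 2 (1 + sin(qd)/(qd))
  d <- 7.3
  p2 <- debye_profile(unit_scatterers(rbind(c(0, 0, 0), c(d, 0, 0))), q,
                      granularity = "atom")
  expected <- 2 * (1 + ifelse(q == 0, 1, sin(q * d) / (q * d)))
  expect_equal(p2$intensity, expected, tolerance = 1e-12)
  # I(0) = (sum f)^2 for any model
  asm <- make_subunit(test_spec(seed = 12, subunit_beads = 30))
  p0 <- debye_profile(asm, c(0, 0.05))
  res <- unique(as.data.frame(asm[, c("seq_id", "aa")]))
  f_sum <- sum(oligoshift:::aa_residue_electrons[res$aa])
  expect_equal(p0$intensity[1], f_sum^2, tolerance = 1e-6)
})

test_that("Debye profile is invariant under rigid motion and non-negative", {
  asm <- make_subunit(test_spec(seed = 13, subunit_beads = 25))
  q <- seq(0.01, 0.45, length.out = 40)
  p <- debye_profile(asm, q)
  tf <- rigid_transform(random_rotation(), c(11, -4, 2))
  moved <- asm
  xyz <- transform_coords(tf, cbind(asm$x, asm$y, asm$z))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  p_moved <- debye_profile(moved, q)
  expect_equal(p_moved$intensity / p$intensity, rep(1, length(q)),
               tolerance = 1e-9)
  expect_true(all(p$intensity >= 0))
})

test_that("rg_from_coordinates matches closed forms", {
  expect_equal(rg_from_coordinates(unit_scatterers(c(0, 0, 0)),
                                   granularity = "atom"), 0)
  two <- unit_scatterers(rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(rg_from_coordinates(two, granularity = "atom"), 3)
  sphere <- make_sphere_beads(800, 30, seed = 2)
  expect_lt(abs(rg_from_coordinates(sphere) / (sqrt(3 / 5) * 30) - 1), 0.02)
})

test_that("Guinier fit recovers Rg exactly on a pure Gaussian curve", {
  q <- seq(0.002, 0.2, by = 0.002)
  rg <- 30
  prof <- saxs_profile(q, 1e5 * exp(-q^2 * rg^2 / 3))
  fit <- guinier_fit(prof)
  expect_lt(abs(fit$Rg - 30), 0.01)
  expect_equal(fit$I0, 1e5, tolerance = 1e-4)
  expect_lte(fit$q_max_used * fit$Rg, 1.5)
})

test_that("Guinier fit on a sphere bead model recovers sqrt(3/5) R", {
  sphere <- make_sphere_beads(800, 30, seed = 3)
  q <- seq(0.002, 0.3, by = 0.002)
  prof <- debye_profile(sphere, q)
  fit <- guinier_fit(prof)
  rg_true <- rg_from_coordinates(sphere)
  expect_lt(abs(fit$Rg / rg_true - 1), 0.03)
  expect_lt(abs(fit$Rg / (sqrt(3 / 5) * 30) - 1), 0.02)
  expect_lte(fit$q_max_used * fit$Rg, 1.5)
})

test_that("Guinier fit rejects unusable input", {
  q <- seq(0.002, 0.1, by = 0.002)
  neg <- saxs_profile(q, c(rep(-1, 6), rep(1, length(q) - 6)))
  expect_error(guinier_fit(neg), "non-positive|usable")
  short <- saxs_profile(q[1:6], exp(-q[1:6]^2 * 300))
  expect_error(guinier_fit(short), "fewer than")
})

test_that("chi fit is exact on proportional curves and has the WLS optimum scale", {
  q <- seq(0.01, 0.4, length.out = 100)
  base <- saxs_profile(q, 1000 * exp(-q^2 * 200) + 5)
  scaled <- saxs_profile(q, 5 * base$intensity)
  fit <- chi_fit(scaled, base)
  expect_equal(fit$scale, 5, tolerance = 1e-12)
  expect_equal(fit$chi, 0, tolerance = 1e-10)
  # reversed: experimental = base, model = 5x base -> scale 0.2
  expect_equal(chi_fit(base, scaled)$scale, 0.2, tolerance = 1e-12)

  # grid-search oracle for the optimal scale under weights
  set.seed(4)
  noisy <- saxs_profile(q, base$intensity * (1 + 0.05 * rnorm(length(q))),
                        sigma = 0.05 * base$intensity)
  fit2 <- chi_fit(noisy, base)
  grid <- seq(0.5, 1.5, by = 1e-4)
  ssr <- vapply(grid, function(cc) {
    sum(((noisy$intensity - cc * base$intensity) / noisy$sigma)^2)
  }, numeric(1))
  expect_equal(fit2$scale, grid[which.min(ssr)], tolerance = 2e-4)
})

test_that("chi is near 1 for data noised at the stated sigma", {
  q <- seq(0.01, 0.4, length.out = 200)
  base <- saxs_profile(q, 1e4 * exp(-q^2 * 150) + 20)
  set.seed(11)
  sig <- 0.02 * base$intensity
  noisy <- saxs_profile(q, base$intensity + sig * rnorm(200), sigma = sig)
  expect_lt(abs(chi_fit(noisy, base)$chi - 1), 0.1)
})

test_that("chi fit refuses non-overlapping q ranges", {
  a <- saxs_profile(seq(0.01, 0.1, by = 0.01), rep(1, 10))
  b <- saxs_profile(seq(0.2, 0.3, by = 0.01), rep(1, 11))
  expect_error(chi_fit(a, b), "overlap")
})

test_that("classification calls the generating assembly", {
  q <- seq(0.01, 0.46, length.out = 150)
  gens <- lapply(c(dimer = "C2", tetramer = "dimer_of_dimers", hexamer = "D3"),
                 function(pg) make_assembly(test_spec(pg, seed = 21))$assembly)
  # exact theoretical tetramer curve: chi ~ 0 for the tetramer
  exact <- debye_profile(gens$tetramer, q)
  call0 <- classify_oligomer(exact, gens)
  expect_equal(call0$best_model, "tetramer")
  expect_lt(call0$chis["tetramer"], 1e-8)
  # noisy hexamer data
  noisy <- make_noisy_profile(gens$hexamer, q, 0.02, seed = 31)
  call1 <- classify_oligomer(noisy, gens, measured_mass = 218.3,
                             subunit_mass = 50)
  expect_equal(call1$best_model, "hexamer")
  expect_gt(call1$chis["dimer"], call1$chis["hexamer"])
  expect_equal(call1$subunit_count, 4L)  # round(218.3 / 50)
  expect_false(call1$mass_consistent)    # hexamer has 6 chains, mass says 4
  expect_error(classify_oligomer(noisy, gens["dimer"]), "at least 2")
})

test_that("frame merging keeps the Rg-uniform run and averages noise", {
  q <- seq(0.004, 0.3, by = 0.004)
  curve <- function(rg) saxs_profile(q, 1e5 * exp(-q^2 * rg^2 / 3),
                                     sigma = rep(100, length(q)))
  frames <- c(replicate(8, curve(30), simplify = FALSE),
              replicate(2, curve(40), simplify = FALSE))
  merged <- merge_frames(frames)
  expect_equal(attr(merged, "frames_used"), 1:8)
  expect_equal(merged$sigma, rep(100 / sqrt(8), length(q)))
  expect_equal(merged$intensity, curve(30)$intensity)
  # ten identical frames: sigma shrinks by sqrt(10)
  same <- replicate(10, curve(25), simplify = FALSE)
  m2 <- merge_frames(same)
  expect_equal(m2$sigma, rep(100 / sqrt(10), length(q)))
  # mismatched grids are refused
  off <- curve(30); off$q <- off$q * 1.01
  expect_error(merge_frames(list(curve(30), off)), "common q grid")
})

test_that("SAXS text files round-trip and reject bad input", {
  q <- seq(0.01, 0.3, length.out = 50)
  prof <- saxs_profile(q, exp(-q^2 * 100) * 1e4, sigma = rep(10, 50))
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs(prof, path)
  back <- read_saxs(path)
  expect_equal(back$q, prof$q, tolerance = 1e-6)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-6)
  expect_equal(back$sigma, prof$sigma, tolerance = 1e-6)
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# header", "0.01 nope"), bad)
  expect_error(read_saxs(bad), "non-numeric")
})
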