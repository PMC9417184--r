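test_that("superpose recovers exact transforms in closed-form cases", {
  set.seed(1)
  pts <- matrix(rnorm(60, sd = 5), ncol = 3)
  fit <- superpose(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$transform$R, diag(3), tolerance = 1e-10)
  # 90 degrees about z: trace 1 + 2 cos(90) = 1
  rot <- axis_rotation("z", pi / 2)
  fit90 <- superpose(pts, transform_coords(rot, pts))
  expect_equal(fit90$rmsd, 0, tolerance = 1e-10)
  expect_equal(sum(diag(fit90$transform$R)), 1, tolerance = 1e-9)
})

test_that("superpose recovers a noisy random transform near the truth", {
  set.seed(42)
  pts <- matrix(rnorm(150, sd = 8), ncol = 3)
  truth <- rigid_transform(random_rotation(), rnorm(3, sd = 10))
  noisy <- transform_coords(truth, pts) + matrix(rnorm(150, sd = 0.1), ncol = 3)
  fit <- superpose(pts, noisy)
  # rmsd is close to the per-point noise magnitude sqrt(3) * 0.1
  expect_lt(abs(fit$rmsd - sqrt(3) * 0.1), 0.08)
  expect_lt(max(abs(fit$transform$R - truth$R)), 1e-2)
  expect_lt(max(abs(fit$transform$t - truth$t)), 0.2)
})

test_that("superpose agrees with the bio3d superposition oracle", {
  set.seed(7)
  a <- matrix(rnorm(90, sd = 6), ncol = 3)
  b <- transform_coords(rigid_transform(random_rotation(), c(3, -2, 9)), a) +
    matrix(rnorm(90, sd = 0.3), ncol = 3)
  ours <- superpose(a, b)$rmsd
  oracle <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
  expect_equal(ours, oracle, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("superpose rejects degenerate inputs", {
  expect_error(superpose(matrix(1:6, 2, 3), matrix(1:6, 2, 3)), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("derive_symmetry recovers the exact generating transforms of a D3 assembly", {
  gen <- make_assembly(test_spec("D3", seed = 2))
  sd <- derive_symmetry(gen$assembly)
  expect_length(sd$transforms, 6)
  expect_true(all(sd$rmsd < 1e-6))
  expect_equal(sd$point_group, "D3")
  for (i in seq_along(sd$transforms)) {
    expect_lt(max(abs(sd$transforms[[i]]$R - gen$symdef$transforms[[i]]$R)), 1e-6)
    expect_lt(max(abs(sd$transforms[[i]]$t - gen$symdef$transforms[[i]]$t)), 1e-5)
  }
})

test_that("derive_symmetry handles single chains and C2 dimers", {
  sub <- make_subunit(test_spec("C1", seed = 4))
  sd1 <- derive_symmetry(sub)
  expect_length(sd1$transforms, 1)
  expect_equal(sd1$point_group, "C1")

  gen <- make_assembly(test_spec("C2", seed = 4))
  sd2 <- derive_symmetry(gen$assembly)
  expect_length(sd2$transforms, 2)
  expect_equal(sd2$point_group, "C2")
  # two-fold: trace(R) = 1 + 2 cos(pi) = -1
  expect_equal(sum(diag(sd2$transforms[[2]]$R)), -1, tolerance = 1e-6)
})

test_that("derive_symmetry flags bad pairings and too-short chains", {
  gen <- make_assembly(test_spec("C2", seed = 6))
  asm <- gen$assembly
  # wreck chain B so no rigid transform fits
  idx <- asm$chain == "B"
  set.seed(1)
  asm$x[idx] <- asm$x[idx] + rnorm(sum(idx), sd = 4)
  asm2 <- assembly(tibble::as_tibble(asm), partition = partition(gen$assembly))
  expect_error(derive_symmetry(asm2, rmsd_tol = 2), "chain B")
  tiny <- make_assembly(test_spec("C2", seed = 6, subunit_beads = 10,
                                  subunit_radius = 9))
  expect_error(derive_symmetry(tiny$assembly), "matched CA")
})

test_that("apply_symmetry preserves intra-subunit distances and round-trips", {
  gen <- make_assembly(test_spec("D3", seed = 3))
  sub <- assembly(gen$assembly[gen$assembly$chain == "A", ])
  rebuilt <- apply_symmetry(sub, derive_symmetry(gen$assembly))
  expect_equal(unique(rebuilt$chain), unique(gen$assembly$chain))
  expect_equal(cbind(rebuilt$x, rebuilt$y, rebuilt$z),
               cbind(gen$assembly$x, gen$assembly$y, gen$assembly$z),
               tolerance = 1e-6)
  # rigid transforms preserve intra-chain distances exactly
  a0 <- sub[1:20, ]
  aF <- rebuilt[rebuilt$chain == "F", ][1:20, ]
  d0 <- dist(cbind(a0$x, a0$y, a0$z))
  dF <- dist(cbind(aF$x, aF$y, aF$z))
  expect_equal(as.vector(dF), as.vector(d0), tolerance = 1e-9)
})

test_that("the D3 transform set is closed under composition", {
  gen <- make_assembly(test_spec("D3", seed = 5))
  tfs <- derive_symmetry(gen$assembly)$transforms
  for (a in tfs) {
    for (b in tfs) {
      comp <- compose_transforms(a, b)
      dists <- vapply(tfs, function(tf) {
        max(abs(tf$R - comp$R)) + max(abs(tf$t - comp$t))
      }, numeric(1))
      expect_lt(min(dists), 1e-5)
    }
  }
})

test_that("symmetry definitions round-trip through JSON", {
  gen <- make_assembly(test_spec("D3", seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_symmetry_json(gen$symdef, path)
  back <- read_symmetry_json(path)
  expect_equal(back$point_group, gen$symdef$point_group)
  expect_equal(back$groups, gen$symdef$groups)
  for (i in seq_along(back$transforms)) {
    expect_equal(back$transforms[[i]]$R, gen$symdef$transforms[[i]]$R,
                 tolerance = 1e-12)
    expect_equal(back$transforms[[i]]$t, gen$symdef$transforms[[i]]$t,
                 tolerance = 1e-12)
  }
})
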