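# Force-field terms: printed forms (no 1/2 prefactors), branch continuity
# of the Ashbaugh-Hatch potential, and analytic forces against finite
# differences.

test_that("harmonic bond follows the printed form and its derivative", {
  m <- interaction_model()
  expect_equal(bond_energy_force(5.5, m)$energy, 0)
  expect_equal(bond_energy_force(6.5, m)$energy, 20)       # K (r - r0)^2
  set.seed(1)
  for (r in runif(20, 4, 8)) {
    h <- 1e-6
    fd <- -(bond_energy_force(r + h, m)$energy -
              bond_energy_force(r - h, m)$energy) / (2 * h)
    expect_rel_equal(bond_energy_force(r, m)$force, fd, 1e-6)
  }
  expect_error(bond_energy_force(-1, m), "geometry")
})

test_that("harmonic angle is symmetric about theta0 and zero at it", {
  m <- interaction_model()
  expect_equal(angle_energy_force(pi, params = m)$energy, 0)
  d <- 0.3
  expect_equal(angle_energy_force(pi - d, params = m)$energy,
               angle_energy_force(pi + d, params = m)$energy)
  # K_theta (theta - pi)^2 directly
  expect_equal(angle_energy_force(pi - 0.5, params = m)$energy, 20 * 0.25)
})

test_that("angle forces match finite differences, sum to zero, no net torque", {
  m <- interaction_model()
  set.seed(42)
  for (rep in 1:5) {
    tri <- matrix(rnorm(9, sd = 4), 3, 3) + 10
    res <- angle_energy_force(params = m, positions = tri)
    expect_equal(colSums(res$forces), c(0, 0, 0), tolerance = 1e-10)
    tau <- colSums(do.call(rbind, lapply(1:3, function(i) {
      r <- tri[i, ]; f <- res$forces[i, ]
      c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
    })))
    expect_equal(tau, c(0, 0, 0), tolerance = 1e-8)
    h <- 1e-6
    for (i in 1:3) for (d in 1:3) {
      tp <- tri; tp[i, d] <- tp[i, d] + h
      tm <- tri; tm[i, d] <- tm[i, d] - h
      fd <- -(angle_energy_force(params = m, positions = tp)$energy -
                angle_energy_force(params = m, positions = tm)$energy) /
        (2 * h)
      expect_equal(res$forces[i, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("colinear angle triplets evaluate with finite forces", {
  m <- interaction_model(theta0 = pi / 2)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))  # theta = pi exactly
  res <- angle_energy_force(params = m, positions = tri)
  expect_true(all(is.finite(res$forces)))
  tri0 <- rbind(c(2, 0, 0), c(1, 0, 0), c(2, 0, 1e-9)) # theta ~ 0
  expect_true(all(is.finite(
    angle_energy_force(params = m, positions = tri0)$forces)))
})

test_that("Ashbaugh-Hatch potential matches its printed values and limits", {
  # at the LJ minimum: U = -lambda epsilon for any lambda
  expect_equal(pair_energy_force(2^(1 / 6) * 50, 50, 1, 0.2, Inf)$energy,
               -0.2)
  expect_equal(pair_energy_force(2^(1 / 6) * 50, 50, 2, 0.2, Inf)$energy,
               -0.4)
  # at r = sigma the LJ part vanishes: U = (1 - lambda) epsilon
  expect_equal(pair_energy_force(50, 50, 0.5, 0.2, Inf)$energy, 0.1)
  # with lambda = 1 it is plain LJ everywhere
  r <- seq(45, 140, by = 0.5)
  ulj <- 4 * 0.2 * ((50 / r)^12 - (50 / r)^6)
  expect_equal(pair_energy_force(r, 50, 1, 0.2, Inf)$energy, ulj,
               tolerance = 1e-12)
  expect_error(pair_energy_force(0, 50, 1, 0.2, Inf), "overlap")
})

test_that("AH branches are continuous at 2^(1/6) sigma for any lambda", {
  rmin <- 2^(1 / 6) * 27.5
  for (lam in c(-1, 0, 0.3, 1, 2, 3.5)) {
    lo <- pair_energy_force(rmin * (1 - 1e-9), 27.5, lam, 0.2, 100)$energy
    hi <- pair_energy_force(rmin * (1 + 1e-9), 27.5, lam, 0.2, 100)$energy
    expect_lt(abs(lo - hi), 1e-10)
  }
})

test_that("DNA-DNA interaction (lambda = -1) is purely repulsive", {
  r <- seq(0.9 * 5, 15 - 1e-9, length.out = 400)
  u <- pair_energy_force(r, 5, -1, 0.2, 15)$energy
  expect_true(all(diff(u) < 0))
})

test_that("pair energy is shifted to zero at the cutoff and symmetric in species", {
  u <- pair_energy_force(150 - 1e-9, 50, 2, 0.2, 150)$energy
  expect_lt(abs(u), 1e-10)
  m <- interaction_model(lambda_pp = 1.7, lambda_pd = 2.5)
  expect_identical(m$lambda["P", "D"], m$lambda["D", "P"])
  expect_identical(m$sigma_matrix["P", "D"], 27.5)
})

test_that("total energy matches the brute-force double-loop oracle", {
  m <- interaction_model(lambda_pp = 2, lambda_pd = 1.2)
  for (seed in 1:3) {
    rc <- random_config_o(20, 30, 300, seed)
    got <- total_energy(rc$config, rc$topology, m)
    want <- total_energy_o(rc$config, rc$topology, m)
    expect_equal(got$pair, want$pair, tolerance = 1e-9)
  }
  # with a bonded chain present
  ch <- build_dna_chain(10, start = c(50, 50, 50), direction = c(1, 0.2, 0))
  set.seed(9)
  pos <- rbind(matrix(runif(15, 40, 120), 5, 3), ch$pos + rnorm(30, sd = 0.3))
  topo <- topology(c(rep(1L, 5), rep(2L, 10)), c(1:5, rep(6L, 10)),
                   ch$bonds + 5L, ch$angles + 5L)
  cfg <- configuration(pos, 400)
  got <- total_energy(cfg, topo, m)
  want <- total_energy_o(cfg, topo, m)
  expect_equal(got$bond, want$bond, tolerance = 1e-9)
  expect_equal(got$angle, want$angle, tolerance = 1e-9)
  expect_equal(got$pair, want$pair, tolerance = 1e-9)
})

test_that("compiled forces equal the finite-difference gradient", {
  m <- interaction_model(lambda_pp = 2, lambda_pd = 1.2)
  ch <- build_dna_chain(6, start = c(60, 60, 60), direction = c(1, 0.3, 0.1))
  set.seed(4)
  pos <- rbind(matrix(runif(9, 50, 110), 3, 3), ch$pos + rnorm(18, sd = 0.4))
  topo <- topology(c(rep(1L, 3), rep(2L, 6)), c(1:3, rep(4L, 6)),
                   ch$bonds + 3L, ch$angles + 3L)
  cfg <- configuration(pos, 400)
  got <- total_energy(cfg, topo, m)$forces
  want <- fd_forces_o(cfg, topo, m)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("isolated equilibrium structures have zero bonded energy", {
  fx <- make_fixture("one-chain-20bp")
  e <- total_energy(fx$config, fx$topology, interaction_model())
  expect_equal(e$bond, 0, tolerance = 1e-12)
  expect_equal(e$angle, 0, tolerance = 1e-12)
  # two isolated proteins at the pair minimum, lambda_PP = 2
  dim_ <- make_fixture("dimer")
  m2 <- interaction_model(lambda_pp = 2, cutoff_factor = 1e6)
  e2 <- total_energy(dim_$config, dim_$topology, m2)
  expect_equal(e2$pair, -0.4, tolerance = 1e-6)
})

test_that("topology referencing missing particles is rejected", {
  topo <- topology(c(1L, 1L), c(1L, 2L), bonds = rbind(c(1L, 5L)))
  cfg <- configuration(matrix(runif(6, 0, 100), 2, 3), 400)
  expect_error(total_energy(cfg, topo, interaction_model()), "missing")
})
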