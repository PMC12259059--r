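# Structural observables against hand-computed and brute-force oracles.

test_that("cluster criterion threshold arithmetic (1.5 sigma_PD = 41.25 A)", {
  topo <- topology(c(1L, 1L), c(1L, 2L))
  near <- configuration(rbind(c(100, 100, 100), c(140, 100, 100)), 500)
  far <- configuration(rbind(c(100, 100, 100), c(142, 100, 100)), 500)
  cl_near <- find_clusters(near, topo)
  cl_far <- find_clusters(far, topo)
  expect_equal(cl_near$cutoff, 41.25)
  expect_equal(max(cl_near$cluster), 1)
  expect_equal(max(cl_far$cluster), 2)
})

test_that("cluster labeling equals brute-force BFS on random configurations", {
  m <- interaction_model()
  for (seed in 1:4) {
    set.seed(seed)
    n_mol <- 60
    pos <- matrix(runif(3 * n_mol, 0, 500), n_mol, 3)
    topo <- topology(rep(1L, n_mol), 1:n_mol)
    cfg <- configuration(pos, 500)
    got <- find_clusters(cfg, topo, cutoff = 60)
    want <- clusters_bfs_o(cfg, topo, 60)
    # same partition up to label permutation
    expect_equal(max(got$cluster), max(want))
    expect_true(all(tapply(want, got$cluster,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("clustering connects molecules through any bead and is invariant
           under reordering and box translation", {
  # two DNA chains whose ends approach within the cutoff
  ch1 <- build_dna_chain(10, start = c(100, 100, 100), direction = c(1, 0, 0))
  ch2 <- build_dna_chain(10, start = c(100 + 9 * 5.5 + 30, 100, 100),
                         direction = c(1, 0, 0))
  pos <- rbind(ch1$pos, ch2$pos)
  topo <- topology(rep(2L, 20), rep(1:2, each = 10),
                   rbind(ch1$bonds, ch2$bonds + 10L),
                   rbind(ch1$angles, ch2$angles + 10L))
  cfg <- configuration(pos, 500)
  expect_equal(max(find_clusters(cfg, topo)$cluster), 1)
  # translate across the periodic boundary: same partition
  cfg2 <- configuration(pos + 450, 500)
  expect_equal(max(find_clusters(cfg2, topo)$cluster), 1)
  # reorder particles
  perm <- sample(20)
  topo3 <- topology(topo$type[perm], topo$molecule[perm],
                    species_names = topo$species_names)
  cfg3 <- configuration(pos[perm, ], 500)
  expect_equal(max(find_clusters(cfg3, topo3)$cluster), 1)
})

test_that("largest-cluster fractions hit their limiting values", {
  # hand-built blob: everything within one cutoff
  set.seed(2)
  pos <- matrix(runif(60, 200, 230), 20, 3)
  topo <- topology(rep(c(1L, 2L), 10), 1:20)
  blob <- configuration(pos, 500)
  fr <- find_clusters(blob, topo)
  expect_equal(fr$protein_fraction, 1)
  expect_equal(fr$dna_fraction, 1)
  # dispersed lattice: all singletons
  g <- as.matrix(expand.grid(1:3, 1:3, 1:3)) * 150
  topo2 <- topology(rep(1L, 27), 1:27)
  disp <- find_clusters(configuration(g, 500), topo2)
  expect_equal(max(disp$cluster), 27)
  expect_equal(disp$protein_fraction, 1 / 27)
})

test_that("weak heterotypic coupling yields a protein-only condensate", {
  # lambda_PP = 4, lambda_PD = 0.3: proteins condense, DNA stays dilute
  m <- interaction_model(lambda_pp = 4, lambda_pd = 0.3)
  spec <- system_spec(n_protein = 200L, dna_length = 50L,
                      n_dna_chains = 4L, box_edge = 1000, seed = 42L,
                      placement = "central-random")
  sys <- build_mixture(spec, m)
  tr <- run_simulation(sys$topology, sys$config, m,
                       thermostat_params(t_damp_ps = 100, seed = 9L),
                       n_steps = 2.5e5, cadence = 1.25e4, quiet = TRUE)
  fr <- largest_cluster_fractions(tr)
  expect_gt(fr$protein$mean, 0.5)
  expect_lt(fr$dna$mean, 0.5)
  expect_gt(fr$protein$mean, 2 * fr$dna$mean)
})

test_that("radius of gyration: hand-computed cases and invariances", {
  # straight 3-bead chain at 5.5 A spacing
  ch <- build_dna_chain(3)
  expect_equal(radius_of_gyration(ch$pos), 5.5 * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(matrix(5, 10, 3)), 0)
  # rigid rotation + translation invariance
  set.seed(3)
  chain <- sample_wlc_chain(50)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- chain %*% rot + matrix(c(10, -4, 7), 50, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(chain),
               tolerance = 1e-10)
  # equals the pairwise-distance formula Rg^2 = mean_ij |ri - rj|^2 / 2
  pw <- sqrt(sum(as.matrix(dist(chain))^2) / (2 * 50^2))
  expect_equal(radius_of_gyration(chain), pw, tolerance = 1e-10)
})

test_that("chain unwrapping through periodic images is exact", {
  ch <- build_dna_chain(40, start = c(480, 250, 250), direction = c(1, 0, 0))
  topo <- topology(rep(2L, 40), rep(1L, 40), ch$bonds, ch$angles)
  cfg <- configuration(ch$pos, 500)  # crosses the +x boundary
  expect_true(any(cfg$img != 0))
  chains <- dna_chains(cfg, topo)
  expect_equal(radius_of_gyration(chains[[1]]),
               radius_of_gyration(ch$pos), tolerance = 1e-12)
})

test_that("sampled free-chain Rg matches the worm-like-chain closed form", {
  set.seed(10)
  rg <- mean(vapply(1:150, function(i)
    radius_of_gyration(sample_wlc_chain(250)), numeric(1)))
  expect_rel_equal(rg, wlc_rg_theory(250)$rg, 0.10)
})

test_that("persistence length is monotone in K_theta and near the stiff limit", {
  set.seed(5)
  lp <- vapply(c(0.5, 1.5, 7.5, 20), function(k) {
    m <- interaction_model(k_angle = k)
    ens <- generate_synthetic("wlc-chain-ensemble",
                              list(n_beads = 250L, n_chains = 60L,
                                   model = m), seed = round(10 * k))
    persistence_length(ens$chains, r0 = 5.5)$lp
  }, numeric(1))
  expect_true(all(diff(lp) > 0))
  stiff <- 2 * 20 * 5.5 / (kB * 300)
  expect_rel_equal(lp[4], stiff, 0.20)
  # flexible limit: l_p on the bond-length scale
  expect_lt(lp[1], 4 * 5.5)
})

test_that("bound-protein criterion threshold and brute-force agreement", {
  topo <- topology(c(1L, 2L), c(1L, 2L))
  near <- configuration(rbind(c(100, 100, 100), c(154, 100, 100)), 500)
  far <- configuration(rbind(c(100, 100, 100), c(156, 100, 100)), 500)
  expect_equal(bound_protein_fraction(near, topo), 1)
  expect_equal(bound_protein_fraction(far, topo), 0)
  for (seed in 1:3) {
    rc <- random_config_o(25, 40, 400, seed)
    got <- bound_protein_fraction(rc$config, rc$topology)
    # brute-force min-distance oracle
    pos <- rc$config$pos
    bound <- 0
    for (i in 1:25) {
      dmin <- min(vapply(26:65, function(j)
        sqrt(sum(min_image_o(pos[i, ] - pos[j, ], 400)^2)), numeric(1)))
      if (dmin <= 55) bound <- bound + 1
    }
    expect_equal(got, bound / 25)
  }
  pro_only <- topology(c(1L, 1L), c(1L, 2L))
  expect_error(bound_protein_fraction(near, pro_only), "no DNA")
})

test_that("radial density profile recovers uniform and dense-sphere references", {
  # dense sphere in a dilute gas: plateau then drop at the sphere radius
  profs <- lapply(1:4, function(s) {
    syn <- generate_synthetic("sphere-in-gas-config",
                              list(rho_dense = 3e-5, rho_dilute = 1e-6,
                                   radius = 120, box = 700), seed = s)
    radial_density_profile(syn$config, topology = syn$topology,
                           shell_width = 10)
  })
  dens <- rowMeans(sapply(profs, `[[`, "density"))
  r <- profs[[1]]$r
  vol <- 4 / 3 * pi * ((r + 5)^3 - (r - 5)^3)
  wmean <- function(sel) sum(dens[sel] * vol[sel]) / sum(vol[sel])
  expect_rel_equal(wmean(r < 90), 3e-5, 0.10)
  expect_rel_equal(wmean(r > 200 & r < 330), 1e-6, 0.35)
  # uniform ideal gas: profile flat at the bulk density wherever centered
  # (skip the innermost shells: centering on the largest-cluster COM of a
  # gas correlates the center with a local density excess)
  set.seed(77)
  n <- 1500
  gdens <- rowMeans(sapply(1:3, function(s) {
    set.seed(77 + s)
    pos <- matrix(runif(3 * n, 0, 700), n, 3)
    topo <- topology(rep(1L, n), seq_len(n))
    radial_density_profile(configuration(pos, 700), topology = topo,
                           shell_width = 20)$density
  }))
  gr <- seq(10, by = 20, length.out = length(gdens))
  gvol <- 4 / 3 * pi * ((gr + 10)^3 - (gr - 10)^3)
  gsel <- gr > 100
  expect_rel_equal(sum(gdens[gsel] * gvol[gsel]) / sum(gvol[gsel]),
                   n / 700^3, 0.10)
})

test_that("periodic-safe center of mass handles boundary-straddling clusters", {
  set.seed(6)
  blob <- matrix(rnorm(300, sd = 10), 100, 3)
  blob <- blob - matrix(colMeans(blob), 100, 3, byrow = TRUE)  # COM at 0
  cfg <- configuration(blob + 499, 500)  # straddles the corner
  com <- periodic_com(cfg$pos, 500)
  d <- min_image_o(com - c(499, 499, 499), 500)
  expect_lt(sqrt(sum(d^2)), 3)
})

test_that("tanh profile fits recover noiseless synthetic parameters", {
  syn1 <- generate_synthetic("tanh-profile",
                             list(rho_dil = 2e-7, delta_rho = 1.5e-5,
                                  radius = 150, width = 25, r_max = 450,
                                  n_shells = 90L), seed = 1)
  f1 <- fit_tanh_profile(syn1$profile, 1L)
  expect_true(f1$converged)
  expect_rel_equal(f1$radius[1], 150, 1e-6)
  expect_rel_equal(f1$width[1], 25, 1e-6)
  expect_rel_equal(f1$delta_rho[1], 1.5e-5, 1e-6)

  syn2 <- generate_synthetic("tanh-profile",
                             list(rho_dil = 2e-7,
                                  delta_rho = c(2e-5, 0.8e-5),
                                  radius = c(100, 220),
                                  width = c(15, 25), r_max = 450,
                                  n_shells = 90L), seed = 1)
  f2 <- fit_tanh_profile(syn2$profile, 2L)
  expect_true(f2$converged)
  expect_equal(f2$chosen, 2L)
  expect_rel_equal(f2$radius[1], 100, 1e-4)
  expect_rel_equal(f2$radius[2], 220, 1e-4)
  # plateau ordering rho_I >= rho_II >= rho_dil
  expect_true(f2$plateaus[1] >= f2$plateaus[2])
  expect_true(f2$plateaus[2] >= f2$rho_dil)
})

test_that("interface radii survive 5 percent multiplicative noise", {
  syn <- generate_synthetic("tanh-profile",
                            list(rho_dil = 2e-7,
                                 delta_rho = c(2e-5, 0.8e-5),
                                 radius = c(100, 220), width = c(15, 25),
                                 r_max = 450, n_shells = 90L,
                                 noise_sd = 0.05), seed = 4)
  f <- fit_tanh_profile(syn$profile, 2L)
  expect_true(f$converged)
  expect_rel_equal(f$radius[1], 100, 0.05)
  expect_rel_equal(f$radius[2], 220, 0.05)
})

test_that("a single-phase profile fitted with two interfaces is flagged degenerate", {
  syn <- generate_synthetic("tanh-profile",
                            list(rho_dil = 2e-7, delta_rho = 1.5e-5,
                                 radius = 150, width = 25, r_max = 450,
                                 n_shells = 90L), seed = 1)
  f <- fit_tanh_profile(syn$profile, 2L)
  expect_equal(f$chosen, 1L)
})

test_that("coexistence concentrations recover a known sphere-in-gas system", {
  # several independent realizations as frames, to average shot noise
  syns <- lapply(1:6, function(s)
    generate_synthetic("sphere-in-gas-config",
                       list(rho_dense = 3e-5, rho_dilute = 5e-7,
                            radius = 130, box = 700), seed = s))
  # frames must share a particle count: use a common topology per frame is
  # not required by the analysis, which only reads type/molecule per frame;
  # build one trajectory per realization and average the profiles by hand
  profs <- lapply(syns, function(syn)
    radial_density_profile(syn$config, topology = syn$topology,
                           shell_width = 10))
  avg <- profs[[1]]
  avg$density <- rowMeans(sapply(profs, `[[`, "density"))
  f <- fit_tanh_profile(avg, 1L)
  expect_true(f$converged)
  expect_rel_equal(f$plateaus[1], 3e-5, 0.05)
  # the full pipeline on one realization: right phases, right ordering
  syn <- syns[[1]]
  fake <- condensr:::new_trajectory(syn$topology, NULL, NULL, 700)
  fake$frames <- list(list(step = 0L, time_fs = 0, pos = syn$config$pos,
                           img = syn$config$img))
  cc <- coexistence_concentrations(fake, n_interfaces = 1L, frames = 1L)
  expect_rel_equal(cc$dense, 3e-5, 0.15)
  expect_rel_equal(cc$dilute, 5e-7, 0.40)
  expect_gt(cc$dense, 10 * cc$dilute)
})

test_that("homogeneous systems give dilute = N/V and undefined dense phase", {
  set.seed(9)
  n <- 400
  pos <- matrix(runif(3 * n, 0, 600), n, 3)
  topo <- topology(rep(1L, n), 1:n)
  fake <- condensr:::new_trajectory(topo, NULL, NULL, 600)
  fake$frames <- list(list(step = 0L, time_fs = 0,
                           pos = configuration(pos, 600)$pos,
                           img = matrix(0L, n, 3)))
  cc <- coexistence_concentrations(fake, frames = 1L)
  expect_true(is.na(cc$dense))
  expect_equal(cc$dilute, n / 600^3, tolerance = 1e-12)
})

test_that("block averaging follows the discard-first-of-five protocol", {
  expect_error(block_average(1:3, n_blocks = 5), "too short")
  bs <- block_average(rep(2.5, 100))
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$se, 0)
  expect_equal(bs$n_blocks, 4)   # five blocks, first discarded
  alt <- block_average(rep(c(1, -1), 500))
  expect_lt(abs(alt$mean), 1e-12)
  # equilibration discard: early transient does not pollute the mean
  series <- c(rep(10, 20), rep(1, 80))
  expect_equal(block_average(series)$mean, 1)
})

test_that("block standard error scales like sigma/sqrt(blocks) for iid noise", {
  set.seed(12)
  ratios <- replicate(200, {
    x <- rnorm(500)
    bs <- block_average(x)
    bs$se
  })
  # 4 analysis blocks of 100 iid N(0,1): SE of the grand mean ~ 1/sqrt(400)
  expect_rel_equal(mean(ratios), 1 / sqrt(400), 0.30)
})
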