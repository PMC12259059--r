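# Synthetic data generators.  Every analysis operation in the package has a
# closed-loop test built on one of these: the generator embeds its ground
# truth in the returned object so recovery can be asserted exactly.

#' Sample one worm-like DNA chain by direct Boltzmann sampling
#'
#' Draws an equilibrium conformation of the bead-spring DNA chain whose
#' Hamiltonian has only bond and angle terms.  Because bonds and angles are
#' then statistically independent, the chain can be sampled exactly: bond
#' lengths from `P(r) ~ r^2 exp(-K_b (r - r0)^2 / kT)`, bend angles
#' `delta = pi - theta` from `P(delta) ~ sin(delta) exp(-K_theta delta^2 / kT)`,
#' and dihedral azimuths uniformly.  This is the fast, exact route to free
#' (isolated-chain) statistics such as the mean radius of gyration or the
#' persistence length; it is cross-validated against Langevin dynamics in the
#' test suite.
#'
#' @param n_beads number of beads (>= 2).
#' @param model an [interaction_model()] supplying `k_bond`, `r0`,
#'   `k_angle`; nonbonded terms are not used (free chain).
#' @param temperature temperature in K.
#' @return an `n_beads` x 3 matrix of positions (A), unwrapped.
#' @export
sample_wlc_chain <- function(n_beads, model = interaction_model(),
                             temperature = 300) {
  stopifnot(n_beads >= 2)
  beta <- 1 / (.kB * temperature)
  nb <- n_beads - 1L
  r <- .sample_bond_lengths(nb, model$k_bond, model$r0, beta)
  pos <- matrix(0, n_beads, 3)
  u <- c(0, 0, 1)
  pos[2, ] <- r[1] * u
  if (n_beads > 2) {
    delta <- .sample_bend_angles(n_beads - 2L, model$k_angle, beta)
    phi <- runif(n_beads - 2L, 0, 2 * pi)
    for (i in 3:n_beads) {
      e1 <- .any_perp(u)
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      d <- delta[i - 2L]; p <- phi[i - 2L]
      u <- cos(d) * u + sin(d) * (cos(p) * e1 + sin(p) * e2)
      u <- u / sqrt(sum(u^2))
      pos[i, ] <- pos[i - 1L, ] + r[i - 1L] * u
    }
  }
  pos
}

.any_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}

# P(r) ~ r^2 exp(-beta K (r - r0)^2), rejection from a normal envelope
.sample_bond_lengths <- function(n, k_bond, r0, beta) {
  s <- sqrt(1 / (2 * beta * k_bond))
  rmax2 <- (r0 + 6 * s)^2
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 2L + 10L
    r <- rnorm(m, r0, s)
    keep <- r > 0 & runif(m) < r^2 / rmax2
    r <- r[keep]
    take <- min(length(r), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- r[seq_len(take)]
      got <- got + take
    }
  }
  out
}

# P(delta) ~ sin(delta) exp(-beta K delta^2) on (0, pi), inverse-CDF on a grid
.sample_bend_angles <- function(n, k_angle, beta, ngrid = 4096L) {
  if (n == 0L) return(numeric(0))
  d <- seq(0, pi, length.out = ngrid)
  w <- sin(d) * exp(-beta * k_angle * d^2)
  cdf <- cumsum(w)
  cdf <- cdf / cdf[ngrid]
  approx(cdf, d, xout = runif(n), ties = "ordered", rule = 2)$y
}

#' Generate synthetic datasets with embedded ground truth
#'
#' Registered kinds:
#' \describe{
#'   \item{`brownian-traj`}{isotropic Brownian particle trajectories with a
#'     known diffusion coefficient.  `params`: `n_particles`, `d` (A^2/ns),
#'     `dt_ns`, `n_steps`, optional `drift` (A/ns, length 3).}
#'   \item{`mixture-displacements`}{radial displacements drawn from the
#'     n-mode isotropic diffusive mixture
#'     `P(r, t) = sum_i p_i 4 pi r^2 (4 pi D_i t)^(-3/2) exp(-r^2 / 4 D_i t)`.
#'     `params`: `p`, `d` (A^2/ns), `t_ns`, `n`.}
#'   \item{`tanh-profile`}{noiseless (or multiplicatively noisy) radial
#'     density profile built from the single/double-tanh interface form.
#'     `params`: `rho_dil`, `delta_rho`, `radius`, `width` (vectors of length
#'     1 or 2), `r_max`, `n_shells`, `noise_sd`.}
#'   \item{`sphere-in-gas-config`}{protein positions from a uniform dense
#'     sphere at the box center embedded in a uniform dilute gas.  `params`:
#'     `rho_dense`, `rho_dilute` (A^-3), `radius`, `box`.}
#'   \item{`wlc-chain-ensemble`}{independent free-chain conformations from
#'     [sample_wlc_chain()].  `params`: `n_beads`, `n_chains`, optional
#'     `model`, `temperature`.}
#' }
#'
#' @param kind one of the registered kinds above.
#' @param params named list of generator parameters (see Details).
#' @param seed integer seed; the output is deterministic given (kind,
#'   params, seed).
#' @return a list with elements `kind`, `truth` (the generator parameters)
#'   and the dataset (named per kind).
#' @export
generate_synthetic <- function(kind, params = list(), seed = 1) {
  set.seed(seed)
  switch(kind,
    "brownian-traj" = .syn_brownian(params),
    "mixture-displacements" = .syn_mixture(params),
    "tanh-profile" = .syn_tanh(params),
    "sphere-in-gas-config" = .syn_sphere(params),
    "wlc-chain-ensemble" = .syn_wlc(params),
    stop("unknown synthetic kind: ", kind))
}

.syn_brownian <- function(p) {
  p <- modifyList(list(n_particles = 100L, d = 10, dt_ns = 0.1,
                       n_steps = 100L, drift = c(0, 0, 0)), p)
  sdstep <- sqrt(2 * p$d * p$dt_ns)
  np <- p$n_particles; ns <- p$n_steps
  pos <- array(0, dim = c(ns + 1L, np, 3))
  for (s in seq_len(ns))
    pos[s + 1L, , ] <- pos[s, , ] +
      matrix(rnorm(np * 3, sd = sdstep), np, 3) +
      matrix(p$drift * p$dt_ns, np, 3, byrow = TRUE)
  list(kind = "brownian-traj", truth = p, positions = pos,
       times_ns = (0:ns) * p$dt_ns)
}

.syn_mixture <- function(p) {
  p <- modifyList(list(p = 1, d = 10, t_ns = 1, n = 1e4L), p)
  stopifnot(abs(sum(p$p) - 1) < 1e-9, all(p$d > 0),
            length(p$p) == length(p$d))
  comp <- sample.int(length(p$p), p$n, replace = TRUE, prob = p$p)
  sd <- sqrt(2 * p$d[comp] * p$t_ns)
  dx <- matrix(rnorm(3 * p$n), p$n, 3) * sd
  r <- sqrt(rowSums(dx^2))
  list(kind = "mixture-displacements", truth = p,
       sample = displacement_sample(r, p$t_ns))
}

.syn_tanh <- function(p) {
  p <- modifyList(list(rho_dil = 1e-7, delta_rho = 2e-5, radius = 150,
                       width = 20, r_max = 400, n_shells = 80L,
                       noise_sd = 0), p)
  r <- seq(p$r_max / p$n_shells / 2, p$r_max - p$r_max / p$n_shells / 2,
           length.out = p$n_shells)
  rho <- tanh_profile_value(r, p$rho_dil, p$delta_rho, p$radius, p$width)
  if (p$noise_sd > 0) rho <- rho * (1 + rnorm(length(r), sd = p$noise_sd))
  list(kind = "tanh-profile", truth = p,
       profile = data.frame(r = r, density = pmax(rho, 0)))
}

.syn_sphere <- function(p) {
  p <- modifyList(list(rho_dense = 2e-5, rho_dilute = 5e-7, radius = 150,
                       box = 1000), p)
  ctr <- rep(p$box / 2, 3)
  n_dense <- rpois(1, p$rho_dense * 4 / 3 * pi * p$radius^3)
  u <- matrix(rnorm(3 * n_dense), n_dense, 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- p$radius * runif(n_dense)^(1 / 3)
  dense <- sweep(u * rad, 2, ctr, `+`)
  vol_out <- p$box^3 - 4 / 3 * pi * p$radius^3
  n_dil <- rpois(1, p$rho_dilute * vol_out)
  dil <- matrix(numeric(0), 0, 3)
  while (nrow(dil) < n_dil) {
    cand <- matrix(runif(3 * (n_dil + 20), 0, p$box), ncol = 3)
    cand <- cand[sqrt(rowSums(sweep(cand, 2, ctr)^2)) > p$radius, ,
                 drop = FALSE]
    dil <- rbind(dil, cand)
  }
  pos <- rbind(dense, dil[seq_len(n_dil), , drop = FALSE])
  n <- nrow(pos)
  topo <- topology(type = rep(1L, n), molecule = seq_len(n),
                   species_names = "P")
  list(kind = "sphere-in-gas-config", truth = p,
       config = configuration(pos, p$box), topology = topo)
}

.syn_wlc <- function(p) {
  p <- modifyList(list(n_beads = 250L, n_chains = 100L,
                       model = interaction_model(), temperature = 300), p)
  chains <- lapply(seq_len(p$n_chains), function(i)
    sample_wlc_chain(p$n_beads, p$model, p$temperature))
  list(kind = "wlc-chain-ensemble",
       truth = p[c("n_beads", "n_chains", "temperature")],
       chains = chains, model = p$model)
}

#' Evaluate the tanh interface profile
#'
#' `rho(r) = rho_dil + sum_k (delta_rho_k / 2) (1 - tanh((r - R_k) / w_k))`,
#' the single- (k = 1) or double- (k = 2) interface sigmoid used to fit
#' radial density profiles of condensates.
#'
#' @param r radii (A).
#' @param rho_dil dilute-phase plateau density.
#' @param delta_rho density steps at each interface (length 1 or 2).
#' @param radius interface radii R_k (A).
#' @param width interface widths w_k (A).
#' @return densities at `r`.
#' @export
tanh_profile_value <- function(r, rho_dil, delta_rho, radius, width) {
  out <- rep(rho_dil, length(r))
  for (k in seq_along(delta_rho))
    out <- out + delta_rho[k] / 2 * (1 - tanh((r - radius[k]) / width[k]))
  out
}

#' Closed-form radius of gyration of the discrete worm-like chain
#'
#' Benchmark value for a free chain: the continuous worm-like-chain result
#' `Rg^2 = lp L / 3 - lp^2 + 2 lp^3 / L [1 - lp / L (1 - exp(-L / lp))]`
#' evaluated with contour length `L = (N - 1) r0` and persistence length
#' `lp = -r0 / log(<cos delta>)`, where `<cos delta>` is the exact mean
#' cosine of the bend angle under the Boltzmann weight
#' `sin(delta) exp(-K_theta delta^2 / kT)`.
#'
#' @param n_beads chain length in beads.
#' @param model an [interaction_model()].
#' @param temperature K.
#' @return list with `rg` (A), `lp` (A), `contour` (A), `mean_cos`.
#' @export
wlc_rg_theory <- function(n_beads, model = interaction_model(),
                          temperature = 300) {
  beta <- 1 / (.kB * temperature)
  d <- seq(0, pi, length.out = 20001)
  w <- sin(d) * exp(-beta * model$k_angle * d^2)
  mc <- sum(w * cos(d)) / sum(w)
  lp <- -model$r0 / log(mc)
  L <- (n_beads - 1) * model$r0
  x <- L / lp
  rg2 <- lp * L / 3 - lp^2 + 2 * lp^3 / L * (1 - lp / L * (1 - exp(-x)))
  list(rg = sqrt(rg2), lp = lp, contour = L, mean_cos = mc)
}
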