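# Force field: harmonic bonds, harmonic angles, and the Ashbaugh-Hatch
# nonbonded pair potential with arithmetic-mean sigma combination.

#' Define the coarse-grained interaction model
#'
#' Bundles every force-field parameter: per-species bead sizes and masses,
#' the hydropathy matrix `lambda` scaling the attractive branch of the
#' Ashbaugh-Hatch pair potential, the global well depth `epsilon`, harmonic
#' bond and angle constants for DNA, the pair cutoff (as a multiple of the
#' pair sigma), and the bonded-exclusion policy.
#'
#' Defaults are the condensate model parameters: protein beads of diameter
#' 50 A and mass 5000 g/mol, DNA beads (one per base pair) of diameter 5 A
#' and mass 500 g/mol, `epsilon` = 0.2 kcal/mol, bond constant
#' 20 kcal/mol/A^2 with equilibrium length 5.5 A, angle constant
#' 20 kcal/mol/rad^2 with equilibrium angle pi, and DNA-DNA interactions made
#' purely repulsive via `lambda_dd = -1`.  Pair sigmas combine by arithmetic
#' mean, so sigma_PD = 27.5 A.
#'
#' @param lambda_pp protein-protein (homotypic) hydropathy.
#' @param lambda_pd protein-DNA (heterotypic) hydropathy.
#' @param lambda_dd DNA-DNA hydropathy (default -1, purely repulsive).
#' @param epsilon pair well depth, kcal/mol.
#' @param k_bond bond spring constant, kcal/mol/A^2 (no 1/2 prefactor:
#'   U = k_bond (r - r0)^2).
#' @param r0 equilibrium bond length, A.
#' @param k_angle angle spring constant, kcal/mol/rad^2 (no 1/2 prefactor).
#' @param theta0 equilibrium angle, rad.
#' @param cutoff_factor pair cutoff as a multiple of the pair sigma; the
#'   potential is shifted so it vanishes at the cutoff.
#' @param species data.frame with columns `name`, `sigma` (A), `mass`
#'   (g/mol); rows must be P then D for the default mixed system.
#' @param lambda optional full hydropathy matrix (overrides the three
#'   scalar lambdas); must be symmetric with dimnames matching species.
#' @param exclude_bonded exclude nonbonded interactions between 1-2 and 1-3
#'   bonded neighbors (default TRUE).
#' @return an object of class `interaction_model`.
#' @examples
#' m <- interaction_model(lambda_pp = 2, lambda_pd = 0.5)
#' m$lambda
#' @export
interaction_model <- function(lambda_pp = 1, lambda_pd = 1, lambda_dd = -1,
                              epsilon = 0.2,
                              k_bond = 20, r0 = 5.5,
                              k_angle = 20, theta0 = pi,
                              cutoff_factor = 3,
                              species = data.frame(
                                name = c("P", "D"),
                                sigma = c(50, 5),
                                mass = c(5000, 500),
                                stringsAsFactors = FALSE),
                              lambda = NULL,
                              exclude_bonded = TRUE) {
  stopifnot(all(species$sigma > 0), all(species$mass > 0),
            epsilon > 0, k_bond >= 0, k_angle >= 0, r0 > 0,
            theta0 > 0, theta0 <= pi,
            cutoff_factor > 2^(1 / 6))
  ns <- nrow(species)
  if (is.null(lambda)) {
    if (ns != 2L)
      stop("scalar lambdas require exactly two species; supply `lambda`")
    lambda <- matrix(c(lambda_pp, lambda_pd, lambda_pd, lambda_dd), 2, 2)
  }
  lambda <- as.matrix(lambda)
  if (!isTRUE(all.equal(lambda, t(lambda))))
    stop("lambda matrix must be symmetric")
  dimnames(lambda) <- list(species$name, species$name)
  sigma_mat <- outer(species$sigma, species$sigma, function(a, b) (a + b) / 2)
  dimnames(sigma_mat) <- dimnames(lambda)
  structure(list(species = species, lambda = lambda, sigma_matrix = sigma_mat,
                 epsilon = epsilon, k_bond = k_bond, r0 = r0,
                 k_angle = k_angle, theta0 = theta0,
                 cutoff_factor = cutoff_factor,
                 exclude_bonded = isTRUE(exclude_bonded)),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("Coarse-grained interaction model\n")
  cat("  species:\n")
  print(x$species, row.names = FALSE)
  cat("  epsilon:", x$epsilon, "kcal/mol   cutoff:", x$cutoff_factor,
      "sigma_ij\n")
  cat("  bonds:  U = ", x$k_bond, " (r - ", x$r0, ")^2\n", sep = "")
  cat("  angles: U = ", x$k_angle, " (theta - ", round(x$theta0, 4),
      ")^2\n", sep = "")
  cat("  lambda matrix:\n")
  print(x$lambda)
  invisible(x)
}

# model fields in the layout the C++ kernels expect
.model_cpp <- function(model) {
  list(sigma = model$species$sigma, lambda = unname(model$lambda),
       epsilon = model$epsilon, cutoff_factor = model$cutoff_factor,
       k_bond = model$k_bond, r0 = model$r0,
       k_angle = model$k_angle, theta0 = model$theta0)
}

#' Harmonic bond energy and force
#'
#' `U(r) = k_bond (r - r0)^2` (note: no 1/2 prefactor).  The returned force
#' is the scalar magnitude along the bond, `f = -dU/dr = -2 k_bond (r - r0)`.
#'
#' @param r bond length(s), A; must be positive.
#' @param params an `interaction_model` (or any list with `k_bond`, `r0`).
#' @return list with components `energy` and `force` (vectors like `r`).
#' @export
bond_energy_force <- function(r, params) {
  if (any(r <= 0)) stop("invalid geometry: non-positive bond length")
  d <- r - params$r0
  list(energy = params$k_bond * d^2, force = -2 * params$k_bond * d)
}

#' Harmonic angle energy and Cartesian forces
#'
#' `U(theta) = k_angle (theta - theta0)^2` with `theta0 = pi` for DNA
#' (no 1/2 prefactor).  Given the positions of the three beads (the middle
#' row is the vertex), returns the energy and the 3x3 matrix of Cartesian
#' forces, which sum to zero and carry no net torque.
#'
#' @param theta angle(s) in radians, or NULL if `positions` given.
#' @param params an `interaction_model` (or list with `k_angle`, `theta0`).
#' @param positions optional 3x3 matrix of bead positions (rows i, j, k with
#'   j the vertex); when supplied, forces are returned.
#' @return with `theta`: list(energy).  With `positions`: list(energy,
#'   theta, forces).
#' @export
angle_energy_force <- function(theta = NULL, params, positions = NULL) {
  if (is.null(positions)) {
    # angles slightly beyond pi (reflex notation) are accepted: the
    # quadratic form is symmetric about theta0 = pi
    stopifnot(all(theta >= 0), all(theta <= 2 * pi))
    return(list(energy = params$k_angle * (theta - params$theta0)^2))
  }
  a <- positions[1, ] - positions[2, ]
  b <- positions[3, ] - positions[2, ]
  ra <- sqrt(sum(a^2)); rb <- sqrt(sum(b^2))
  cc <- min(1, max(-1, sum(a * b) / (ra * rb)))
  s <- max(sqrt(1 - cc^2), 1e-8)
  th <- acos(cc)
  dU <- 2 * params$k_angle * (th - params$theta0)
  coef <- -dU / s
  fi <- -coef * (b / (ra * rb) - cc * a / ra^2)
  fk <- -coef * (a / (ra * rb) - cc * b / rb^2)
  forces <- rbind(fi, -(fi + fk), fk)
  rownames(forces) <- NULL
  list(energy = params$k_angle * (th - params$theta0)^2, theta = th,
       forces = forces)
}

#' Ashbaugh-Hatch pair energy and force
#'
#' The hydropathy-scaled Lennard-Jones potential: for r below `2^(1/6) sigma`
#' the full LJ core plus the offset `(1 - lambda) epsilon`; beyond the
#' minimum, `lambda` times the LJ tail.  Both branches meet continuously at
#' `-lambda epsilon`.  `lambda` may be negative (purely repulsive) or exceed
#' one.  The energy is shifted so that it vanishes at the cutoff, and is
#' zero beyond it.
#'
#' @param r separation(s), A; positive.
#' @param sigma pair diameter, A.
#' @param lambda hydropathy scaling of the attractive branch.
#' @param epsilon well depth, kcal/mol.
#' @param cutoff cutoff distance, A (must exceed `2^(1/6) sigma`); use
#'   `Inf` for the unshifted potential.
#' @return list with `energy` and `force` (`f = -dU/dr`), zero beyond the
#'   cutoff.
#' @examples
#' # at the LJ minimum the potential is -lambda * epsilon (unshifted)
#' pair_energy_force(2^(1/6) * 50, 50, 1, 0.2, Inf)$energy
#' @export
pair_energy_force <- function(r, sigma, lambda, epsilon, cutoff) {
  if (any(r <= 0)) stop("overlap: non-positive pair distance")
  stopifnot(cutoff > 2^(1 / 6) * sigma)
  sr6 <- (sigma / r)^6
  ulj <- 4 * epsilon * (sr6^2 - sr6)
  flj <- 4 * epsilon * (12 * sr6^2 - 6 * sr6) / r
  shift <- if (is.finite(cutoff)) {
    s6 <- (sigma / cutoff)^6
    lambda * 4 * epsilon * (s6^2 - s6)
  } else 0
  core <- r <= 2^(1 / 6) * sigma
  u <- ifelse(core, ulj + (1 - lambda) * epsilon, lambda * ulj) - shift
  f <- ifelse(core, flj, lambda * flj)
  u[r > cutoff] <- 0
  f[r > cutoff] <- 0
  list(energy = u, force = f)
}

#' Total potential energy of a configuration
#'
#' Evaluates every force-field term (bond, angle, nonbonded pair) for one
#' configuration and returns the per-term breakdown, the total, and the
#' Cartesian forces.  Nonbonded interactions between 1-2 and 1-3 bonded
#' neighbors are excluded when the model says so.
#'
#' @param config a `cg_configuration` (see [configuration()]).
#' @param topology a `cg_topology` (see [topology()]).
#' @param model an [interaction_model()].
#' @return list with `bond`, `angle`, `pair`, `total` (kcal/mol) and
#'   `forces` (N x 3, kcal/mol/A).
#' @export
total_energy <- function(config, topology, model) {
  n <- nrow(config$pos)
  check_topology(topology, n)
  excl <- if (model$exclude_bonded) bonded_exclusions(topology) else
    matrix(integer(0), 0, 2)
  cpp_energy_forces(config$pos, topology$type - 1L, .model_cpp(model),
                    zero_index(topology$bonds), zero_index(topology$angles),
                    zero_index(excl), config$box)
}

# 1-based R matrices -> 0-based integer matrices for C++
zero_index <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m)) m - 1L else m
}

#' Bonded exclusion pairs (1-2 and 1-3 neighbors)
#' @param topology a `cg_topology`.
#' @return two-column integer matrix of 1-based particle pairs.
#' @export
bonded_exclusions <- function(topology) {
  b <- topology$bonds
  a <- topology$angles
  ex <- rbind(b, if (nrow(a)) a[, c(1, 3), drop = FALSE])
  if (is.null(ex) || !nrow(ex)) return(matrix(integer(0), 0, 2))
  ex <- t(apply(ex, 1, sort))
  unique(ex)
}

check_topology <- function(topology, n) {
  idx <- c(topology$bonds, topology$angles)
  if (length(idx) && (max(idx) > n || min(idx) < 1))
    stop("topology references missing particles")
  if (length(topology$type) != n)
    stop("type vector length does not match configuration")
  invisible(TRUE)
}
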