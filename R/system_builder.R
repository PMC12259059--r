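# System builders: topologies and initial configurations for protein-only,
# DNA-only and mixed systems at 1:1 protein:DNA-bead stoichiometry.

#' Particle topology
#'
#' Species index, molecule id, bond list and angle list for a system.
#' Proteins are single beads with no bonded terms; a DNA chain of L beads
#' contributes L-1 bonds and L-2 angles.
#'
#' @param type integer species index per particle (1-based into
#'   `species_names`).
#' @param molecule integer molecule id per particle; ids partition particles.
#' @param bonds two-column integer matrix of bonded pairs (1-based).
#' @param angles three-column integer matrix of angle triplets (vertex in
#'   the middle).
#' @param species_names character vector naming the species.
#' @return object of class `cg_topology`.
#' @export
topology <- function(type, molecule, bonds = matrix(integer(0), 0, 2),
                     angles = matrix(integer(0), 0, 3),
                     species_names = c("P", "D")) {
  type <- as.integer(type); molecule <- as.integer(molecule)
  stopifnot(length(type) == length(molecule))
  structure(list(type = type, molecule = molecule,
                 bonds = as.matrix(bonds), angles = as.matrix(angles),
                 species_names = species_names),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", length(x$type), "particles,",
      length(unique(x$molecule)), "molecules,",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles\n")
  tab <- table(x$species_names[x$type])
  cat("  composition:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' One trajectory frame
#'
#' Positions are stored wrapped into the primary box `[0, box)` with integer
#' image flags so unwrapped coordinates `pos + img * box` are always
#' recoverable.
#'
#' @param pos N x 3 numeric matrix of positions (A); wrapped on input, with
#'   any wrapping absorbed into the image flags.
#' @param box cubic box edge (A).
#' @param img N x 3 integer image-flag matrix (default zero).
#' @param step integer MD step of the frame.
#' @param time_fs simulation time of the frame, fs.
#' @return object of class `cg_configuration`.
#' @export
configuration <- function(pos, box, img = NULL, step = 0L, time_fs = 0) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, box > 0)
  if (is.null(img)) img <- matrix(0L, nrow(pos), 3)
  wrap <- floor(pos / box)
  pos <- pos - wrap * box
  img <- img + wrap
  storage.mode(img) <- "integer"
  structure(list(pos = pos, img = img, box = box, step = as.integer(step),
                 time_fs = time_fs),
            class = "cg_configuration")
}

#' Unwrapped coordinates of a configuration
#' @param config a `cg_configuration`.
#' @return N x 3 matrix `pos + img * box`.
#' @export
unwrap_positions <- function(config) config$pos + config$img * config$box

#' System specification for the mixture builder
#'
#' In stoichiometric mode the number of protein beads equals the total
#' number of DNA beads (`dna_length * n_dna_chains`), the protocol used for
#' every mixed condensate system.
#'
#' @param n_protein number of protein beads; defaults to
#'   `dna_length * n_dna_chains` (1:1 bead stoichiometry).
#' @param dna_length DNA chain length in base pairs (beads).
#' @param n_dna_chains number of DNA chains.
#' @param box_edge cubic box edge, A.
#' @param seed integer seed for placement.
#' @param placement one of `"central-random"` (all molecules inside the
#'   central cube of half the box edge, the condensate-seeding protocol),
#'   `"uniform-random"`, or `"lattice"`.
#' @return object of class `system_spec`.
#' @export
system_spec <- function(n_protein = NULL, dna_length = 250L,
                        n_dna_chains = 20L, box_edge = 2000,
                        seed = 1L,
                        placement = c("central-random", "uniform-random",
                                      "lattice")) {
  placement <- match.arg(placement)
  if (is.null(n_protein)) n_protein <- dna_length * n_dna_chains
  stopifnot(box_edge > 0, n_protein >= 0, n_dna_chains >= 0)
  if (n_dna_chains > 0) stopifnot(dna_length >= 2)
  structure(list(n_protein = as.integer(n_protein),
                 dna_length = as.integer(dna_length),
                 n_dna_chains = as.integer(n_dna_chains),
                 box_edge = box_edge, seed = as.integer(seed),
                 placement = placement),
            class = "system_spec")
}

#' Build one straight DNA chain
#'
#' Beads spaced at the equilibrium bond length along `direction`, with
#' bonds and angles enumerated in order, so the bonded energy of the
#' returned fragment is exactly zero.
#'
#' @param length chain length in beads (>= 2).
#' @param start position of the first bead.
#' @param direction chain direction (normalized internally).
#' @param r0 bead spacing, A.
#' @return list with `pos` (length x 3), `bonds` (1-based, local indices),
#'   `angles`.
#' @export
build_dna_chain <- function(length, start = c(0, 0, 0),
                            direction = c(0, 0, 1), r0 = 5.5) {
  if (length < 2) stop("invalid spec: DNA chain needs at least 2 beads")
  u <- direction / sqrt(sum(direction^2))
  pos <- outer((seq_len(length) - 1) * r0, u) +
    matrix(start, length, 3, byrow = TRUE)
  bonds <- cbind(seq_len(length - 1L), seq_len(length - 1L) + 1L)
  angles <- if (length >= 3)
    cbind(seq_len(length - 2L), seq_len(length - 2L) + 1L,
          seq_len(length - 2L) + 2L)
  else matrix(integer(0), 0, 3)
  list(pos = pos, bonds = bonds, angles = angles)
}

#' Build a protein/DNA mixture
#'
#' Places `n_protein` protein beads and `n_dna_chains` worm-like DNA chains
#' (equilibrium conformations from [sample_wlc_chain()], randomly rotated)
#' according to the placement mode, then removes overlaps with a short
#' force-capped Langevin relaxation ramp.  `"central-random"` places all
#' molecule centers inside the central cube of half the box edge, seeding a
#' single condensate.  Deterministic for a fixed spec seed.
#'
#' @param spec a [system_spec()].
#' @param model an [interaction_model()].
#' @param relax_steps steps per stage of the capped relaxation ramp.
#' @param max_tries placement retries before giving up.
#' @return list with `topology` (`cg_topology`) and `config`
#'   (`cg_configuration`).
#' @export
build_mixture <- function(spec, model = interaction_model(),
                          relax_steps = 1000L, max_tries = 5L) {
  for (try in seq_len(max_tries)) {
    set.seed(spec$seed + (try - 1L) * 1000003L)
    built <- .place_molecules(spec, model)
    relaxed <- .relax_overlaps(built$topology, built$config, model,
                               relax_steps)
    ratio <- min_pair_distance_ratio(relaxed, built$topology, model)
    if (is.na(ratio) || ratio >= 0.8)
      return(list(topology = built$topology, config = relaxed))
  }
  stop("placement failure: could not reach the overlap floor after ",
       max_tries, " tries (density too high?)")
}

.place_molecules <- function(spec, model) {
  box <- spec$box_edge
  region <- switch(spec$placement,
                   "central-random" = c(box / 4, 3 * box / 4),
                   "uniform-random" = c(0, box),
                   "lattice" = c(0, box))
  np <- spec$n_protein; nc <- spec$n_dna_chains; L <- spec$dna_length
  n <- np + nc * L
  pos <- matrix(0, n, 3)
  type <- integer(n); mol <- integer(n)
  bonds <- vector("list", nc); angles <- vector("list", nc)
  if (np > 0) {
    if (spec$placement == "lattice") {
      k <- ceiling(np^(1 / 3))
      g <- (seq_len(k) - 0.5) / k * box
      grid <- as.matrix(expand.grid(g, g, g))[seq_len(np), , drop = FALSE]
      pos[seq_len(np), ] <- grid
    } else {
      pos[seq_len(np), ] <- matrix(runif(np * 3, region[1], region[2]),
                                   np, 3)
    }
    type[seq_len(np)] <- 1L
    mol[seq_len(np)] <- seq_len(np)
  }
  at <- np
  for (c in seq_len(nc)) {
    chain <- sample_wlc_chain(L, model)
    chain <- scale(chain, center = TRUE, scale = FALSE)  # COM at origin
    rot <- .random_rotation()
    com <- runif(3, region[1], region[2])
    idx <- at + seq_len(L)
    pos[idx, ] <- sweep(chain %*% rot, 2, com, `+`)
    type[idx] <- 2L
    mol[idx] <- np + c
    bonds[[c]] <- cbind(idx[-L], idx[-1])
    angles[[c]] <- if (L >= 3) cbind(idx[1:(L - 2)], idx[2:(L - 1)],
                                     idx[3:L]) else matrix(integer(0), 0, 3)
    at <- at + L
  }
  all_bonds <- if (nc > 0) do.call(rbind, bonds) else
    matrix(integer(0), 0, 2)
  all_angles <- if (nc > 0) do.call(rbind, angles) else
    matrix(integer(0), 0, 3)
  topo <- topology(type, mol, all_bonds, all_angles)
  list(topology = topo, config = configuration(pos, box))
}

.random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))[col(q)]
}

# capped-force Langevin ramp to push overlapping beads apart
.relax_overlaps <- function(topo, config, model, relax_steps) {
  state <- config
  # capped ramp at 300 K, then a short cool quench that settles marginal
  # contacts into their local minima before production re-thermalizes
  stages <- list(c(300, 5), c(300, 20), c(300, 100), c(60, 100))
  for (st in stages) {
    run <- run_simulation(topo, state, model,
                          params = thermostat_params(temperature = st[1],
                                                     t_damp_ps = 10,
                                                     dt_fs = 5, seed = 12345L),
                          n_steps = relax_steps, cadence = relax_steps,
                          force_cap = st[2], quiet = TRUE)
    state <- get_frame(run, n_frames(run))
  }
  state
}

#' Minimum pair distance relative to the pair diameter
#'
#' Scans all nonbonded (non-excluded) pairs and returns the minimum of
#' `d_ij / sigma_ij`; `NA` when no pair is within 1.2 sigma of another.
#'
#' @param config a `cg_configuration`.
#' @param topology a `cg_topology`.
#' @param model an [interaction_model()].
#' @return scalar ratio (or NA).
#' @export
min_pair_distance_ratio <- function(config, topology, model) {
  smax <- max(model$sigma_matrix)
  pairs <- cpp_neighbor_pairs(config$pos, config$box, 1.2 * smax)
  if (!nrow(pairs)) return(NA_real_)
  ex <- bonded_exclusions(topology)
  if (nrow(ex)) {
    n <- nrow(config$pos)
    exk <- ex[, 1] * n + ex[, 2]
    pk <- pmin(pairs[, 1], pairs[, 2]) * n + pmax(pairs[, 1], pairs[, 2])
    pairs <- pairs[!(pk %in% exk), , drop = FALSE]
    if (!nrow(pairs)) return(NA_real_)
  }
  d <- sqrt(rowSums(.min_image(config$pos[pairs[, 1], , drop = FALSE] -
                               config$pos[pairs[, 2], , drop = FALSE],
                               config$box)^2))
  sij <- model$sigma_matrix[cbind(topology$type[pairs[, 1]],
                                  topology$type[pairs[, 2]])]
  ok <- d <= 1.2 * sij
  if (!any(ok)) return(NA_real_)
  min(d[ok] / sij[ok])
}

.min_image <- function(d, box) d - box * round(d / box)

#' Load a bundled equilibrated condensate state
#'
#' Reads one of the plain-text equilibrated snapshots shipped with the
#' package (see `inst/extdata`).  The file stores unwrapped coordinates for
#' 500 proteins followed by two 250-bead DNA chains in bonded order, plus
#' the box edge; the bonded topology is reconstructed here.  These states
#' were prepared with the package itself (build, strong-coupling collapse
#' anneal, re-equilibration at the target Hamiltonian) and serve as
#' starting points for observables whose de novo equilibration exceeds
#' desk scale.
#'
#' @param name file name under the package's `extdata` directory.
#' @param n_protein,dna_length,n_dna_chains layout of the stored system.
#' @return list with `topology` and `config`.
#' @export
read_equilibrated_state <- function(name, n_protein = 500L,
                                    dna_length = 250L,
                                    n_dna_chains = 2L) {
  path <- system.file("extdata", name, package = "condensr")
  if (!nzchar(path)) stop("no bundled state named ", name)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  box <- as.numeric(sub("^box ", "", lines[startsWith(lines, "box")]))
  coords <- lines[!startsWith(lines, "box")]
  pos <- do.call(rbind, lapply(strsplit(coords, " "), as.numeric))
  n <- n_protein + dna_length * n_dna_chains
  if (nrow(pos) != n) stop("unexpected bead count in ", name)
  type <- c(rep(1L, n_protein), rep(2L, dna_length * n_dna_chains))
  mol <- c(seq_len(n_protein),
           rep(n_protein + seq_len(n_dna_chains), each = dna_length))
  bonds <- NULL; angles <- NULL
  for (c in seq_len(n_dna_chains)) {
    off <- n_protein + (c - 1L) * dna_length
    idx <- off + seq_len(dna_length)
    bonds <- rbind(bonds, cbind(idx[-dna_length], idx[-1]))
    angles <- rbind(angles, cbind(idx[1:(dna_length - 2)],
                                  idx[2:(dna_length - 1)],
                                  idx[3:dna_length]))
  }
  list(topology = topology(type, mol, bonds, angles),
       config = configuration(pos, box))
}

#' Deterministic tiny test systems
#'
#' Registered fixtures:
#' \describe{
#'   \item{`dimer`}{two protein beads at the pair-potential minimum
#'     `2^(1/6) sigma_P`.}
#'   \item{`one-chain-20bp`}{one straight 20-bead DNA chain (19 bonds, 18
#'     angles) at equilibrium spacing.}
#'   \item{`mini-condensate`}{200 proteins + 4 x 50 bp DNA (400 beads,
#'     stoichiometric) centrally placed in a 600 A box.}
#' }
#'
#' @param name fixture name.
#' @param model an [interaction_model()].
#' @return list with `topology` and `config`.
#' @export
make_fixture <- function(name, model = interaction_model()) {
  switch(name,
    "dimer" = {
      sp <- model$species$sigma[1]
      pos <- rbind(c(100, 100, 100), c(100 + 2^(1 / 6) * sp, 100, 100))
      list(topology = topology(c(1L, 1L), c(1L, 2L)),
           config = configuration(pos, 400))
    },
    "one-chain-20bp" = {
      ch <- build_dna_chain(20, start = c(100, 100, 100), r0 = model$r0)
      list(topology = topology(rep(2L, 20), rep(1L, 20), ch$bonds,
                               ch$angles),
           config = configuration(ch$pos, 400))
    },
    "mini-condensate" = build_mixture(
      system_spec(n_protein = 200L, dna_length = 50L, n_dna_chains = 4L,
                  box_edge = 600, seed = 42L,
                  placement = "central-random"),
      model),
    stop("unknown fixture name: ", name))
}
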