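# Independent oracles used across the suite.  These deliberately avoid the
# package's own kernels: brute-force double loops, BFS on a full distance
# matrix, and central finite differences.

kB <- 0.0019872041

min_image_o <- function(d, box) d - box * round(d / box)

# Ashbaugh-Hatch pair energy, written independently of the package
ah_energy_o <- function(r, sigma, lambda, epsilon, cutoff) {
  ulj <- function(x) 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6)
  u <- if (r <= 2^(1 / 6) * sigma) ulj(r) + (1 - lambda) * epsilon
       else lambda * ulj(r)
  if (is.finite(cutoff)) {
    if (r > cutoff) return(0)
    u <- u - lambda * ulj(cutoff)
  }
  u
}

# O(N^2) total-energy oracle with bonded exclusions
total_energy_o <- function(config, topo, model) {
  pos <- config$pos; box <- config$box; n <- nrow(pos)
  excl <- matrix(FALSE, n, n)
  b <- topo$bonds
  for (q in seq_len(nrow(b))) excl[b[q, 1], b[q, 2]] <- excl[b[q, 2], b[q, 1]] <- TRUE
  a <- topo$angles
  for (q in seq_len(nrow(a))) excl[a[q, 1], a[q, 3]] <- excl[a[q, 3], a[q, 1]] <- TRUE
  e_pair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (model$exclude_bonded && excl[i, j]) next
    d <- sqrt(sum(min_image_o(pos[i, ] - pos[j, ], box)^2))
    ti <- topo$type[i]; tj <- topo$type[j]
    sig <- model$sigma_matrix[ti, tj]
    e_pair <- e_pair + ah_energy_o(d, sig, model$lambda[ti, tj],
                                   model$epsilon,
                                   model$cutoff_factor * sig)
  }
  e_bond <- 0
  for (q in seq_len(nrow(b))) {
    d <- sqrt(sum(min_image_o(pos[b[q, 1], ] - pos[b[q, 2], ], box)^2))
    e_bond <- e_bond + model$k_bond * (d - model$r0)^2
  }
  e_angle <- 0
  for (q in seq_len(nrow(a))) {
    v1 <- min_image_o(pos[a[q, 1], ] - pos[a[q, 2], ], box)
    v2 <- min_image_o(pos[a[q, 3], ] - pos[a[q, 2], ], box)
    th <- acos(min(1, max(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2)))))
    e_angle <- e_angle + model$k_angle * (th - model$theta0)^2
  }
  list(bond = e_bond, angle = e_angle, pair = e_pair,
       total = e_bond + e_angle + e_pair)
}

# central finite-difference gradient of the total energy w.r.t. positions
fd_forces_o <- function(config, topo, model, h = 1e-5) {
  n <- nrow(config$pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    cp <- config; cp$pos[i, d] <- cp$pos[i, d] + h
    cm <- config; cm$pos[i, d] <- cm$pos[i, d] - h
    ep <- total_energy(cp, topo, model)$total
    em <- total_energy(cm, topo, model)$total
    f[i, d] <- -(ep - em) / (2 * h)
  }
  f
}

# brute-force BFS molecule clustering oracle
clusters_bfs_o <- function(config, topo, cutoff) {
  pos <- config$pos; box <- config$box
  mols <- sort(unique(topo$molecule))
  nm <- length(mols)
  adj <- matrix(FALSE, nm, nm)
  midx <- match(topo$molecule, mols)
  n <- nrow(pos)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (midx[i] == midx[j]) next
    d <- sqrt(sum(min_image_o(pos[i, ] - pos[j, ], box)^2))
    if (d <= cutoff) adj[midx[i], midx[j]] <- adj[midx[j], midx[i]] <- TRUE
  }
  comp <- rep(0L, nm); cur <- 0L
  for (s in seq_len(nm)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# random small mixed configuration for oracle comparisons
random_config_o <- function(n_protein, n_dna_beads, box, seed) {
  set.seed(seed)
  n <- n_protein + n_dna_beads
  pos <- matrix(runif(3 * n, 0, box), n, 3)
  type <- c(rep(1L, n_protein), rep(2L, n_dna_beads))
  topo <- topology(type, seq_len(n))
  list(config = configuration(pos, box), topology = topo)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
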