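# Structural observables: molecule-level clustering, largest-cluster
# composition, DNA radius of gyration, persistence length, DNA-bound
# protein fraction, radial density profiles with tanh interface fits,
# coexistence concentrations, and block averaging.

#' Block statistics for a time series
#'
#' Splits the series into `n_blocks` equal blocks, discards the leading
#' `discard_fraction` of blocks for equilibration (default: the first of
#' five blocks, i.e. the initial 20 percent of the data), and reports the
#' mean of the remaining block means with its standard error over blocks.
#'
#' @param series numeric vector (one value per frame).
#' @param n_blocks number of equal blocks (>= 2).
#' @param discard_fraction fraction of blocks discarded from the start, in
#'   `[0, 1)`.
#' @return object of class `block_stats`: list(mean, se, n_blocks,
#'   discard_fraction, block_means).
#' @export
block_average <- function(series, n_blocks = 5L, discard_fraction = 0.2) {
  stopifnot(n_blocks >= 2, discard_fraction >= 0, discard_fraction < 1)
  n <- length(series)
  if (n < n_blocks) stop("series too short for ", n_blocks, " blocks")
  idx <- floor(seq_len(n) / (n + 1e-9) * n_blocks) + 1L   # block of each pt
  means <- tapply(series, idx, mean)
  drop <- floor(n_blocks * discard_fraction + 1e-9)
  keep <- means[seq.int(drop + 1L, n_blocks)]
  if (length(keep) < 1) stop("all blocks discarded")
  se <- if (length(keep) > 1) stats::sd(keep) / sqrt(length(keep)) else NA_real_
  structure(list(mean = mean(keep), se = se, n_blocks = length(keep),
                 discard_fraction = discard_fraction,
                 block_means = unname(keep)),
            class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf("block mean = %.6g +/- %.3g (SE over %d blocks)\n",
              x$mean, x$se, x$n_blocks))
  invisible(x)
}

#' Molecule-level cluster analysis
#'
#' Two molecules belong to the same cluster when any bead of one lies
#' within `cutoff` of any bead of the other under the minimum-image
#' convention; clusters are the connected components of that contact
#' graph.  The default cutoff is `1.5 sigma_PD` (41.25 A for the standard
#' bead sizes), applied to all species pairs.
#'
#' With `criterion = "fixed"` (the default) the single literal cutoff is
#' used for every species pair.  Note that this cutoff is smaller than the
#' protein-protein contact distance `2^(1/6) sigma_P ~ 56` A, so it sees
#' DNA-scaffolded clusters (protein-DNA contacts sit at ~31 A) but cannot
#' connect two touching proteins; `criterion = "contact"` instead connects
#' beads within `1.5 sigma_ij` of each other per species pair (75 A for
#' P-P, 41.25 A for P-D), which resolves protein-only condensates and is
#' the default for trajectory-level observables.
#'
#' @param config a `cg_configuration`.
#' @param topology a `cg_topology`.
#' @param cutoff contact cutoff, A; default `1.5 * sigma_PD` from `model`.
#' @param model an [interaction_model()] (for the default cutoffs).
#' @param criterion `"fixed"` (one cutoff for all pairs) or `"contact"`
#'   (per-pair `1.5 sigma_ij`; `cutoff` is ignored).
#' @return object of class `cluster_result`: `cluster` (id per molecule,
#'   names = molecule ids), `largest` (molecule ids of the largest
#'   cluster), `protein_fraction`, `dna_fraction` (fractions of protein
#'   molecules / DNA chains in the largest cluster), plus bead-count
#'   fractions `protein_bead_fraction`, `dna_bead_fraction`.
#' @export
find_clusters <- function(config, topology, cutoff = NULL,
                          model = interaction_model(),
                          criterion = c("fixed", "contact")) {
  criterion <- match.arg(criterion)
  if (is.null(cutoff)) cutoff <- 1.5 * model$sigma_matrix["P", "D"]
  stopifnot(cutoff > 0)
  mols <- sort(unique(topology$molecule))
  nm <- length(mols)
  mol_idx <- match(topology$molecule, mols)
  search_cut <- if (criterion == "contact")
    1.5 * max(model$sigma_matrix) else cutoff
  pairs <- cpp_neighbor_pairs(config$pos, config$box, search_cut)
  if (criterion == "contact" && nrow(pairs)) {
    d <- sqrt(rowSums(.min_image(config$pos[pairs[, 1], , drop = FALSE] -
                                 config$pos[pairs[, 2], , drop = FALSE],
                                 config$box)^2))
    sij <- model$sigma_matrix[cbind(topology$type[pairs[, 1]],
                                    topology$type[pairs[, 2]])]
    pairs <- pairs[d <= 1.5 * sij, , drop = FALSE]
  }
  parent <- seq_len(nm)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (nrow(pairs)) {
    mp <- cbind(mol_idx[pairs[, 1]], mol_idx[pairs[, 2]])
    mp <- mp[mp[, 1] != mp[, 2], , drop = FALSE]
    for (q in seq_len(nrow(mp))) {
      ra <- find(mp[q, 1]); rb <- find(mp[q, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(nm), find, integer(1))
  cl <- match(root, unique(root))
  sizes <- tabulate(cl)
  big <- which.max(sizes)
  is_protein_mol <- tapply(topology$type == 1L, mol_idx, all)
  in_big <- cl == big
  npro <- sum(is_protein_mol); ndna <- nm - npro
  beads_in_big <- mol_idx %in% which(in_big)
  structure(list(
    cluster = setNames(cl, mols),
    largest = mols[in_big],
    protein_fraction = if (npro) sum(in_big & is_protein_mol) / npro else NA_real_,
    dna_fraction = if (ndna) sum(in_big & !is_protein_mol) / ndna else NA_real_,
    protein_bead_fraction = if (npro) sum(beads_in_big & topology$type == 1L) /
      sum(topology$type == 1L) else NA_real_,
    dna_bead_fraction = if (ndna) sum(beads_in_big & topology$type == 2L) /
      sum(topology$type == 2L) else NA_real_,
    criterion = criterion,
    cutoff = if (criterion == "contact") NA_real_ else cutoff),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("clusters: %d (largest: %d molecules); protein fraction %.3f, DNA fraction %.3f\n",
              max(x$cluster), length(x$largest), x$protein_fraction,
              x$dna_fraction))
  invisible(x)
}

#' Largest-cluster composition over a trajectory
#'
#' Per-frame fraction of protein molecules (and DNA chains) in the largest
#' cluster, block-averaged.  This is the observable gridded over
#' (lambda_PP, lambda_PD) in condensate phase diagrams.
#'
#' @param traj a `cg_trajectory` (>= 2 frames).
#' @param cutoff contact cutoff, A (default `1.5 sigma_PD`).
#' @param n_blocks,discard_fraction passed to [block_average()].
#' @param count `"molecules"` (default) or `"beads"`.
#' @param criterion cluster criterion (see [find_clusters()]); trajectory
#'   observables default to the per-pair `"contact"` form, which resolves
#'   protein-only condensates.
#' @return list with `protein` and `dna` (`block_stats`), and `per_frame`
#'   data.frame(frame, step, protein_fraction, dna_fraction).
#' @export
largest_cluster_fractions <- function(traj, cutoff = NULL, n_blocks = 5L,
                                      discard_fraction = 0.2,
                                      count = c("molecules", "beads"),
                                      criterion = c("contact", "fixed")) {
  count <- match.arg(count)
  criterion <- match.arg(criterion)
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 analysis frames")
  model <- if (!is.null(traj$model)) traj$model else interaction_model()
  pf <- df <- numeric(nf); steps <- integer(nf)
  for (i in seq_len(nf)) {
    cl <- find_clusters(get_frame(traj, i), traj$topology, cutoff, model,
                        criterion)
    pf[i] <- if (count == "molecules") cl$protein_fraction else
      cl$protein_bead_fraction
    df[i] <- if (count == "molecules") cl$dna_fraction else
      cl$dna_bead_fraction
    steps[i] <- traj$frames[[i]]$step
  }
  list(protein = block_average(pf, n_blocks, discard_fraction),
       dna = if (!all(is.na(df)))
         block_average(df, n_blocks, discard_fraction) else NULL,
       per_frame = data.frame(frame = seq_len(nf), step = steps,
                              protein_fraction = pf, dna_fraction = df))
}

#' Radius of gyration of one chain
#'
#' Standard root-mean-square distance of beads from the chain centroid
#' (equal bead masses).  Input must be unwrapped coordinates (a chain made
#' whole through periodic images).
#'
#' @param pos L x 3 matrix of unwrapped bead positions.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(pos) {
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

#' Unwrapped coordinates of every DNA chain in a frame
#'
#' Uses the stored image flags (unwrapped coordinates are continuous in
#' time, so a chain that started whole stays whole); falls back to
#' bond-walking when image flags are absent.
#'
#' @param config a `cg_configuration`.
#' @param topology a `cg_topology`.
#' @return named list of L x 3 matrices, one per DNA molecule.
#' @export
dna_chains <- function(config, topology) {
  if (is.null(config$img))
    stop("wrapped input without image flags: cannot unwrap chains")
  up <- unwrap_positions(config)
  dna_mols <- unique(topology$molecule[topology$type == 2L])
  out <- lapply(dna_mols, function(m) up[topology$molecule == m, , drop = FALSE])
  names(out) <- dna_mols
  out
}

#' Mean DNA radius of gyration over a trajectory
#'
#' Per-chain Rg, averaged over chains within each frame, then
#' block-averaged over frames.
#'
#' @param traj a `cg_trajectory` containing DNA.
#' @param n_blocks,discard_fraction passed to [block_average()].
#' @return list with `stats` (`block_stats`) and `per_frame` data.frame.
#' @export
dna_rg <- function(traj, n_blocks = 5L, discard_fraction = 0.2) {
  nf <- n_frames(traj)
  per <- vapply(seq_len(nf), function(i) {
    chains <- dna_chains(get_frame(traj, i), traj$topology)
    if (!length(chains)) stop("no DNA in system")
    mean(vapply(chains, radius_of_gyration, numeric(1)))
  }, numeric(1))
  list(stats = block_average(per, n_blocks, discard_fraction),
       per_frame = data.frame(frame = seq_len(nf), rg = per))
}

#' Bond-vector orientation correlation of chains
#'
#' `<cos theta(s)>`: mean dot product of unit bond vectors separated by
#' `s` bonds along the chain, averaged over positions and chains.
#'
#' @param chains list of L x 3 unwrapped chain conformations.
#' @param s_max largest separation (default L/2).
#' @return data.frame(s, mean_cos).
#' @export
bond_correlation <- function(chains, s_max = NULL) {
  L <- nrow(chains[[1]])
  if (is.null(s_max)) s_max <- (L - 1L) %/% 2L
  acc <- numeric(s_max); cnt <- numeric(s_max)
  for (ch in chains) {
    b <- diff(ch)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (s in seq_len(min(s_max, nb - 1L))) {
      acc[s] <- acc[s] + sum(b[1:(nb - s), ] * b[(1 + s):nb, ])
      cnt[s] <- cnt[s] + (nb - s)
    }
  }
  data.frame(s = seq_len(s_max), mean_cos = acc / cnt)
}

#' Persistence length from the bond-correlation decay
#'
#' Fits `<cos theta(s)> = exp(-s r0 / l_p)` by linear regression of
#' `log <cos>` against the contour separation `s r0`.  The fit window runs
#' from one bond up to `min(l_p estimate, L/4)` and is iterated once to
#' avoid finite-chain end effects.
#'
#' @param chains list of unwrapped chain conformations (or a
#'   `cg_trajectory` of a single chain, whose frames are used as the
#'   ensemble).
#' @param r0 bond length, A.
#' @return object of class `persistence_fit`: `lp` (A), `window_s`,
#'   `correlation` (data.frame), `ok` (FALSE when the correlation does not
#'   decay within the window).
#' @export
persistence_length <- function(chains, r0 = 5.5) {
  if (inherits(chains, "cg_trajectory")) {
    traj <- chains
    chains <- unlist(lapply(seq_len(n_frames(traj)), function(i)
      dna_chains(get_frame(traj, i), traj$topology)), recursive = FALSE)
  }
  L <- nrow(chains[[1]])
  if (L < 20) stop("persistence length needs chains of >= 20 beads")
  corr <- bond_correlation(chains)
  fit_window <- function(smax) {
    w <- corr[corr$s <= smax & corr$mean_cos > 0, , drop = FALSE]
    if (nrow(w) < 2) return(NULL)
    b <- stats::coef(stats::lm(log(mean_cos) ~ 0 + I(s * r0), data = w))
    list(lp = -1 / b, n = nrow(w))
  }
  smax0 <- max(2L, (L - 1L) %/% 4L)
  f1 <- fit_window(smax0)
  if (is.null(f1) || !is.finite(f1$lp) || f1$lp <= 0)
    return(structure(list(lp = NA_real_, window_s = smax0,
                          correlation = corr, ok = FALSE),
                     class = "persistence_fit"))
  smax <- max(2L, min(smax0, floor(f1$lp / r0)))
  f2 <- fit_window(smax)
  if (is.null(f2) || !is.finite(f2$lp) || f2$lp <= 0) f2 <- f1
  structure(list(lp = f2$lp, window_s = smax, correlation = corr,
                 ok = TRUE),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("persistence length l_p = %.1f A (fit window s <= %d)%s\n",
              x$lp, x$window_s, if (!x$ok) " [fit-window failure]" else ""))
  invisible(x)
}

#' Fraction of proteins bound to DNA
#'
#' A protein is bound when its minimum-image distance to any DNA bead is at
#' most `sigma_P + sigma_D` (55 A for the standard bead sizes).
#'
#' @param config a `cg_configuration`.
#' @param topology a `cg_topology` (must contain DNA).
#' @param threshold binding distance, A.
#' @return fraction in `[0, 1]`.
#' @export
bound_protein_fraction <- function(config, topology, threshold = 55) {
  pro <- which(topology$type == 1L)
  dna <- which(topology$type == 2L)
  if (!length(dna)) stop("no DNA in system: bound fraction undefined")
  if (!length(pro)) stop("no proteins in system")
  pairs <- cpp_neighbor_pairs(config$pos, config$box, threshold)
  if (!nrow(pairs)) return(0)
  tp <- topology$type[pairs[, 1]]; tq <- topology$type[pairs[, 2]]
  pd <- pairs[(tp == 1L & tq == 2L) | (tp == 2L & tq == 1L), , drop = FALSE]
  if (!nrow(pd)) return(0)
  bound <- unique(c(pd[, 1][topology$type[pd[, 1]] == 1L],
                    pd[, 2][topology$type[pd[, 2]] == 1L]))
  length(bound) / length(pro)
}

#' Bound protein fraction over a trajectory, block-averaged
#' @param traj a `cg_trajectory`.
#' @param threshold binding distance, A.
#' @param n_blocks,discard_fraction passed to [block_average()].
#' @return list with `stats` (`block_stats`) and `per_frame` data.frame.
#' @export
bound_fraction_trajectory <- function(traj, threshold = 55, n_blocks = 5L,
                                      discard_fraction = 0.2) {
  per <- vapply(seq_len(n_frames(traj)), function(i)
    bound_protein_fraction(get_frame(traj, i), traj$topology, threshold),
    numeric(1))
  list(stats = block_average(per, n_blocks, discard_fraction),
       per_frame = data.frame(frame = seq_along(per), bound_fraction = per))
}

#' Periodic-safe center of mass
#'
#' Circular-coordinate averaging: each axis is mapped to an angle on the
#' unit circle, averaged, and mapped back, which is robust when the point
#' set straddles a periodic boundary.
#'
#' @param pos N x 3 wrapped positions.
#' @param box box edge, A.
#' @return length-3 center of mass inside `[0, box)`.
#' @export
periodic_com <- function(pos, box) {
  th <- pos / box * 2 * pi
  ang <- atan2(colMeans(sin(th)), colMeans(cos(th)))
  (ang %% (2 * pi)) / (2 * pi) * box
}

#' Radial protein density profile about the largest cluster
#'
#' Protein number density in spherical shells centered on the
#' (periodic-safe) center of mass of the proteins in the largest cluster,
#' averaged over the analysis frames.
#'
#' @param traj a `cg_trajectory` (or a single `cg_configuration` plus
#'   `topology`).
#' @param shell_width shell thickness, A.
#' @param r_max outermost radius (default just under half the box).
#' @param frames frame indices to use (default: all after the first 20
#'   percent).
#' @param cutoff cluster cutoff passed to [find_clusters()].
#' @param topology needed only when `traj` is a single configuration.
#' @return data.frame(r, density) with shell mid radii (A) and densities
#'   (beads/A^3), with attribute `n_frames`.
#' @export
radial_density_profile <- function(traj, shell_width = 10, r_max = NULL,
                                   frames = NULL, cutoff = NULL,
                                   topology = NULL,
                                   criterion = c("contact", "fixed")) {
  criterion <- match.arg(criterion)
  if (inherits(traj, "cg_configuration")) {
    stopifnot(!is.null(topology))
    fake <- new_trajectory(topology, NULL, NULL, traj$box)
    fake$frames <- list(list(step = traj$step, time_fs = traj$time_fs,
                             pos = traj$pos, img = traj$img))
    traj <- fake
    frames <- 1L
  }
  topo <- traj$topology
  model <- if (!is.null(traj$model)) traj$model else interaction_model()
  if (is.null(r_max)) r_max <- traj$box / 2 * 0.95
  if (is.null(frames)) {
    nf <- n_frames(traj)
    frames <- seq.int(max(1L, floor(nf * 0.2) + 1L), nf)
  }
  edges <- seq(0, r_max, by = shell_width)
  if (length(edges) < 3) stop("r_max too small for the shell width")
  vol <- 4 / 3 * pi * diff(edges^3)
  counts <- numeric(length(edges) - 1L)
  pro <- which(topo$type == 1L)
  if (!length(pro)) stop("no proteins in system")
  for (i in frames) {
    cfg <- get_frame(traj, i)
    cl <- find_clusters(cfg, topo, cutoff, model, criterion)
    inbig <- pro[topo$molecule[pro] %in% cl$largest]
    if (!length(inbig)) stop("empty largest cluster")
    com <- periodic_com(cfg$pos[inbig, , drop = FALSE], cfg$box)
    d <- sqrt(rowSums(.min_image(sweep(cfg$pos[pro, , drop = FALSE], 2,
                                       com), cfg$box)^2))
    h <- hist(d[d < max(edges)], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                    density = counts / (vol * length(frames)))
  attr(out, "n_frames") <- length(frames)
  out
}

#' Fit a tanh interface profile to a radial density profile
#'
#' Least-squares fit of
#' `rho(r) = rho_dil + sum_k (delta_rho_k / 2) (1 - tanh((r - R_k) / w_k))`
#' with one or two interfaces, via Levenberg-Marquardt with multiple
#' starting points.  When `n_interfaces = 2`, the single-interface model is
#' also fitted and the double form is preferred only when it reduces the
#' residual norm by more than `improve_factor`.
#'
#' @param profile data.frame(r, density) (>= 10 shells).
#' @param n_interfaces 1 or 2.
#' @param improve_factor relative residual-norm improvement required to
#'   prefer the double-interface model (default 0.1 = 10 percent).
#' @return object of class `tanh_fit`: `rho_dil`, `delta_rho`, `radius`,
#'   `width` (vectors, inner interface first), `plateaus` (phase densities,
#'   densest first), `n_interfaces` (fitted), `chosen` (preferred model
#'   given `improve_factor`), `residual_norm`, `fitted`, `converged`,
#'   `degenerate` (TRUE when a second interface collapsed).
#' @export
fit_tanh_profile <- function(profile, n_interfaces = 1L,
                             improve_factor = 0.1) {
  stopifnot(n_interfaces %in% c(1L, 2L))
  if (nrow(profile) < 10) stop("need at least 10 shells to fit")
  f1 <- .tanh_fit_n(profile, 1L)
  if (n_interfaces == 1L) return(f1)
  f2 <- .tanh_fit_n(profile, 2L)
  if (!f2$converged) { f1$chosen <- 1L; return(f1) }
  prefer2 <- f2$residual_norm < (1 - improve_factor) * f1$residual_norm &&
    !f2$degenerate
  f2$chosen <- if (prefer2) 2L else 1L
  f2$single <- f1
  f2
}

.tanh_fit_n <- function(profile, k) {
  r <- profile$r; y <- profile$density
  scale_y <- max(y)
  if (scale_y <= 0) stop("empty profile")
  ys <- y / scale_y
  # Poisson shot noise in a shell scales as 1/sqrt(volume): weight by
  # sqrt(shell volume) so the tiny innermost shells do not dominate
  h <- stats::median(diff(r))
  vol <- 4 / 3 * pi * ((r + h / 2)^3 - (r - h / 2)^3)
  wt <- sqrt(vol / mean(vol))
  tail_n <- max(3L, length(ys) %/% 5L)
  rho_dil0 <- mean(tail(ys, tail_n))
  amp0 <- max(ys[1:3]) - rho_dil0
  # initial interface radii from the half-height crossings
  half <- rho_dil0 + amp0 * 0.5
  cross <- r[which(ys < half)[1]]
  if (is.na(cross)) cross <- stats::median(r)
  starts <- list()
  if (k == 1L) {
    for (w0 in c(0.05, 0.15, 0.4) * max(r))
      starts[[length(starts) + 1L]] <-
        c(rho_dil0, amp0, cross, w0)
  } else {
    for (fr in list(c(0.5, 1.4), c(0.7, 1.2), c(0.35, 1.8))) {
      for (w0 in c(0.05, 0.15) * max(r)) {
        a1 <- max(ys[1:3]) - ys[which.min(abs(r - cross * mean(fr)))]
        starts[[length(starts) + 1L]] <-
          c(rho_dil0, pmax(amp0 / 2, 1e-4), pmax(a1, 1e-4),
            cross * fr[1], cross * fr[2], w0, w0)
      }
    }
  }
  resid_fun <- function(par) {
    f <- if (k == 1L)
      tanh_profile_value(r, par[1], par[2], par[3], par[4])
    else
      tanh_profile_value(r, par[1], par[2:3], par[4:5], par[6:7])
    wt * (f - ys)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fun,
                         lower = if (k == 1L) c(0, -1, 0, 1e-3) else
                           c(0, -1, -1, 0, 0, 1e-3, 1e-3),
                         upper = if (k == 1L) c(2, 2, max(r) * 1.5, max(r)) else
                           c(2, 2, 2, max(r) * 1.5, max(r) * 1.5, max(r), max(r)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, n_interfaces = k,
                          residual_norm = Inf),
                     class = "tanh_fit"))
  par <- best$fit$par
  if (k == 2L) {
    ord <- order(par[4:5])
    par <- c(par[1], par[2:3][ord], par[4:5][ord], par[6:7][ord])
  }
  rho_dil <- par[1] * scale_y
  delta <- par[2:(1 + k)] * scale_y
  radius <- par[(2 + k):(1 + 2 * k)]
  width <- par[(2 + 2 * k):(1 + 3 * k)]
  plateaus <- rho_dil + rev(cumsum(rev(delta)))   # density inside each R_k
  degenerate <- k == 2L &&
    (min(abs(delta)) < 0.02 * max(abs(delta), scale_y * 1e-3) ||
     abs(diff(radius)) < 1.5 * min(width))
  structure(list(rho_dil = rho_dil, delta_rho = delta, radius = radius,
                 width = width, plateaus = plateaus,
                 n_interfaces = k, chosen = k,
                 residual_norm = best$rn * scale_y,
                 fitted = tanh_profile_value(r, rho_dil, delta, radius,
                                             width),
                 r = r, converged = TRUE, degenerate = degenerate),
            class = "tanh_fit")
}

#' @export
print.tanh_fit <- function(x, ...) {
  if (!x$converged) { cat("tanh fit: not converged\n"); return(invisible(x)) }
  cat(sprintf("tanh fit (%d interface%s%s): rho_dil = %.3g\n",
              x$n_interfaces, if (x$n_interfaces > 1) "s" else "",
              if (!is.null(x$chosen) && x$chosen != x$n_interfaces)
                ", single preferred" else "", x$rho_dil))
  for (kk in seq_along(x$radius))
    cat(sprintf("  R_%d = %.1f A, w_%d = %.1f A, plateau rho = %.3g\n",
                kk, x$radius[kk], kk, x$width[kk], x$plateaus[kk]))
  cat(sprintf("  residual norm = %.3g\n", x$residual_norm))
  invisible(x)
}

#' Coexistence concentrations of proteins
#'
#' Dense-phase concentration from the inner plateau of the radial density
#' profile (the phase-I plateau for double-tanh fits); dilute-phase
#' concentration from the shells beyond the outermost interface plus two
#' interface widths.  For a homogeneous system (no interface found) the
#' dense concentration is undefined and the dilute one equals N/V.
#'
#' @param traj a `cg_trajectory`.
#' @param n_interfaces fit order passed to [fit_tanh_profile()].
#' @param shell_width,r_max,frames passed to [radial_density_profile()].
#' @param conversion multiplicative unit conversion applied to both
#'   densities (default 1: beads/A^3; use `1.66054e6` for mM).
#' @return list with `dense`, `dilute` (converted densities), `fit`
#'   (`tanh_fit`) and `profile`.
#' @export
coexistence_concentrations <- function(traj, n_interfaces = 1L,
                                       shell_width = 10, r_max = NULL,
                                       frames = NULL, conversion = 1) {
  n_pro <- sum(traj$topology$type == 1L)
  bulk <- n_pro / traj$box^3
  prof <- tryCatch(
    radial_density_profile(traj, shell_width, r_max, frames),
    error = function(e) NULL)
  if (is.null(prof))
    return(list(dense = NA_real_, dilute = bulk * conversion, fit = NULL,
                profile = NULL))
  fit <- fit_tanh_profile(prof, n_interfaces)
  homogeneous <- !fit$converged || fit$radius[1] < prof$r[2]
  if (!homogeneous) {
    # demand a measured (not merely fitted) density contrast between the
    # inside of the innermost interface and the far field
    h <- stats::median(diff(prof$r))
    vol <- 4 / 3 * pi * ((prof$r + h / 2)^3 - (prof$r - h / 2)^3)
    inside <- prof$r < fit$radius[1]
    outside <- prof$r > fit$radius[length(fit$radius)] +
      2 * fit$width[length(fit$width)]
    rho_in <- sum(prof$density[inside] * vol[inside]) / sum(vol[inside])
    rho_out <- if (any(outside))
      sum(prof$density[outside] * vol[outside]) / sum(vol[outside]) else bulk
    n_in <- sum(prof$density[inside] * vol[inside])   # particles inside
    homogeneous <- !any(inside) || rho_in < 2 * max(rho_out, 1e-300) ||
      n_in < 10 || fit$radius[1] < 2.5 * h
  }
  if (homogeneous)
    return(list(dense = NA_real_, dilute = bulk * conversion, fit = fit,
                profile = prof))
  outer_k <- length(fit$radius)
  r_out <- fit$radius[outer_k] + 2 * fit$width[outer_k]
  sel <- prof$r > r_out
  # volume-weighted mean = total counts / total volume beyond the interface
  h <- stats::median(diff(prof$r))
  vol <- 4 / 3 * pi * ((prof$r + h / 2)^3 - (prof$r - h / 2)^3)
  dilute <- if (any(sel))
    sum(prof$density[sel] * vol[sel]) / sum(vol[sel]) else fit$rho_dil
  list(dense = fit$plateaus[1] * conversion,
       dilute = dilute * conversion, fit = fit, profile = prof)
}
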