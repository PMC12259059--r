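# Protein displacement statistics and the multi-mode diffusion
# decomposition: the radial displacement distribution
#   P(r, t) = sum_i p_i 4 pi r^2 (4 pi D_i t)^(-3/2) exp(-r^2 / (4 D_i t))
# is fitted with a simplex constraint on the weights and positivity on the
# diffusivities; the mode count n grows until the residual stops improving.

#' Displacement sample with histogram
#'
#' Bundles radial displacements at one lag time with their normalized
#' histogram (Freedman-Diaconis bin width on the pooled sample).
#'
#' @param r radial displacements, A (nonnegative).
#' @param lag_ns lag time, ns.
#' @param bin_width optional override of the bin width, A.
#' @return object of class `displacement_sample`: `r`, `lag_ns`, `breaks`,
#'   `mids`, `counts`, `density` (integrates to ~1 over the support).
#' @export
displacement_sample <- function(r, lag_ns, bin_width = NULL) {
  stopifnot(all(r >= 0), lag_ns > 0)
  if (is.null(bin_width)) {
    bin_width <- 2 * stats::IQR(r) / length(r)^(1 / 3)
    # multi-scale samples (diffusivities spread over decades): make sure the
    # slowest fraction of the sample still spans several bins
    if (any(r > 0))
      bin_width <- min(bin_width,
                       max(stats::quantile(r[r > 0], 0.02) / 2, 1e-6))
    if (bin_width <= 0) bin_width <- max(max(r) / 50, 1e-6)
  }
  breaks <- seq(0, max(r) + bin_width, by = bin_width)
  h <- hist(r, breaks = breaks, plot = FALSE)
  structure(list(r = r, lag_ns = lag_ns, breaks = breaks, mids = h$mids,
                 counts = h$counts, density = h$density),
            class = "displacement_sample")
}

#' @export
print.displacement_sample <- function(x, ...) {
  cat(sprintf("displacement sample: n = %d, lag = %g ns, mean r^2 = %.4g A^2\n",
              length(x$r), x$lag_ns, mean(x$r^2)))
  invisible(x)
}

#' Radial displacements of proteins at a lag time
#'
#' `|dx(t)|` over all proteins and all sliding time origins at the given
#' lag, computed on unwrapped coordinates.  Origins are strided by the lag
#' itself to reduce autocorrelation between samples.
#'
#' @param traj a `cg_trajectory` spanning at least one lag.
#' @param lag_ns lag time, ns.
#' @param stride origin stride in frames (default: the lag).
#' @return a [displacement_sample()].
#' @export
radial_displacements <- function(traj, lag_ns, stride = NULL) {
  nf <- n_frames(traj)
  times <- vapply(traj$frames, function(f) f$time_fs, numeric(1)) / 1e6  # ns
  dt_frame <- if (nf > 1) times[2] - times[1] else 0
  lag_frames <- as.integer(round(lag_ns / dt_frame))
  if (lag_frames < 1 || lag_frames > nf - 1)
    stop("lag exceeds trajectory span (or is below frame cadence)")
  if (is.null(stride)) stride <- lag_frames
  pro <- which(traj$topology$type == 1L)
  if (!length(pro)) stop("no proteins in trajectory")
  origins <- seq.int(1L, nf - lag_frames, by = stride)
  disp <- vector("list", length(origins))
  for (k in seq_along(origins)) {
    i <- origins[k]
    a <- unwrap_positions(get_frame(traj, i))[pro, , drop = FALSE]
    b <- unwrap_positions(get_frame(traj, i + lag_frames))[pro, , drop = FALSE]
    disp[[k]] <- sqrt(rowSums((b - a)^2))
  }
  displacement_sample(unlist(disp), lag_frames * dt_frame)
}

#' Evaluate the multi-mode diffusive mixture density
#'
#' The radial density of an n-component isotropic Gaussian displacement
#' mixture: each component is `4 pi r^2 (4 pi D t)^(-3/2) exp(-r^2/4Dt)`,
#' weighted by `p_i` with `sum p_i = 1`.
#'
#' @param r radii, A.
#' @param t_ns lag time, ns.
#' @param p mode weights (simplex).
#' @param d diffusivities, A^2/ns (positive).
#' @return density values at `r`.
#' @export
eval_mixture <- function(r, t_ns, p, d) {
  stopifnot(length(p) == length(d), all(d > 0),
            abs(sum(p) - 1) < 1e-6, all(p >= -1e-12))
  out <- numeric(length(r))
  for (i in seq_along(p)) {
    s <- 4 * d[i] * t_ns
    out <- out + p[i] * 4 * pi * r^2 * (pi * s)^(-3 / 2) * exp(-r^2 / s)
  }
  out
}

# EM on raw radial samples -- used to seed the least-squares fit
.em_modes <- function(r, t_ns, n, iters = 60L) {
  if (length(r) > 20000L) r <- r[seq(1L, length(r), length.out = 20000L)]
  r2 <- r^2
  q <- stats::quantile(r2, probs = (seq_len(n) - 0.5) / n)
  d <- pmax(q / (6 * t_ns), 1e-12)
  p <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    lg <- sapply(seq_len(n), function(i)
      log(p[i] + 1e-300) - 1.5 * log(4 * pi * d[i] * t_ns) -
        r2 / (4 * d[i] * t_ns))
    m <- apply(lg, 1, max)
    g <- exp(lg - m)
    g <- g / rowSums(g)
    p <- colMeans(g)
    d <- pmax(colSums(g * r2) / (6 * t_ns * colSums(g) + 1e-300), 1e-12)
  }
  list(p = p, d = d)
}

#' Fit n diffusive modes to a displacement sample
#'
#' Poisson-weighted least squares in histogram space over the mode weights
#' (simplex-constrained via a softmax parameterization) and log
#' diffusivities, with multi-start initialization: diffusivities log-spaced
#' between `r_min^2/4t` and `r_max^2/4t` plus an EM-refined start.
#'
#' @param sample a [displacement_sample()].
#' @param n mode count (>= 1).
#' @param n_starts random restarts.
#' @return object of class `diffusion_mode_fit`: `n`, `p`, `d` (sorted by
#'   descending D), `residual` (profile over the histogram mids),
#'   `residual_norm`, `mean_r2`, `msd_consistency`
#'   (`sum(p 6 D t) / mean(r^2)`), `converged`.
#' @export
fit_modes <- function(sample, n, n_starts = 20L) {
  stopifnot(n >= 1, inherits(sample, "displacement_sample"))
  mids <- sample$mids; dens <- sample$density; cnt <- sample$counts
  t_ns <- sample$lag_ns
  keep <- is.finite(dens)
  mids <- mids[keep]; dens <- dens[keep]; cnt <- cnt[keep]
  ntot <- sum(cnt); bw <- diff(sample$breaks[1:2])
  w <- (ntot * bw)^2 / (cnt + 1)          # inverse Poisson variance
  w <- w / mean(w)
  obj <- function(par) {
    pd <- .par_to_modes(par, n)
    f <- eval_mixture(mids, t_ns, pd$p, pd$d)
    v <- sum(w * (f - dens)^2)
    if (!is.finite(v)) 1e300 else v
  }
  r_pos <- sample$r[sample$r > 0]
  dmin <- max(stats::quantile(r_pos, 0.002)^2, 1e-10) / (4 * t_ns)
  dmax <- max(sample$r)^2 / (4 * t_ns)
  lower <- c(rep(-30, n - 1), rep(log(dmin) - 3, n))
  upper <- c(rep(30, n - 1), rep(log(dmax) + 3, n))
  starts <- list()
  em <- tryCatch(.em_modes(sample$r, t_ns, n), error = function(e) NULL)
  if (!is.null(em) && all(is.finite(log(em$d)))) {
    p_em <- pmax(em$p, 1e-6)
    starts[[1]] <- c(log(p_em[-n] / p_em[n]), log(em$d))
  }
  for (k in seq_len(n_starts)) {
    d0 <- sort(exp(runif(n, log(dmin), log(dmax))), decreasing = TRUE)
    starts[[length(starts) + 1L]] <- c(rep(0, n - 1), log(d0))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 1000, factr = 1e3)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mode fit failed to converge from every start")
  pd <- .par_to_modes(best$par, n)
  ord <- order(pd$d, decreasing = TRUE)
  p <- pd$p[ord]; d <- pd$d[ord]
  f <- eval_mixture(mids, t_ns, p, d)
  mean_r2 <- mean(sample$r^2)
  structure(list(n = n, p = p, d = d, lag_ns = t_ns,
                 mids = mids, residual = f - dens,
                 residual_norm = sqrt(best$value),
                 mean_r2 = mean_r2,
                 msd_consistency = sum(p * 6 * d * t_ns) / mean_r2,
                 converged = best$convergence == 0 || best$value < Inf),
            class = "diffusion_mode_fit")
}

.par_to_modes <- function(par, n) {
  logits <- c(par[seq_len(n - 1)], 0)
  e <- exp(logits - max(logits))
  list(p = e / sum(e), d = exp(par[n:(2 * n - 1)]))
}

#' @export
print.diffusion_mode_fit <- function(x, ...) {
  cat(sprintf("diffusion mode fit: n = %d, lag = %g ns\n", x$n, x$lag_ns))
  for (i in seq_len(x$n))
    cat(sprintf("  mode %d: p = %.3f, D = %.4g A^2/ns\n", i, x$p[i],
                x$d[i]))
  cat(sprintf("  residual norm = %.4g, sum(p 6 D t)/<r^2> = %.3f\n",
              x$residual_norm, x$msd_consistency))
  invisible(x)
}

#' Choose the number of diffusive modes
#'
#' Starting from one mode, n is incremented while the weighted residual
#' norm improves by more than `threshold` (relative), the operational
#' reading of "increase n until the fit achieves minimal residuals".
#'
#' @param sample a [displacement_sample()].
#' @param n_max largest mode count considered.
#' @param threshold relative residual-norm improvement required to accept
#'   n+1 over n (default 0.1).
#' @param n_starts restarts per fit.
#' @return list with `n` (chosen), `fit` (the chosen fit), `fits` (all
#'   fits), `residual_norms`.
#' @export
select_mode_count <- function(sample, n_max = 6L, threshold = 0.1,
                              n_starts = 20L) {
  stopifnot(n_max >= 1)
  fits <- list()
  fits[[1]] <- fit_modes(sample, 1L, n_starts)
  n <- 1L
  while (n < n_max) {
    cand <- fit_modes(sample, n + 1L, n_starts)
    fits[[n + 1L]] <- cand
    if (cand$residual_norm < (1 - threshold) * fits[[n]]$residual_norm)
      n <- n + 1L
    else break
  }
  list(n = n, fit = fits[[n]], fits = fits,
       residual_norms = vapply(fits, `[[`, numeric(1), "residual_norm"))
}

#' Diffusivity stability across lag times
#'
#' Fits each lag independently (with a common mode count, by default the
#' majority choice of [select_mode_count()] across lags) and reports the
#' per-mode diffusivities, their coefficient of variation across lags, and
#' lag-averaged values.  A diffusive process gives lag-stable D_i; CV above
#' `cv_flag` marks a mode unstable (e.g. ballistic or aging dynamics).
#'
#' @param samples list of [displacement_sample()]s at different lags (>= 3).
#' @param n mode count; default: majority vote of per-lag selection.
#' @param n_max,threshold,n_starts passed to the per-lag fits.
#' @param cv_flag CV level above which a mode is flagged unstable.
#' @return object of class `mode_stability`: `n`, `table`
#'   (data.frame lag_ns x modes), `d_mean`, `p_mean`, `cv`, `stable`,
#'   `consistent_n` (FALSE when per-lag selection disagreed).
#' @export
mode_stability <- function(samples, n = NULL, n_max = 6L, threshold = 0.1,
                           n_starts = 20L, cv_flag = 0.1) {
  stopifnot(length(samples) >= 3)
  consistent <- TRUE
  if (is.null(n)) {
    ns <- vapply(samples, function(s)
      select_mode_count(s, n_max, threshold, n_starts)$n, integer(1))
    consistent <- length(unique(ns)) == 1L
    tab <- table(ns)
    n <- as.integer(names(tab)[which.max(tab)])
  }
  fits <- lapply(samples, fit_modes, n = n, n_starts = n_starts)
  lags <- vapply(samples, `[[`, numeric(1), "lag_ns")
  dmat <- do.call(rbind, lapply(fits, `[[`, "d"))
  pmat <- do.call(rbind, lapply(fits, `[[`, "p"))
  cv <- apply(dmat, 2, function(col) stats::sd(col) / mean(col))
  tabd <- data.frame(lag_ns = lags, dmat, pmat)
  names(tabd) <- c("lag_ns", paste0("D", seq_len(n)),
                   paste0("p", seq_len(n)))
  structure(list(n = n, table = tabd, d_mean = colMeans(dmat),
                 p_mean = colMeans(pmat), cv = cv,
                 stable = all(cv < cv_flag), consistent_n = consistent,
                 fits = fits),
            class = "mode_stability")
}

#' @export
print.mode_stability <- function(x, ...) {
  cat(sprintf("mode stability: n = %d over %d lags%s\n", x$n,
              nrow(x$table),
              if (!x$consistent_n) " (per-lag n inconsistent, majority used)"
              else ""))
  for (i in seq_len(x$n))
    cat(sprintf("  D%d = %.4g A^2/ns (CV %.1f%%)%s\n", i, x$d_mean[i],
                100 * x$cv[i], if (x$cv[i] >= 0.1) " [unstable]" else ""))
  invisible(x)
}
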