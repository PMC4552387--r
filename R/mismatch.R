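# Mismatch distributions and the sudden (stepwise) expansion model:
# observed pairwise-difference histogram, closed-form expected distribution,
# least-squares fitting of (tau, theta0, theta1), and parametric-bootstrap
# confidence intervals for tau.

#' Observed mismatch distribution
#'
#' Relative frequency of sequence pairs differing at j sites, over all
#' C(n, 2) pairs, computed on the complete-deletion site set.
#'
#' @param x a [seq_alignment()] or character matrix for one population.
#' @return an object of class `mismatch_distribution`: numeric vector `F`
#'   indexed from j = 0, with attributes `pairs` (number of pairs) and
#'   `counts`.
#' @export
observed_mismatch <- function(x) {
  mat <- as_seq_matrix(x, filter = TRUE)
  n <- nrow(mat)
  if (n < 2) stop("mismatch distribution undefined for n < 2", call. = FALSE)
  D <- pairwise_difference_matrix(mat, filter = FALSE)
  d <- D[upper.tri(D)]
  counts <- tabulate(d + 1, nbins = max(d) + 1)
  F <- counts / length(d)
  names(F) <- as.character(seq_along(F) - 1)
  structure(F, pairs = length(d), counts = counts,
            class = "mismatch_distribution")
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' A population of size `theta0` grows instantaneously to `theta1` at `tau`
#' mutational units before the present. The pairwise coalescence-time
#' density in mutational units is
#' \deqn{g(x) = \theta_1^{-1} e^{-x/\theta_1}, \quad 0 \le x < \tau;\qquad
#'   g(x) = e^{-\tau/\theta_1}\,\theta_0^{-1} e^{-(x-\tau)/\theta_0},
#'   \quad x \ge \tau,}
#' and \eqn{F_j = \int \mathrm{Pois}(j; x)\, g(x)\, dx}, which integrates in
#' closed form to incomplete-gamma terms:
#' \deqn{F_j = \frac{\theta_1^j}{(1+\theta_1)^{j+1}} P(j+1, a\tau)
#'   + e^{\tau(1/\theta_0 - 1/\theta_1)} \frac{\theta_0^j}{(1+\theta_0)^{j+1}}
#'   Q(j+1, b\tau)}
#' with \eqn{a = 1 + 1/\theta_1}, \eqn{b = 1 + 1/\theta_0}, and P/Q the
#' regularised lower/upper incomplete gamma functions (for `theta0 = 0` the
#' second term degenerates to \eqn{e^{-\tau/\theta_1}\mathrm{Pois}(j;\tau)}).
#' When `theta0 = theta1` or `tau = 0` the distribution reduces to the
#' equilibrium geometric \eqn{\theta^j/(1+\theta)^{j+1}}.
#'
#' @param model list with `tau`, `theta0`, `theta1` (see [expansion_model()]).
#' @param j_max largest difference class to return.
#' @param fold fold the truncated tail mass into class `j_max` (flagged via
#'   the `folded_mass` attribute); default `FALSE` returns the raw head of
#'   the distribution.
#' @return `mismatch_distribution` of length `j_max + 1`.
#' @export
expected_mismatch <- function(model, j_max, fold = FALSE) {
  tau <- model$tau; th0 <- model$theta0; th1 <- model$theta1
  if (!all(is.finite(c(tau, th0, th1))) || tau < 0 || th0 < 0 || th1 < 0) {
    stop("invalid expansion-model parameters", call. = FALSE)
  }
  j <- 0:j_max
  eps <- 1e-12
  geom <- function(theta) {
    if (theta < eps) c(1, rep(0, j_max)) else
      exp(j * log(theta) - (j + 1) * log1p(theta))
  }
  if (tau < eps || abs(th0 - th1) < eps * max(1, th1)) {
    theta <- if (tau < eps) th0 else th1
    F <- geom(theta)
  } else {
    # recent (theta1) segment
    if (th1 < eps) {
      A <- rep(0, j_max + 1)   # no mutations can accumulate in zero-size limit
    } else {
      a <- 1 + 1 / th1
      A <- geom(th1) * stats::pgamma(a * tau, shape = j + 1)
    }
    # ancestral (theta0) segment, entered with probability exp(-tau/theta1)
    if (th0 < eps) {
      B <- exp(-tau / th1) * stats::dpois(j, tau)
    } else {
      b <- 1 + 1 / th0
      logB <- tau * (1 / th0 - 1 / th1) + j * log(th0) - (j + 1) * log1p(th0) +
        stats::pgamma(b * tau, shape = j + 1, lower.tail = FALSE, log.p = TRUE)
      B <- exp(logB)
    }
    F <- A + B
  }
  folded <- 0
  if (fold) {
    folded <- max(0, 1 - sum(F))
    F[j_max + 1] <- F[j_max + 1] + folded
  }
  names(F) <- as.character(j)
  structure(F, pairs = NA_integer_, counts = NULL, folded_mass = folded,
            class = "mismatch_distribution")
}

#' Expansion model parameter container
#'
#' @param tau expansion age in mutational units (>= 0).
#' @param theta0,theta1 pre-/post-expansion scaled population sizes.
#' @return list of class `expansion_model`.
#' @export
expansion_model <- function(tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0)
  structure(list(tau = tau, theta0 = theta0, theta1 = theta1),
            class = "expansion_model")
}

# Sum of squared deviations between an observed mismatch vector and the
# model expectation over the same support.
.mismatch_ssd <- function(obs, tau, th0, th1) {
  jm <- length(obs) - 1
  ex <- expected_mismatch(list(tau = tau, theta0 = th0, theta1 = th1), jm)
  sum((as.numeric(obs) - as.numeric(ex))^2)
}

#' Least-squares fit of the sudden-expansion model
#'
#' Minimises \eqn{\sum_j (F^{obs}_j - F^{exp}_j)^2} over
#' \eqn{(\tau, \theta_0, \theta_1)} by a fixed coarse grid
#' (tau in \[0, 20\], theta0 in \[0, 10\], theta1 in \[theta0, 1000\])
#' followed by Nelder-Mead refinement from the best grid point, with
#' parameters clamped to the valid region. The grid is fixed so point
#' estimates are reproducible. The fit is evaluated on difference classes
#' 0..(max observed mismatch + 5).
#'
#' @param obs a `mismatch_distribution` from [observed_mismatch()].
#' @param n sample size behind `obs` (recorded; used by the bootstrap).
#' @param j_extra tail padding beyond the largest observed difference.
#' @param init optional [expansion_model()] used as a warm start; the coarse
#'   grid is then reduced to a neighbourhood of `init` (used by the
#'   parametric bootstrap, where the truth lies near the original fit).
#' @return object of class `expansion_fit`: `model` ([expansion_model()]),
#'   `ssd`, `converged`, `n`, `j_max`, `grid_version`.
#' @export
fit_expansion <- function(obs, n = NA_integer_, j_extra = 5, init = NULL) {
  if (abs(sum(obs) - 1) > 1e-6) stop("observed mismatch must be a distribution",
                                     call. = FALSE)
  j_obs <- max(which(as.numeric(obs) > 0)) - 1
  jm <- j_obs + j_extra
  ov <- c(as.numeric(obs), rep(0, jm + 1 - length(obs)))[seq_len(jm + 1)]

  if (is.null(init)) {
    tau_grid <- c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 14, 20)
    th0_grid <- c(0, 0.25, 0.5, 1, 2, 5, 10)
    th1_grid <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 300, 1000)
  } else {
    tau_grid <- unique(pmin(pmax(init$tau * c(0, 0.5, 1, 2), 0), 20))
    th0_grid <- unique(pmin(pmax(init$theta0 * c(0, 1, 2), 0), 10))
    th1_grid <- unique(pmin(pmax(init$theta1 * c(0.5, 1, 2), 0.5), 1000))
  }
  best <- list(val = Inf, par = c(1, 1, 10))
  for (tau in tau_grid) for (th0 in th0_grid) {
    for (th1 in th1_grid[th1_grid >= th0]) {
      v <- .mismatch_ssd(ov, tau, th0, th1)
      if (v < best$val) best <- list(val = v, par = c(tau, th0, th1))
    }
  }
  # Nelder-Mead on (tau, theta0, delta = theta1 - theta0), clamped
  fn <- function(p) {
    tau <- min(max(p[1], 0), 20)
    th0 <- min(max(p[2], 0), 10)
    th1 <- th0 + min(max(p[3], 0), 1000)
    .mismatch_ssd(ov, tau, th0, th1)
  }
  p0 <- c(best$par[1], best$par[2], best$par[3] - best$par[2])
  opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  tau <- min(max(opt$par[1], 0), 20)
  th0 <- min(max(opt$par[2], 0), 10)
  th1 <- th0 + min(max(opt$par[3], 0), 1000)
  structure(list(model = expansion_model(tau, th0, th1), ssd = opt$value,
                 converged = opt$convergence == 0, n = n, j_max = jm,
                 grid_version = "v1"),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau = %.4f, theta0 = %.4f, theta1 = %.4f (SSD = %.3g%s)\n",
              x$model$tau, x$model$theta0, x$model$theta1, x$ssd,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Parametric-bootstrap confidence interval for tau
#'
#' Simulates `B` coalescent samples of size `n` over `L` sites under the
#' fitted stepwise-expansion model, refits each and returns the percentile
#' 2.5/97.5 bounds and median of the bootstrap tau distribution. If more
#' than 10% of replicate fits fail the interval is flagged unreliable.
#'
#' @param fit an `expansion_fit`.
#' @param n sample size for the bootstrap samples (defaults to `fit$n`).
#' @param L alignment length in sites.
#' @param B bootstrap replicates.
#' @param seed RNG seed (required; logged in the result).
#' @return list with `lower`, `upper`, `median`, `tau_boot`, `failures`,
#'   `reliable`, `B`, `seed`.
#' @export
bootstrap_tau_ci <- function(fit, n = fit$n, L, B = 3000, seed) {
  stopifnot(inherits(fit, "expansion_fit"), is.finite(n), n >= 2)
  set.seed(seed)
  dem <- demog_stepwise(fit$model$tau, fit$model$theta0, max(fit$model$theta1, 1e-6))
  taus <- rep(NA_real_, B)
  fails <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      sm <- simulate_sample(n, L, demography = dem, mode = "theta")
      if (attr(sm, "realized_S") == 0) {
        0  # no variation: expansion age indistinguishable from 0
      } else {
        fit_expansion(observed_mismatch(sm), n = n, init = fit$model)$model$tau
      }
    }, error = function(e) NA_real_)
    if (is.na(res)) fails <- fails + 1L else taus[b] <- res
  }
  tb <- taus[!is.na(taus)]
  ci <- stats::quantile(tb, c(0.025, 0.975), names = FALSE, type = 7)
  out <- list(lower = ci[1], upper = ci[2], median = stats::median(tb),
              tau_boot = tb, failures = fails, reliable = fails <= 0.1 * B,
              B = B, seed = seed)
  if (!out$reliable) warning(sprintf("bootstrap CI unreliable: %d/%d refits failed",
                                     fails, B))
  if (fit$model$tau < out$lower - 1e-8 || fit$model$tau > out$upper + 1e-8) {
    out$point_outside_ci <- TRUE
  }
  out
}

#' Export observed vs expected mismatch as TSV
#'
#' @param obs observed `mismatch_distribution`.
#' @param fit an `expansion_fit` (optional; adds the expected column).
#' @param path output file.
#' @export
write_mismatch <- function(obs, fit = NULL, path) {
  jm <- length(obs) - 1
  df <- data.frame(j = 0:jm, observed = as.numeric(obs))
  if (!is.null(fit)) {
    df$expected <- as.numeric(expected_mismatch(fit$model, jm))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
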