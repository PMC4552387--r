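# Neutrality statistics: Tajima's D, Fu's Fs (Ewens sampling formula,
# log-space Stirling numbers), Ramos-Onsins & Rozas R2, and their
# coalescent-simulation significance.

#' Tajima's D
#'
#' \deqn{D = \frac{\bar k - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}}
#' with the standard constants \eqn{a_1 = \sum_{i=1}^{n-1} 1/i},
#' \eqn{a_2 = \sum 1/i^2}, \eqn{b_1 = (n+1)/(3(n-1))},
#' \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))}, \eqn{c_1 = b_1 - 1/a_1},
#' \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2}, \eqn{e_1 = c_1/a_1},
#' \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param n sample size (>= 4).
#' @param S number of segregating sites (>= 1).
#' @param kbar mean pairwise differences.
#' @return Tajima's D.
#' @export
tajimas_d <- function(n, S, kbar) {
  if (n < 4) stop("Tajima's D requires n >= 4", call. = FALSE)
  if (S < 1) stop("Tajima's D undefined when S = 0", call. = FALSE)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n: log |s(n, k)| for
# k = 1..n, by the recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| evaluated
# in log space (overflow-safe far beyond n = 60). Rows are memoised.
.stirling_env <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_env[[key]])) return(.stirling_env[[key]])
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n > 1) for (m in seq_len(n - 1)) {
    # row holds log|s(m, 1..m)|; build m+1
    up <- c(-Inf, row)                 # |s(m, k-1)|
    left <- c(row, -Inf) + log(m)      # m |s(m, k)|
    row <- pmax(up, left) + log1p(exp(-abs(up - left)))
    row[!is.finite(row)] <- -Inf
  }
  .stirling_env[[key]] <- row
  row
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs statistic
#'
#' With theta set to the mean pairwise difference, the probability of
#' observing at least the sampled number of haplotypes under the Ewens
#' sampling formula is
#' \deqn{S' = \Pr(K \ge k_{obs}) = \sum_{k \ge k_{obs}}
#'   \frac{|s(n,k)|\,\theta^k}{\theta(\theta+1)\cdots(\theta+n-1)}}
#' and \eqn{F_s = \ln(S'/(1-S'))}. Evaluated in log space with exact
#' log-Stirling recurrences, stable far beyond n = 60. A sample with a
#' single haplotype has \eqn{S' = 1} and returns `Inf` with a warning
#' (degenerate input).
#'
#' @param n sample size (>= 2).
#' @param kbar mean pairwise differences (> 0), used as the theta estimate.
#' @param k_obs observed number of haplotypes (1 <= k_obs <= n).
#' @return Fu's Fs (finite for `1 < k_obs <= n`).
#' @export
fu_fs <- function(n, kbar, k_obs) {
  if (n < 2) stop("Fu's Fs requires n >= 2", call. = FALSE)
  if (kbar <= 0) stop("Fu's Fs undefined when mean pairwise differences are 0",
                      call. = FALSE)
  if (k_obs < 1 || k_obs > n) stop("k_obs must be in 1..n", call. = FALSE)
  if (k_obs == 1) {
    warning("k_obs = 1: S' = 1, Fs is infinite (degenerate input)")
    return(Inf)
  }
  theta <- kbar
  lq <- log_stirling_row(n) + seq_len(n) * log(theta)  # unnormalised log masses
  ltail <- logsumexp(lq[k_obs:n])
  lhead <- logsumexp(lq[seq_len(k_obs - 1)])
  ltail - lhead
}

#' Ramos-Onsins & Rozas R2
#'
#' \deqn{R_2 = \frac{\sqrt{\frac{1}{n}\sum_i (U_i - \bar k/2)^2}}{S}}
#' where \eqn{U_i} is the number of singleton mutations carried by sequence
#' i. Small values signal an excess of recent mutations (expansion); the
#' statistic is designed for small samples.
#'
#' @param n sample size.
#' @param S number of segregating sites (>= 1).
#' @param kbar mean pairwise differences.
#' @param U integer vector of per-sequence singleton counts (length n).
#' @return R2 (>= 0).
#' @export
rozas_r2 <- function(n, S, kbar, U) {
  if (S < 1) stop("R2 undefined when S = 0", call. = FALSE)
  if (length(U) != n) stop("U must have one entry per sequence", call. = FALSE)
  sqrt(mean((U - kbar / 2)^2)) / S
}

#' Observed neutrality-test inputs from an alignment
#'
#' Computes, on the complete-deletion site set: sample size, segregating
#' sites, mean pairwise differences, number of distinct haplotypes, and the
#' per-sequence singleton counts `U` (site variants carried by exactly one
#' sequence).
#'
#' @param x a [seq_alignment()] or character matrix for one population.
#' @return list with `n`, `S`, `kbar`, `k_obs`, `U`.
#' @export
observed_neutrality_stats <- function(x) {
  mat <- as_seq_matrix(x, filter = TRUE)
  n <- nrow(mat)
  D <- pairwise_difference_matrix(mat, filter = FALSE)
  kbar <- if (n >= 2) sum(D[upper.tri(D)]) / choose(n, 2) else 0
  U <- integer(n)
  S <- 0L
  for (s in seq_len(ncol(mat))) {
    tabu <- table(mat[, s])
    if (length(tabu) > 1) {
      S <- S + 1L
      singles <- names(tabu)[tabu == 1]
      for (b in singles) U[which(mat[, s] == b)] <- U[which(mat[, s] == b)] + 1L
    }
  }
  k_obs <- length(unique(apply(mat, 1, paste, collapse = "")))
  list(n = n, S = S, kbar = kbar, k_obs = k_obs, U = U)
}

#' Simulation-based p-values for the neutrality statistics
#'
#' Compares observed D, Fs and R2 against `reps` neutral coalescent
#' replicates (see [simulate_neutrality_null()]), conditioning by default on
#' the observed number of segregating sites. Fs and R2 are tested one-tailed
#' (lower: expansion signal), D two-tailed; all p-values use the add-one
#' rule so they are never exactly zero.
#'
#' @param obs list as returned by [observed_neutrality_stats()].
#' @param reps number of coalescent replicates; values below 100 give coarse
#'   p-value resolution and trigger a warning.
#' @param conditioning `"fixed_s"` (default) or `"theta"` (theta set to
#'   Watterson's estimate `S/a1`).
#' @param seed RNG seed (required: the procedure is stochastic).
#' @param null optional precomputed null data frame from
#'   [simulate_neutrality_null()] with matching conditioning, to amortise
#'   simulation cost across datasets sharing (n, S).
#' @return list with `p_D`, `p_Fs`, `p_R2`, the observed statistics, `reps`
#'   and `seed`.
#' @export
simulate_null_pvalues <- function(obs, reps = 1000,
                                  conditioning = c("fixed_s", "theta"),
                                  seed = NULL, null = NULL) {
  conditioning <- match.arg(conditioning)
  if (reps < 100) warning("fewer than 100 replicates: low p-value resolution")
  if (obs$S < 1) stop("no segregating sites: tests undefined", call. = FALSE)
  if (is.null(null)) {
    if (is.null(seed)) stop("a seed is required for coalescent simulation",
                            call. = FALSE)
    theta_w <- obs$S / sum(1 / seq_len(obs$n - 1))
    null <- simulate_neutrality_null(obs$n, reps, conditioning = conditioning,
                                     S = obs$S, theta = theta_w, seed = seed)
  }
  reps <- nrow(null)
  D_obs <- tajimas_d(obs$n, obs$S, obs$kbar)
  Fs_obs <- if (obs$kbar > 0 && obs$k_obs > 1) fu_fs(obs$n, obs$kbar, obs$k_obs)
            else NA_real_
  R2_obs <- rozas_r2(obs$n, obs$S, obs$kbar, obs$U)
  lower_p <- function(sim, x) (sum(sim <= x, na.rm = TRUE) + 1) / (sum(!is.na(sim)) + 1)
  upper_p <- function(sim, x) (sum(sim >= x, na.rm = TRUE) + 1) / (sum(!is.na(sim)) + 1)
  p_D <- min(1, 2 * min(lower_p(null$D, D_obs), upper_p(null$D, D_obs)))
  p_Fs <- if (is.na(Fs_obs)) NA_real_ else lower_p(null$Fs, Fs_obs)
  p_R2 <- lower_p(null$R2, R2_obs)
  list(p_D = p_D, p_Fs = p_Fs, p_R2 = p_R2,
       D = D_obs, Fs = Fs_obs, R2 = R2_obs, reps = reps, seed = seed)
}

#' Full neutrality-test summary for one population
#'
#' Computes D, Fs and R2 with coalescent-simulation p-values and
#' significance flags. Fu's Fs is flagged significant at p <= 0.02 (its
#' non-standard null behaviour makes 0.02 the operative 5% level); D and R2
#' use 0.05.
#'
#' @param x a [seq_alignment()] or character matrix for one population.
#' @param reps number of coalescent replicates (default 1000).
#' @param conditioning `"fixed_s"` or `"theta"`.
#' @param seed RNG seed.
#' @param fs_alpha,alpha significance levels for Fs and for D/R2.
#' @return an object of class `neutrality_summary` (a one-row data frame
#'   with statistics, p-values and significance flags) with the observed
#'   inputs attached as attributes.
#' @export
neutrality_test <- function(x, reps = 1000, conditioning = "fixed_s",
                            seed = NULL, fs_alpha = 0.02, alpha = 0.05) {
  obs <- observed_neutrality_stats(x)
  pv <- simulate_null_pvalues(obs, reps = reps, conditioning = conditioning,
                              seed = seed)
  out <- data.frame(n = obs$n, S = obs$S, kbar = obs$kbar, h = obs$k_obs,
                    D = pv$D, p_D = pv$p_D, sig_D = pv$p_D <= alpha,
                    Fs = pv$Fs, p_Fs = pv$p_Fs,
                    sig_Fs = !is.na(pv$p_Fs) & pv$p_Fs <= fs_alpha,
                    R2 = pv$R2, p_R2 = pv$p_R2, sig_R2 = pv$p_R2 <= alpha,
                    reps = pv$reps)
  attr(out, "observed") <- obs
  attr(out, "seed") <- seed
  class(out) <- c("neutrality_summary", "data.frame")
  out
}
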