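# Neutral coalescent simulator: constant-size, stepwise-expansion and
# two-deme divergence models. Time is measured in per-lineage mutational
# units so that a pair of sequences separated for coalescence time T differs
# at Poisson(2T) sites; with theta = 2Nu per locus the coalescence rate for j
# lineages is j(j-1)/theta and the expected pairwise difference under a
# constant-size model is exactly theta. On this scale the stepwise-expansion
# breakpoint sits at time tau/2, so simulator parameters (tau, theta0,
# theta1) align one-to-one with the mismatch model's.

#' Demography constructors for the coalescent simulator
#'
#' `demog_constant(theta)`: constant scaled population size.
#' `demog_stepwise(tau, theta0, theta1)`: present size `theta1`, ancestral
#' size `theta0`, instantaneous change `tau` mutational units ago (on the
#' pairwise-distance scale). `theta0 = 0` collapses every remaining lineage
#' at the breakpoint (star genealogy).
#'
#' @param theta,theta0,theta1 scaled population mutation parameters (>= 0).
#' @param tau expansion age in mutational units (>= 0).
#' @return a demography description list.
#' @export
demog_constant <- function(theta) {
  stopifnot(theta > 0)
  list(type = "constant", theta = theta)
}

#' @rdname demog_constant
#' @export
demog_stepwise <- function(tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0, is.finite(tau))
  list(type = "stepwise", tau = tau, theta0 = theta0, theta1 = theta1)
}

# theta at time t (backwards); breakpoint for stepwise at tau/2.
.demog_intervals <- function(demography) {
  if (demography$type == "constant") {
    list(breaks = numeric(0), thetas = demography$theta)
  } else {
    list(breaks = demography$tau / 2,
         thetas = c(demography$theta1, demography$theta0))
  }
}

# Simulate a coalescent genealogy for tips `tips`, starting at time t0, under
# piecewise-constant demography. Returns open lineages if `stop_at` reached.
.coalesce_tips <- function(tips, t0, demography, stop_at = Inf) {
  iv <- .demog_intervals(demography)
  lineages <- lapply(tips, function(i) i)
  births <- rep(t0, length(lineages))
  branches <- list(); lengths <- numeric(0)
  t <- t0
  while (length(lineages) > 1) {
    j <- length(lineages)
    # current interval
    seg <- findInterval(t, iv$breaks) + 1L
    theta <- iv$thetas[seg]
    seg_end <- if (seg <= length(iv$breaks)) iv$breaks[seg] else Inf
    seg_end <- min(seg_end, stop_at)
    if (theta <= 0) {
      tc <- t  # instantaneous coalescence of the whole interval
    } else {
      w <- stats::rexp(1, rate = j * (j - 1) / theta)
      tc <- t + w
    }
    if (tc > seg_end) {
      t <- seg_end
      if (t >= stop_at) break
      next
    }
    t <- tc
    pair <- sample.int(j, 2)
    a <- pair[1]; b <- pair[2]
    branches[[length(branches) + 1L]] <- lineages[[a]]
    lengths <- c(lengths, t - births[a])
    branches[[length(branches) + 1L]] <- lineages[[b]]
    lengths <- c(lengths, t - births[b])
    merged <- c(lineages[[a]], lineages[[b]])
    lineages[[min(a, b)]] <- merged
    lineages[[max(a, b)]] <- NULL
    births <- births[-max(a, b)]
    births[min(a, b)] <- t
  }
  list(branches = branches, lengths = lengths,
       open = lineages, open_births = births, time = t)
}

#' Simulate a neutral coalescent genealogy
#'
#' @param n sample size (>= 2).
#' @param demography see [demog_constant()] / [demog_stepwise()].
#' @return an object of class `genealogy`: list of `branches` (tip index
#'   sets), `lengths` (branch lengths in mutational units), `n`, `tmrca`.
#' @export
simulate_genealogy <- function(n, demography = demog_constant(1)) {
  stopifnot(n >= 2)
  res <- .coalesce_tips(seq_len(n), 0, demography)
  structure(list(branches = res$branches, lengths = res$lengths, n = n,
                 tmrca = res$time), class = "genealogy")
}

#' Drop mutations on a genealogy and build sequences
#'
#' In `"fixed_s"` mode exactly `S` mutations are placed multinomially by
#' branch length (the conditioning used for simulation-based significance);
#' in `"theta"` mode each branch receives Poisson(length) mutations (branch
#' lengths are already in mutational units). Each mutation occupies its own
#' site drawn without replacement from `L` positions (infinite-sites
#' assumption mapped to a finite alignment); ancestral bases are uniform and
#' the derived state is a random different base.
#'
#' @param genealogy a `genealogy`.
#' @param L number of sites.
#' @param mode `"theta"` or `"fixed_s"`.
#' @param S number of segregating sites for `"fixed_s"` mode.
#' @return a [seq_alignment()] with attributes `realized_S` and `mutations`.
#' @export
drop_mutations <- function(genealogy, L, mode = c("theta", "fixed_s"), S = NULL) {
  mode <- match.arg(mode)
  lens <- genealogy$lengths
  if (mode == "fixed_s") {
    stopifnot(!is.null(S), S >= 0)
    m_b <- if (S == 0) rep(0L, length(lens)) else
      as.integer(stats::rmultinom(1, S, prob = lens / sum(lens)))
  } else {
    m_b <- stats::rpois(length(lens), lens)
  }
  m <- sum(m_b)
  if (m > L) stop(sprintf("capacity error: %d mutations exceed %d sites", m, L),
                  call. = FALSE)
  n <- genealogy$n
  mat <- matrix(sample(DNA_BASES, L, replace = TRUE), n, L, byrow = TRUE)
  sites <- if (m > 0) sample.int(L, m) else integer(0)
  k <- 0L
  mut_branch <- integer(m)
  for (b in seq_along(m_b)) {
    if (m_b[b] > 0) for (r in seq_len(m_b[b])) {
      k <- k + 1L
      site <- sites[k]
      anc <- mat[1, site]
      der <- sample(setdiff(DNA_BASES, anc), 1)
      mat[genealogy$branches[[b]], site] <- der
      mut_branch[k] <- b
    }
  }
  rownames(mat) <- sprintf("s%03d", seq_len(n))
  out <- seq_alignment(mat)
  attr(out, "realized_S") <- m
  attr(out, "mutations") <- data.frame(site = sites, branch = mut_branch)
  out
}

#' Simulate an aligned sample under a neutral coalescent
#'
#' Convenience wrapper: genealogy plus mutations in one call.
#'
#' @inheritParams simulate_genealogy
#' @inheritParams drop_mutations
#' @param seed optional RNG seed (logged as an attribute).
#' @return a [seq_alignment()] with attribute `realized_S`.
#' @export
simulate_sample <- function(n, L, demography = demog_constant(1),
                            mode = c("theta", "fixed_s"), S = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genealogy(n, demography)
  out <- drop_mutations(g, L, mode = match.arg(mode), S = S)
  attr(out, "seed") <- seed
  out
}

#' Simulate a two-deme divergence sample
#'
#' Two populations isolated since `t_div` (per-lineage mutational units) with
#' no migration; lineages remaining at the split join an ancestral pool of
#' size `theta_anc`. Expected between-deme pairwise difference is
#' `2*t_div + theta_anc`, so `t_div` directly controls the expected
#' divergence and Fst.
#'
#' @param n1,n2 sample sizes of the two demes.
#' @param L number of sites.
#' @param theta1,theta2,theta_anc scaled sizes of the demes and the ancestor.
#' @param t_div divergence time (per-lineage mutational units).
#' @param seed optional RNG seed.
#' @return a [seq_alignment()] with attributes `realized_S` and `metadata`
#'   (data frame `sample_id`, `population`, `group`).
#' @export
simulate_structured <- function(n1, n2, L, theta1 = 1, theta2 = 1,
                                theta_anc = 1, t_div = 1, seed = NULL) {
  stopifnot(n1 >= 1, n2 >= 1, t_div >= 0)
  if (!is.null(seed)) set.seed(seed)
  d1 <- .coalesce_tips(seq_len(n1), 0, demog_constant(theta1), stop_at = t_div)
  d2 <- .coalesce_tips(n1 + seq_len(n2), 0, demog_constant(theta2), stop_at = t_div)
  branches <- c(d1$branches, d2$branches)
  lengths <- c(d1$lengths, d2$lengths)
  open <- c(d1$open, d2$open)
  births <- c(rep(t_div, 0), d1$open_births, d2$open_births)
  if (length(open) > 1) {
    anc <- .coalesce_tips_from(open, births, t_div, demog_constant(theta_anc))
    branches <- c(branches, anc$branches)
    lengths <- c(lengths, anc$lengths)
  }
  g <- structure(list(branches = branches, lengths = lengths, n = n1 + n2,
                      tmrca = NA_real_), class = "genealogy")
  out <- drop_mutations(g, L, mode = "theta")
  meta <- data.frame(sample_id = rownames(out$seqs),
                     population = rep(c("popA", "popB"), c(n1, n2)),
                     group = rep(c("grpA", "grpB"), c(n1, n2)),
                     stringsAsFactors = FALSE)
  attr(out, "metadata") <- meta
  attr(out, "seed") <- seed
  out
}

# Continue coalescing pre-existing lineages (with their birth times) under a
# constant demography starting at time t0.
.coalesce_tips_from <- function(lineages, births, t0, demography) {
  branches <- list(); lengths <- numeric(0)
  t <- t0
  theta <- demography$theta
  while (length(lineages) > 1) {
    j <- length(lineages)
    t <- t + stats::rexp(1, rate = j * (j - 1) / theta)
    pair <- sample.int(j, 2)
    a <- pair[1]; b <- pair[2]
    branches[[length(branches) + 1L]] <- lineages[[a]]
    lengths <- c(lengths, t - births[a])
    branches[[length(branches) + 1L]] <- lineages[[b]]
    lengths <- c(lengths, t - births[b])
    lineages[[min(a, b)]] <- c(lineages[[a]], lineages[[b]])
    lineages[[max(a, b)]] <- NULL
    births <- births[-max(a, b)]
    births[min(a, b)] <- t
  }
  list(branches = branches, lengths = lengths)
}

#' Write a simulated sample as FASTA plus metadata TSV
#'
#' Exports through the same plain-text formats the readers consume, so every
#' downstream module can be exercised on synthetic data via the public
#' interface.
#'
#' @param sample a [seq_alignment()], e.g. from [simulate_structured()].
#' @param fasta_path,meta_path output file paths.
#' @param metadata optional metadata data frame; defaults to the sample's
#'   `metadata` attribute or a single-population layout.
#' @export
write_simulated <- function(sample, fasta_path, meta_path, metadata = NULL) {
  if (is.null(metadata)) metadata <- attr(sample, "metadata")
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sample$ids, population = "pop1",
                           group = "group1", stringsAsFactors = FALSE)
  }
  write_alignment(sample, fasta_path)
  utils::write.table(metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, metadata = meta_path))
}

# Summary statistics (S, kbar, k_obs, U_i) straight from a mutated genealogy,
# bypassing sequence construction -- the fast path for null distributions.
.genealogy_stats <- function(genealogy, m_b) {
  n <- genealogy$n
  mutated <- which(m_b > 0)
  S <- sum(m_b)
  U <- integer(n)
  kbar <- 0
  sig <- character(n)
  for (b in mutated) {
    tips <- genealogy$branches[[b]]
    c_b <- length(tips)
    kbar <- kbar + m_b[b] * c_b * (n - c_b)
    if (c_b == 1) U[tips] <- U[tips] + m_b[b]
    sig[tips] <- paste0(sig[tips], ",", b)
  }
  kbar <- kbar / choose(n, 2)
  list(S = S, kbar = kbar, k_obs = length(unique(sig)), U = U)
}

#' Simulate the null distribution of neutrality statistics
#'
#' Repeated neutral coalescent draws with mutations conditioned either on the
#' observed number of segregating sites (`"fixed_s"`, the customary default
#' for simulation-based significance) or on a theta value (`"theta"`).
#' Statistics are computed directly from the mutated genealogies.
#'
#' @param n sample size.
#' @param reps number of replicates.
#' @param conditioning `"fixed_s"` or `"theta"`.
#' @param S segregating sites (fixed-S mode).
#' @param theta scaled mutation parameter (theta mode).
#' @param demography demography for the genealogies (default constant size).
#' @param seed optional RNG seed.
#' @return data frame with columns `D`, `Fs`, `R2`, `S`, `kbar`, `k_obs`.
#' @export
simulate_neutrality_null <- function(n, reps, conditioning = c("fixed_s", "theta"),
                                     S = NULL, theta = NULL,
                                     demography = NULL, seed = NULL) {
  conditioning <- match.arg(conditioning)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(demography)) {
    demography <- if (conditioning == "theta") demog_constant(theta)
                  else demog_constant(1)
  }
  out <- matrix(NA_real_, reps, 6,
                dimnames = list(NULL, c("D", "Fs", "R2", "S", "kbar", "k_obs")))
  for (r in seq_len(reps)) {
    g <- simulate_genealogy(n, demography)
    lens <- g$lengths
    if (conditioning == "fixed_s") {
      m_b <- if (S == 0) rep(0L, length(lens)) else
        as.integer(stats::rmultinom(1, S, prob = lens / sum(lens)))
    } else {
      m_b <- stats::rpois(length(lens), lens)
    }
    st <- .genealogy_stats(g, m_b)
    out[r, "S"] <- st$S
    out[r, "kbar"] <- st$kbar
    out[r, "k_obs"] <- st$k_obs
    if (st$S > 0) {
      out[r, "D"] <- tajimas_d(n, st$S, st$kbar)
      out[r, "R2"] <- rozas_r2(n, st$S, st$kbar, st$U)
      out[r, "Fs"] <- if (st$kbar > 0) fu_fs(n, st$kbar, st$k_obs) else NA_real_
    }
  }
  as.data.frame(out)
}
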