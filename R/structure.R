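# Pairwise difference matrices, hierarchical AMOVA, Phi-statistics and
# gene-flow conversion.

#' Pairwise difference matrix between sequences
#'
#' Entry (i, j) is the number of sites at which sequences i and j differ.
#' By default the alignment is first restricted to the complete-deletion
#' site set, so one fixed site set underlies every entry.
#'
#' @param x a [seq_alignment()] or character matrix.
#' @param filter apply complete-deletion site filtering first.
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_difference_matrix <- function(x, filter = TRUE) {
  mat <- as_seq_matrix(x, filter = filter)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(D)
  code <- matrix(match(mat, DNA_BASES), n, ncol(mat))  # NA = undetermined
  for (i in seq_len(n - 1)) {
    ri <- code[i, ]
    for (j in (i + 1):n) {
      d <- sum(ri != code[j, ], na.rm = TRUE)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Sum over i<j within each label class of d[i,j] / class size; the building
# block of the AMOVA sums of squares (distances enter as squared distances).
ss_within <- function(d, labels) {
  tot <- 0
  for (u in unique(labels)) {
    idx <- which(labels == u)
    if (length(idx) > 1) {
      sub <- d[idx, idx, drop = FALSE]
      tot <- tot + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  tot
}

# Core decomposition used by both the full three-level AMOVA and the
# two-population Phi_st: returns sums of squares, variance components and
# Phi-statistics for given population/group label vectors.
amova_components <- function(d, pop, grp) {
  N <- nrow(d)
  pops <- unique(pop); grps <- unique(grp)
  P <- length(pops); G <- length(grps)
  grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], grp[1])

  ss_total <- sum(d[upper.tri(d)]) / N
  ss_wp <- ss_within(d, pop)
  ss_wg <- ss_within(d, grp)
  ss_ap <- ss_wg - ss_wp           # among populations within groups
  ss_ag <- ss_total - ss_wg        # among groups

  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  n_g <- vapply(grps, function(g) sum(grp == g), 0)
  sum_np2_over_ng <- sum(vapply(seq_along(pops), function(i)
    n_p[i]^2 / n_g[match(grp_of_pop[i], grps)], 0))

  sigma_c <- if (df_wp > 0) ss_wp / df_wp else 0
  if (df_ap > 0) {
    n1 <- (N - sum_np2_over_ng) / df_ap
    sigma_b <- (ss_ap / df_ap - sigma_c) / n1
  } else {
    n1 <- NA_real_; sigma_b <- 0
  }
  if (df_ag > 0) {
    n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  } else {
    n2 <- NA_real_; n3 <- NA_real_; sigma_a <- 0
  }
  sigma_t <- sigma_a + sigma_b + sigma_c
  clamp <- function(x) if (is.finite(x)) max(-1, min(1, x)) else NA_real_
  phi_st <- if (sigma_t > 0) clamp((sigma_a + sigma_b) / sigma_t) else 0
  phi_ct <- if (sigma_t > 0) clamp(sigma_a / sigma_t) else 0
  phi_sc <- if ((sigma_b + sigma_c) > 0) clamp(sigma_b / (sigma_b + sigma_c)) else 0
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within_pops = ss_wp,
              total = ss_total),
       df = c(among_groups = df_ag, among_pops = df_ap, within_pops = df_wp,
              total = N - 1),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c, total = sigma_t),
       phi = c(phi_ct = phi_ct, phi_sc = phi_sc, phi_st = phi_st))
}

#' Three-level analysis of molecular variance
#'
#' Hierarchical partition of squared inter-sequence distances into
#' among-group, among-population-within-group and within-population
#' components, with Phi-statistics
#' \eqn{\Phi_{CT} = \sigma_a^2/\sigma_T^2},
#' \eqn{\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)},
#' \eqn{\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2}.
#' The input matrix of pairwise differences enters the sums of squares
#' directly as squared distances. Negative variance-component estimates are
#' reported as estimated (they are not truncated), but Phi-statistics are
#' clamped to `[-1, 1]`. Permutation significance uses the standard schemes:
#' individuals among populations ignoring groups (Phi_ST), individuals among
#' populations within groups (Phi_SC), whole populations among groups
#' (Phi_CT); p-values use the add-one rule.
#'
#' @param d symmetric matrix of pairwise differences between individual
#'   sequences (see [pairwise_difference_matrix()]).
#' @param grouping metadata data frame aligned with the rows of `d` (columns
#'   `population`, `group`), or a list with `population`/`group` vectors.
#' @param permutations number of permutations for the p-values (0 = skip).
#' @param seed RNG seed for the permutations; required when `permutations > 0`.
#' @return an object of class `amova_result`: data frame `table` (source,
#'   df, SS, variance component, percent of variation), `phi`, `p_values`,
#'   `permutations`, `seed`.
#' @export
amova3 <- function(d, grouping, permutations = 0, seed = NULL) {
  pop <- if (is.data.frame(grouping)) grouping$population else grouping$population
  grp <- if (is.data.frame(grouping)) grouping$group else grouping$group
  if (length(pop) != nrow(d)) stop("grouping does not match distance matrix",
                                   call. = FALSE)
  if (length(unique(grp)) < 2) {
    stop("degenerate design: at least two groups are required for the among-group level; use pairwise_fst() for a two-level analysis",
         call. = FALSE)
  }
  obs <- amova_components(d, pop, grp)
  pct <- 100 * obs$sigma[c("a", "b", "c")] / obs$sigma["total"]
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = obs$df,
    SS = obs$ss,
    variance = c(obs$sigma[c("a", "b", "c")], obs$sigma["total"]),
    percent = c(pct, NA_real_),
    row.names = NULL)

  pvals <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (permutations > 0) {
    if (is.null(seed)) stop("a seed is required for permutation tests", call. = FALSE)
    set.seed(seed)
    N <- nrow(d)
    grp_of_pop <- vapply(unique(pop), function(p) grp[match(p, pop)], grp[1])
    names(grp_of_pop) <- unique(pop)
    ge_st <- 0L; ge_sc <- 0L; ge_ct <- 0L
    for (b in seq_len(permutations)) {
      # Phi_ST: shuffle individuals among populations ignoring groups
      perm <- sample.int(N)
      ge_st <- ge_st + isTRUE(unname(
        amova_components(d, pop[perm], grp_of_pop[pop[perm]])$phi["phi_st"] >=
          obs$phi["phi_st"]))
      # Phi_SC: shuffle individuals among populations within their group
      perm2 <- seq_len(N)
      for (g in unique(grp)) {
        idx <- which(grp == g)
        perm2[idx] <- idx[sample.int(length(idx))]
      }
      ge_sc <- ge_sc + isTRUE(unname(
        amova_components(d, pop[perm2], grp)$phi["phi_sc"] >= obs$phi["phi_sc"]))
      # Phi_CT: shuffle whole populations among groups (keep sizes in pops)
      gop <- grp_of_pop[sample.int(length(grp_of_pop))]
      names(gop) <- names(grp_of_pop)
      ge_ct <- ge_ct + isTRUE(unname(
        amova_components(d, pop, unname(gop[pop]))$phi["phi_ct"] >=
          obs$phi["phi_ct"]))
    }
    pvals <- c(phi_ct = (ge_ct + 1) / (permutations + 1),
               phi_sc = (ge_sc + 1) / (permutations + 1),
               phi_st = (ge_st + 1) / (permutations + 1))
  }
  structure(list(table = tab, phi = obs$phi, p_values = pvals,
                 permutations = permutations, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat(sprintf("Phi_CT = %.5f  Phi_SC = %.5f  Phi_ST = %.5f\n",
              x$phi["phi_ct"], x$phi["phi_sc"], x$phi["phi_st"]))
  if (x$permutations > 0) {
    cat(sprintf("p (CT/SC/ST) = %.4g / %.4g / %.4g  [%d permutations]\n",
                x$p_values["phi_ct"], x$p_values["phi_sc"], x$p_values["phi_st"],
                x$permutations))
  }
  invisible(x)
}

#' Two-population Phi_st with permutation significance and gene flow
#'
#' Two-level molecular-variance decomposition between two populations; the
#' permutation null shuffles individuals between the populations; p uses the
#' add-one rule. `Nm` applies the haploid island-model conversion of
#' [nm_from_fst()].
#'
#' @param x,y sequences of the two populations ([seq_alignment()] or matrix,
#'   same site coordinates).
#' @param permutations number of label permutations.
#' @param seed RNG seed, required when `permutations > 0`.
#' @return list with `fst`, `p_value`, `nm`, `n`, `permutations`, `seed`.
#' @export
pairwise_fst <- function(x, y, permutations = 0, seed = NULL) {
  mx <- as_seq_matrix(x, filter = FALSE)
  my <- as_seq_matrix(y, filter = FALSE)
  if (nrow(mx) < 2 || nrow(my) < 2) stop("both populations need n >= 2", call. = FALSE)
  both <- rbind(mx, my)
  rownames(both) <- paste0("s", seq_len(nrow(both)))
  d <- pairwise_difference_matrix(both, filter = TRUE)
  pop <- rep(c("X", "Y"), c(nrow(mx), nrow(my)))
  fst_two <- function(pp) amova_components(d, pp, rep("g", length(pp)))$phi["phi_sc"]
  obs <- unname(fst_two(pop))
  p <- NA_real_
  if (permutations > 0) {
    if (is.null(seed)) stop("a seed is required for permutation tests", call. = FALSE)
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(permutations)) {
      ge <- ge + (unname(fst_two(pop[sample.int(length(pop))])) >= obs)
    }
    p <- (ge + 1) / (permutations + 1)
  }
  list(fst = obs, p_value = p, nm = nm_from_fst(obs),
       n = c(nrow(mx), nrow(my)), permutations = permutations, seed = seed)
}

#' Migrants per generation from Fst (haploid island model)
#'
#' \eqn{Nm = (1 - F_{st}) / (2 F_{st})} for a haploid, maternally inherited
#' marker. `Fst = 1` gives `Nm = 0`; non-positive `Fst` carries no finite
#' gene-flow signal and returns `Inf` (with `NaN` avoided), not an error.
#'
#' @param fst fixation index.
#' @return migrants per generation (possibly `Inf`).
#' @export
nm_from_fst <- function(fst) {
  ifelse(fst > 0, (1 - pmin(fst, 1)) / (2 * pmin(fst, 1)), Inf)
}

#' Pairwise Fst / divergence matrix across populations
#'
#' Mirror of a gene-flow table: Fst (with Nm in parentheses conceptually)
#' above the diagonal and percentage Dxy (Da) below it.
#'
#' @param aln a [seq_alignment()].
#' @param grouping metadata data frame.
#' @param permutations permutations per population pair.
#' @param seed RNG seed.
#' @return list of matrices `fst`, `nm`, `p`, `dxy_pct`, `da_pct` and a
#'   combined character `display` matrix.
#' @export
geneflow_matrix <- function(aln, grouping, permutations = 0, seed = NULL) {
  grouping <- check_grouping(aln, grouping)
  pops <- sort(unique(grouping$population))
  k <- length(pops)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(pops, pops))
  fst <- mk(); nm <- mk(); pv <- mk(); dxy <- mk(); da <- mk()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mi <- pop_matrix(aln, grouping, pops[i])
    mj <- pop_matrix(aln, grouping, pops[j])
    if (nrow(mi) >= 2 && nrow(mj) >= 2) {
      f <- pairwise_fst(mi, mj, permutations = permutations,
                        seed = if (is.null(seed)) NULL else seed + i * 131L + j)
      fst[i, j] <- f$fst; nm[i, j] <- f$nm; pv[i, j] <- f$p_value
    }
    dv <- dxy_da(mi, mj)
    dxy[j, i] <- dv$dxy_pct; da[j, i] <- dv$da_pct
  }
  display <- matrix("-", k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && !is.na(fst[i, j])) {
      display[i, j] <- sprintf("%.5f (%.2f)", fst[i, j], nm[i, j])
    } else if (i > j && !is.na(dxy[i, j])) {
      display[i, j] <- sprintf("%.3f (%.3f)", dxy[i, j], da[i, j])
    }
  }
  list(fst = fst, nm = nm, p = pv, dxy_pct = dxy, da_pct = da,
       display = display)
}
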