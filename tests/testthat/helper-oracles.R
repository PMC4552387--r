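# Independent brute-force oracles. These deliberately use the most literal
# (slow) formulation of each quantity so they share no code path with the
# package implementation.

BASES <- c("A", "C", "G", "T")

# Random toy alignment: start from one random sequence, apply `nmut`
# mutations at random sites/rows so the data contain segregating sites,
# singletons and shared variants.
random_alignment <- function(n, L, nmut = NULL) {
  if (is.null(nmut)) nmut <- sample(1:min(20, L), 1)
  anc <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  for (m in seq_len(nmut)) {
    site <- sample.int(L, 1)
    rows <- sample.int(n, sample.int(n - 1, 1))
    mat[rows, site] <- sample(setdiff(BASES, mat[rows[1], site]), 1)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}

oracle_pairwise_diff <- function(mat) {
  n <- nrow(mat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- 0
    for (s in seq_len(ncol(mat))) if (mat[i, s] != mat[j, s]) d <- d + 1
    D[i, j] <- d
  }
  D
}

oracle_pi_kbar_S <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    for (s in seq_len(L)) if (mat[i, s] != mat[j, s]) tot <- tot + 1
  }
  S <- 0
  for (s in seq_len(L)) if (length(unique(mat[, s])) > 1) S <- S + 1
  kbar <- tot / (n * (n - 1) / 2)
  list(pi = kbar / L, kbar = kbar, S = S)
}

oracle_tajima <- function(n, S, kbar) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (kbar - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Unsigned Stirling numbers of the first kind via polynomial expansion of
# theta*(theta+1)*...*(theta+n-1): coefficient of theta^k is |s(n,k)|.
oracle_stirling <- function(n) {
  coef <- 1                      # polynomial "1"
  for (m in 0:(n - 1)) {
    # multiply by (theta + m): new_k = old_{k-1} + m * old_k
    coef <- c(0, coef) + m * c(coef, 0)
  }
  coef[-1]                       # drop theta^0 coefficient (zero)
}

oracle_fs <- function(n, theta, k_obs) {
  st <- oracle_stirling(n)
  denom <- prod(theta + 0:(n - 1))
  pk <- st * theta^(1:n) / denom
  sp <- sum(pk[k_obs:n])
  log(sp / (1 - sp))
}

oracle_r2 <- function(mat) {
  n <- nrow(mat)
  U <- rep(0, n)
  S <- 0
  for (s in seq_len(ncol(mat))) {
    tb <- table(mat[, s])
    if (length(tb) > 1) {
      S <- S + 1
      for (b in names(tb)[tb == 1]) U[mat[, s] == b] <- U[mat[, s] == b] + 1
    }
  }
  kbar <- oracle_pi_kbar_S(mat)$kbar
  sqrt(sum((U - kbar / 2)^2) / n) / S
}

# Literal sums-of-squared-distances AMOVA oracle (distances enter as
# squared distances), following the expected-mean-squares coefficients.
oracle_amova <- function(d, pop, grp) {
  N <- nrow(d)
  ssd_set <- function(idx) {
    tot <- 0
    for (i in idx) for (j in idx) tot <- tot + d[i, j]
    tot / (2 * length(idx))
  }
  ss_total <- ssd_set(seq_len(N))
  ss_wp <- 0
  for (p in unique(pop)) ss_wp <- ss_wp + ssd_set(which(pop == p))
  ss_wg <- 0
  for (g in unique(grp)) ss_wg <- ss_wg + ssd_set(which(grp == g))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg
  P <- length(unique(pop)); G <- length(unique(grp))
  n_p <- sapply(unique(pop), function(p) sum(pop == p))
  grp_of <- sapply(unique(pop), function(p) grp[pop == p][1])
  n_g <- sapply(unique(grp), function(g) sum(grp == g))
  names(n_g) <- unique(grp)
  A <- sum(n_p^2 / n_g[grp_of])
  sigma_c <- ss_wp / (N - P)
  n1 <- (N - A) / (P - G)
  sigma_b <- (ss_ap / (P - G) - sigma_c) / n1
  n2 <- (A - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_a <- (ss_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  list(ss = c(ss_ag, ss_ap, ss_wp, ss_total),
       sigma = c(sigma_a, sigma_b, sigma_c))
}

# All spanning trees of the complete graph on n <= 6 labelled nodes, by
# enumerating edge subsets of size n-1; returns the union of edges of all
# minimum-weight spanning trees as a "i-j" character set.
oracle_mst_union <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    D[i, j] <- sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
  }
  pairs <- t(combn(n, 2))
  trees <- combn(nrow(pairs), n - 1)
  spans <- function(cols) {
    parent <- 1:n
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in cols) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    length(unique(sapply(1:n, find))) == 1
  }
  wts <- apply(trees, 2, function(cols) {
    if (!spans(cols)) return(Inf)
    sum(D[pairs[cols, , drop = FALSE]])
  })
  wmin <- min(wts)
  best <- trees[, wts == wmin, drop = FALSE]
  sort(unique(as.vector(apply(best, 2, function(cols)
    paste(pairs[cols, 1], pairs[cols, 2], sep = "-")))))
}

# Clade enumeration by explicit edge-matrix traversal (independent of ape's
# monophyly test): returns list of sorted tip-label sets, one per internal
# node.
oracle_clades <- function(tree) {
  n <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply((n + 1):(n + tree$Nnode), function(nd) sort(desc(nd)))
}

# Random alignment written to temp FASTA + metadata, for reader tests.
write_temp_fasta <- function(seqs, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (is.null(width)) writeLines(s, con)
    else writeLines(substring(s, seq(1, nchar(s), width),
                              pmin(seq(width, nchar(s) + width - 1, width), nchar(s))), con)
  }
  close(con)
  path
}
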