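# Within-population diversity and between-population divergence.

#' Haplotype diversity with Nei's sampling standard deviation
#'
#' Unbiased haplotype (gene) diversity
#' \deqn{Hd = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with sampling variance (Nei 1987)
#' \deqn{V(Hd) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 -
#'   (\sum p_i^2)^2\right) + \sum p_i^2 - (\sum p_i^2)^2\right].}
#'
#' @param x a `haplotype_table`, a vector of haplotype counts, or a vector of
#'   haplotype frequencies summing to 1 (then `n` is required).
#' @param population for a multi-population table, the population column to
#'   restrict to; default pools all samples.
#' @param n sample size, only needed when `x` is a frequency vector.
#' @return list with `Hd`, `sd` and `n`.
#' @export
haplotype_diversity <- function(x, population = NULL, n = NULL) {
  if (inherits(x, "haplotype_table")) {
    cnt <- if (is.null(population)) rowSums(x$counts) else x$counts[, population]
    cnt <- cnt[cnt > 0]
    n <- sum(cnt)
    p <- cnt / n
  } else if (is.null(n)) {
    cnt <- x[x > 0]
    n <- sum(cnt)
    p <- cnt / n
  } else {
    p <- x[x > 0]
    if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1", call. = FALSE)
  }
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  s2 <- sum(p^2); s3 <- sum(p^3)
  Hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)), n = as.integer(n))
}

# Count of differing sites between two rows of a character matrix; sites where
# either sequence is undetermined are skipped.
seq_diff <- function(a, b) {
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  sum(a[ok] != b[ok])
}

#' Nucleotide diversity, mean pairwise differences and segregating sites
#'
#' \eqn{\pi = \sum_{i<j} d_{ij} / (\binom{n}{2} L)} where \eqn{d_{ij}} is the
#' number of differing sites; \eqn{\bar k} is the same sum divided by the
#' number of pairs (absolute differences); `S` is the number of polymorphic
#' sites. Computed on the complete-deletion site set unless
#' `filter = FALSE`. The sampling standard deviation of \eqn{\pi} follows
#' Nei's (1987) no-recombination variance
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#'
#' @param x a [seq_alignment()] or a character matrix of aligned sequences.
#' @param filter apply complete-deletion site filtering first (default TRUE).
#' @return list with `pi`, `sd_pi`, `kbar`, `S`, `n` and `L_eff`.
#' @export
nucleotide_diversity <- function(x, filter = TRUE) {
  mat <- as_seq_matrix(x, filter = filter)
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2) stop("nucleotide diversity undefined for n < 2", call. = FALSE)
  D <- pairwise_difference_matrix(mat, filter = FALSE)
  kbar <- sum(D[upper.tri(D)]) / choose(n, 2)
  S <- sum(apply(mat, 2, function(col) length(unique(col[col %in% DNA_BASES])) > 1))
  pi <- if (L > 0) kbar / L else 0
  v <- if (L > 0) (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2 else 0
  list(pi = pi, sd_pi = sqrt(max(v, 0)), kbar = kbar, S = as.integer(S),
       n = n, L_eff = L)
}

as_seq_matrix <- function(x, filter = TRUE) {
  if (inherits(x, "seq_alignment")) {
    if (filter) x <- filter_complete_sites(x)
    x$seqs
  } else if (is.matrix(x)) {
    x <- toupper(x)
    if (filter) x[, apply(x, 2, function(col) all(col %in% DNA_BASES)), drop = FALSE]
    else x
  } else if (is.character(x)) {
    as_seq_matrix(seq_alignment(x, ids = if (is.null(names(x)))
      paste0("s", seq_along(x)) else names(x)), filter = filter)
  } else stop("cannot interpret sequences", call. = FALSE)
}

#' Jukes-Cantor distance correction
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)} for an observed proportion
#' `p` of differing sites. Saturated inputs (`p >= 0.75`) are rejected.
#'
#' @param p proportion of differing sites, in `[0, 0.75)`.
#' @return corrected substitutions per site, `d >= p`.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("negative distance", call. = FALSE)
  if (any(p >= 0.75)) {
    stop(sprintf("Jukes-Cantor saturation: p = %.4f >= 0.75", max(p)), call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Mean JC-corrected pairwise distance within a set of sequences. The default
# normalisation averages over all n^2 ordered pairs (self-pairs included with
# distance 0), the frequency-weighted convention entering net divergence; the
# unbiased C(n,2) form matches the reported within-population diversity.
jc_pi <- function(mat, pair_label = "within-population", unbiased = FALSE) {
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2 || L == 0) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- seq_diff(mat[i, ], mat[j, ]) / L
    if (p >= 0.75) stop(sprintf("Jukes-Cantor saturation in %s pair (%d,%d)",
                                pair_label, i, j), call. = FALSE)
    tot <- tot + jc_correct(p)
  }
  if (unbiased) tot / choose(n, 2) else 2 * tot / n^2
}

#' Between-population divergence Dxy and net divergence Da
#'
#' `Dxy` is the mean Jukes-Cantor corrected per-site distance over all
#' between-population sequence pairs (correction applied per pair, then
#' averaged); `Da = Dxy - (piX + piY)/2` with the within-population terms
#' also JC-corrected and normalised over all n^2 ordered pairs
#' (frequency-weighted convention, so a population against itself gives
#' exactly `Da = 0`). Both alignments are reduced to their joint
#' complete-deletion site set first so distances are comparable.
#'
#' @param x,y character matrices or [seq_alignment()] objects holding the two
#'   populations' aligned sequences (same original site coordinates).
#' @return list with `dxy`, `da`, `pi_x`, `pi_y`, `L_eff`, and the
#'   percentage forms `dxy_pct`/`da_pct`.
#' @export
dxy_da <- function(x, y) {
  mx <- as_seq_matrix(x, filter = FALSE)
  my <- as_seq_matrix(y, filter = FALSE)
  if (nrow(mx) == 0 || nrow(my) == 0) stop("empty population", call. = FALSE)
  if (ncol(mx) != ncol(my)) stop("alignments have different lengths", call. = FALSE)
  both <- rbind(mx, my)
  keep <- apply(both, 2, function(col) all(col %in% DNA_BASES))
  mx <- mx[, keep, drop = FALSE]; my <- my[, keep, drop = FALSE]
  L <- ncol(mx)
  if (L == 0) stop("no unambiguous sites shared by the two populations", call. = FALSE)
  tot <- 0
  for (i in seq_len(nrow(mx))) for (j in seq_len(nrow(my))) {
    p <- seq_diff(mx[i, ], my[j, ]) / L
    if (p >= 0.75) stop(sprintf("Jukes-Cantor saturation in between-population pair (%d,%d)",
                                i, j), call. = FALSE)
    tot <- tot + jc_correct(p)
  }
  dxy <- tot / (nrow(mx) * nrow(my))
  pi_x <- jc_pi(mx); pi_y <- jc_pi(my)
  da <- dxy - (pi_x + pi_y) / 2
  list(dxy = dxy, da = da, pi_x = pi_x, pi_y = pi_y, L_eff = L,
       dxy_pct = 100 * dxy, da_pct = 100 * da)
}

#' Grant & Bowen diversity category
#'
#' 2x2 rubric on haplotype diversity (high/low) and nucleotide diversity
#' (high/low). Category 1: low Hd, low pi (recent severe bottleneck);
#' category 2: high Hd, low pi (rapid growth from a small ancestral
#' population); category 3: low Hd, high pi; category 4: high Hd, high pi
#' (large stable or admixed population). Thresholds are not fixed by theory;
#' the defaults (0.5, 0.005) are conventional and exposed as arguments.
#'
#' @param Hd haplotype diversity in `[0, 1]`.
#' @param pi nucleotide diversity per site.
#' @param hd_threshold,pi_threshold high/low cut points.
#' @return list with integer `category` and a short `label`.
#' @export
grant_bowen_category <- function(Hd, pi, hd_threshold = 0.5, pi_threshold = 0.005) {
  high_hd <- Hd >= hd_threshold
  high_pi <- pi >= pi_threshold
  category <- ifelse(!high_hd & !high_pi, 1L,
              ifelse(high_hd & !high_pi, 2L,
              ifelse(!high_hd & high_pi, 3L, 4L)))
  labels <- c("low Hd, low pi", "high Hd, low pi",
              "low Hd, high pi", "high Hd, high pi")
  list(category = category, label = labels[category])
}

#' Per-population diversity summary table
#'
#' One row per population (plus a pooled `All` row): n, number of haplotypes,
#' haplotype diversity with SD, nucleotide diversity with SD, segregating
#' sites and mean pairwise differences.
#'
#' @param aln a [seq_alignment()].
#' @param grouping metadata data frame.
#' @param by group samples by `"population"` (default) or `"group"`.
#' @return data frame.
#' @export
diversity_table <- function(aln, grouping, by = c("population", "group")) {
  by <- match.arg(by)
  grouping <- check_grouping(aln, grouping)
  labels <- grouping[[by]]
  units <- c("All", sort(unique(labels)))
  rows <- lapply(units, function(u) {
    idx <- if (u == "All") rep(TRUE, aln$n) else labels == u
    sub <- seq_alignment(aln$seqs[idx, , drop = FALSE], ids = aln$ids[idx])
    tab <- collapse_haplotypes(sub)
    if (sub$n >= 2) {
      hd <- haplotype_diversity(tab)
      nd <- nucleotide_diversity(sub)
      data.frame(unit = u, n = sub$n, h = tab$h, Hd = hd$Hd, sd_Hd = hd$sd,
                 pi = nd$pi, sd_pi = nd$sd_pi, S = nd$S, kbar = nd$kbar,
                 L_eff = nd$L_eff)
    } else {
      data.frame(unit = u, n = sub$n, h = tab$h, Hd = NA_real_, sd_Hd = NA_real_,
                 pi = NA_real_, sd_pi = NA_real_, S = NA_integer_,
                 kbar = NA_real_, L_eff = NA_integer_)
    }
  })
  do.call(rbind, rows)
}
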