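# Haplotype networks: minimum spanning network (union of all minimum
# spanning trees within tolerance epsilon) and median-joining augmentation
# with inferred intermediate (median / Steiner) haplotypes. Only variable
# sites carry information; all variable sites get equal weight.

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

hamming_matrix <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D <- matrix(0L, n, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- sum(chars[i, ] != chars[j, ])
  }
  D
}

# Prim's algorithm: total weight of a minimum spanning tree.
mst_length <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(0L)
  D <- hamming_matrix(seqs)
  intree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  tot <- 0L
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    nxt <- cand[which.min(best[cand])]
    tot <- tot + best[nxt]
    intree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  tot
}

# Restrict sequences to their variable sites (distances are unchanged).
variable_sites <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(chars, 2, function(col) length(unique(col)) > 1)
  list(seqs = apply(chars[, keep, drop = FALSE], 1, paste, collapse = ""),
       sites = which(keep))
}

#' Minimum spanning network of haplotypes
#'
#' Union of all minimum spanning trees of the complete Hamming-distance
#' graph, relaxed by the tolerance `epsilon`: processing distance classes in
#' increasing order, an edge of weight w joins two nodes unless they are
#' already connected by edges of weight <= w - epsilon - 1. With
#' `epsilon = 0` this is exactly the set of edges that occur in at least one
#' minimum spanning tree. Nodes are sorted lexicographically by sequence so
#' the construction is order-invariant.
#'
#' @param haplotypes character vector of distinct equal-length sequences
#'   (or a `haplotype_table`).
#' @param epsilon non-negative integer relaxation parameter (default 0).
#' @return list with `nodes` (data frame `id`, `sequence`) and `edges`
#'   (data frame `from`, `to`, `weight`; ids index `nodes`).
#' @export
build_msn <- function(haplotypes, epsilon = 0) {
  if (inherits(haplotypes, "haplotype_table")) haplotypes <- haplotypes$haplotypes
  haplotypes <- sort(unique(haplotypes))
  n <- length(haplotypes)
  nodes <- data.frame(id = seq_len(n), sequence = haplotypes,
                      stringsAsFactors = FALSE)
  empty <- data.frame(from = integer(0), to = integer(0), weight = integer(0))
  if (n == 1) return(list(nodes = nodes, edges = empty))
  D <- hamming_matrix(haplotypes)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ew <- D[upper.tri(D)]
  ord <- order(ew, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; ew <- ew[ord]
  find <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- empty
  for (w in sort(unique(ew))) {
    # connectivity from edges of weight <= w - epsilon - 1
    parent <- seq_len(n)
    done <- edges[edges$weight <= w - epsilon - 1, , drop = FALSE]
    if (nrow(done)) for (e in seq_len(nrow(done))) {
      ra <- find(parent, done$from[e]); rb <- find(parent, done$to[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    comp <- vapply(seq_len(n), function(i) find(parent, i), integer(1))
    idx <- which(ew == w)
    keep <- comp[pairs[idx, 1]] != comp[pairs[idx, 2]]
    if (any(keep)) {
      edges <- rbind(edges,
                     data.frame(from = pairs[idx[keep], 1],
                                to = pairs[idx[keep], 2], weight = w))
    }
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

# Site-wise median of three sequences: majority state; three-way ties take
# the lexicographically smallest of the three observed states.
median_vector <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  paste(apply(m, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (tb[1] >= 2) names(tb)[1] else sort(col)[1]
  }), collapse = "")
}

# Remove inferred (non-observed) nodes of degree < 3 from a node set,
# repeatedly, rebuilding the network after each removal.
prune_medians <- function(seqs, observed, epsilon = 0) {
  repeat {
    net <- build_msn(seqs, epsilon = epsilon)
    seqs <- net$nodes$sequence
    deg <- tabulate(c(net$edges$from, net$edges$to), nbins = length(seqs))
    drop <- which(!(seqs %in% observed) & deg < 3)
    if (!length(drop)) return(net)
    seqs <- seqs[-drop[1]]
  }
}

#' Median-joining haplotype network
#'
#' Starting from the minimum spanning network, repeatedly considers node
#' triplets (u, v, w) with u--v and u--w network edges, forms their
#' site-wise median (Steiner) vector, and adds the new vectors whose
#' connection cost \eqn{d(m,u)+d(m,v)+d(m,w)} is within `epsilon` of the
#' round's minimum, provided the augmented node set has a strictly shorter
#' minimum spanning tree (the medians must pay for themselves). After each
#' round the network is rebuilt and inferred vectors of degree < 3 carrying
#' no samples are pruned; iteration stops at a fixpoint (cap `max_rounds`).
#' Ties are broken lexicographically so the result is independent of input
#' order.
#'
#' @param haplotypes character vector of distinct sequences or a
#'   `haplotype_table` (frequencies are carried into the node table).
#' @param epsilon non-negative relaxation parameter (default 0, the
#'   customary strict setting).
#' @param max_rounds iteration cap; exceeding it returns the current
#'   network flagged `converged = FALSE`.
#' @return object of class `haplotype_network`: `nodes` (data frame `id`,
#'   `sequence` (full-length), `is_median`, `frequency`), `edges` (`from`,
#'   `to`, `weight`), `epsilon`, `converged`, `variable_sites`, and
#'   `populations` (per-node population composition when built from a
#'   multi-population `haplotype_table`).
#' @export
median_joining_network <- function(haplotypes, epsilon = 0, max_rounds = 100) {
  counts <- NULL
  if (inherits(haplotypes, "haplotype_table")) {
    counts <- haplotypes$counts
    rownames(counts) <- haplotypes$haplotypes
    haplotypes <- haplotypes$haplotypes
  }
  obs_full <- sort(unique(haplotypes))
  vs <- variable_sites(obs_full)
  obs <- vs$seqs
  if (anyDuplicated(obs)) stop("haplotypes not distinct on variable sites",
                               call. = FALSE)
  nodeset <- obs
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    net <- build_msn(nodeset, epsilon = epsilon)
    cand <- character(0); cost <- numeric(0)
    ed <- net$edges
    if (nrow(ed) >= 2) {
      inc <- split(c(ed$to, ed$from), c(ed$from, ed$to))
      for (uc in names(inc)) {
        u <- as.integer(uc)
        nbrs <- sort(unique(inc[[uc]]))
        if (length(nbrs) < 2) next
        cmb <- utils::combn(nbrs, 2)
        for (q in seq_len(ncol(cmb))) {
          v <- cmb[1, q]; w <- cmb[2, q]
          m <- median_vector(net$nodes$sequence[u], net$nodes$sequence[v],
                             net$nodes$sequence[w])
          if (m %in% nodeset || m %in% cand) next
          cand <- c(cand, m)
          cost <- c(cost, hamming(m, net$nodes$sequence[u]) +
                          hamming(m, net$nodes$sequence[v]) +
                          hamming(m, net$nodes$sequence[w]))
        }
      }
    }
    added <- FALSE
    if (length(cand)) {
      lambda <- min(cost)
      new_m <- sort(unique(cand[cost <= lambda + epsilon]))
      if (mst_length(c(nodeset, new_m)) < mst_length(nodeset)) {
        pruned <- prune_medians(sort(c(nodeset, new_m)), obs, epsilon = epsilon)
        if (!identical(pruned$nodes$sequence, nodeset)) {
          nodeset <- pruned$nodes$sequence
          added <- TRUE
        }
      }
    }
    if (!added) { converged <- TRUE; break }
  }
  net <- prune_medians(nodeset, obs, epsilon = epsilon)
  seqs <- net$nodes$sequence
  is_median <- !(seqs %in% obs)
  # rebuild full-length sequences: constant sites from the shared template,
  # variable sites from the (possibly inferred) core sequence
  template <- strsplit(obs_full[1], "")[[1]]
  full_seq <- vapply(seqs, function(s) {
    tmpl <- template
    if (length(vs$sites)) tmpl[vs$sites] <- strsplit(s, "")[[1]]
    paste(tmpl, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  frequency <- rep(0L, length(seqs))
  populations <- rep(NA_character_, length(seqs))
  if (!is.null(counts)) {
    ri <- match(full_seq, rownames(counts))
    ok <- !is.na(ri)
    frequency[ok] <- rowSums(counts)[ri[ok]]
    populations[ok] <- apply(counts[ri[ok], , drop = FALSE], 1, function(r)
      paste(sprintf("%s:%d", colnames(counts), r)[r > 0], collapse = ";"))
  } else {
    frequency[!is_median] <- 1L
  }
  nodes <- data.frame(id = net$nodes$id, sequence = full_seq,
                      is_median = is_median, frequency = frequency,
                      populations = populations, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = net$edges, epsilon = epsilon,
                 converged = converged, variable_sites = vs$sites),
            class = "haplotype_network")
}

total_length <- function(net) sum(net$edges$weight)

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d observed + %d median nodes, %d edges (epsilon = %g)\n",
              sum(!x$nodes$is_median), sum(x$nodes$is_median), nrow(x$edges),
              x$epsilon))
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes a node table and edge list as TSV and (optionally) GraphML.
#'
#' @param net a `haplotype_network`.
#' @param nodes_path,edges_path TSV output paths.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, nodes_path, edges_path, graphml_path = NULL) {
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    con <- file(graphml_path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="seq" for="node" attr.name="sequence" attr.type="string"/>',
      '<key id="med" for="node" attr.name="is_median" attr.type="boolean"/>',
      '<key id="freq" for="node" attr.name="frequency" attr.type="int"/>',
      '<key id="w" for="edge" attr.name="weight" attr.type="int"/>',
      '<graph edgedefault="undirected">'), con)
    for (i in seq_len(nrow(net$nodes))) {
      writeLines(sprintf(
        '<node id="n%d"><data key="seq">%s</data><data key="med">%s</data><data key="freq">%d</data></node>',
        net$nodes$id[i], net$nodes$sequence[i],
        tolower(as.character(net$nodes$is_median[i])), net$nodes$frequency[i]),
        con)
    }
    for (i in seq_len(nrow(net$edges))) {
      writeLines(sprintf('<edge source="n%d" target="n%d"><data key="w">%d</data></edge>',
                         net$edges$from[i], net$edges$to[i],
                         net$edges$weight[i]), con)
    }
    writeLines(c('</graph>', '</graphml>'), con)
  }
  invisible(list(nodes = nodes_path, edges = edges_path, graphml = graphml_path))
}
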