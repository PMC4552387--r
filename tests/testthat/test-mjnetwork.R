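test_that("two haplotypes give a single weighted edge; chains give paths", {
  net <- build_msn(c("AAA", "TTA"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
  net3 <- build_msn(c("AAAA", "TAAA"))
  expect_equal(net3$edges$weight, 1)

  chain <- median_joining_network(c("AAA", "TAA", "TTA"))
  expect_equal(sum(chain$nodes$is_median), 0)
  expect_equal(nrow(chain$edges), 2)
  expect_equal(sort(chain$edges$weight), c(1, 1))
})

test_that("the minimum spanning network is exactly the union of all MSTs", {
  set.seed(71)
  for (rep in 1:15) {
    k <- sample(4:5, 1)
    seqs <- unique(replicate(k, paste(sample(c("A", "T"), 6, replace = TRUE),
                                      collapse = "")))
    if (length(seqs) < 3) next
    net <- build_msn(seqs)
    got <- sort(paste(net$edges$from, net$edges$to, sep = "-"))
    want <- oracle_mst_union(sort(seqs))
    expect_equal(got, want)
  }
})

test_that("a tied 4-haplotype case keeps every MST edge", {
  seqs <- c("AAAA", "AATT", "TTAA", "TTTT")  # symmetric distances, many ties
  net <- build_msn(seqs)
  expect_equal(sort(paste(net$edges$from, net$edges$to, sep = "-")),
               oracle_mst_union(sort(seqs)))
})

test_that("the Steiner triplet gains a median vector cutting the length 4 -> 3", {
  seqs <- c("AAA", "ATT", "TAT")
  expect_equal(paicdemog:::mst_length(seqs), 4)
  net <- median_joining_network(seqs)
  expect_equal(sum(net$nodes$is_median), 1)
  med <- net$nodes$sequence[net$nodes$is_median]
  expect_equal(med, "AAT")  # site-wise majority of the three
  expect_equal(sum(net$edges$weight), 3)
  expect_equal(nrow(net$edges), 3)
  deg <- tabulate(c(net$edges$from, net$edges$to), nbins = nrow(net$nodes))
  expect_equal(deg[net$nodes$is_median], 3)  # medians have degree >= 3
})

test_that("star-like data keep a central hub without medians", {
  seqs <- c("AAAAA", "TAAAA", "ATAAA", "AATAA", "AAATA")
  net <- median_joining_network(seqs)
  expect_equal(sum(net$nodes$is_median), 0)
  deg <- tabulate(c(net$edges$from, net$edges$to), nbins = nrow(net$nodes))
  expect_equal(sort(deg), c(1, 1, 1, 1, 4))
  expect_true(all(net$edges$weight == 1))
})

test_that("networks span all observed haplotypes and stay connected", {
  set.seed(73)
  for (rep in 1:10) {
    mat <- random_alignment(sample(5:8, 1), 20)
    haps <- unique(apply(mat, 1, paste, collapse = ""))
    net <- median_joining_network(haps)
    expect_true(all(haps %in% net$nodes$sequence))
    # connectivity by union-find over edges
    nn <- nrow(net$nodes)
    parent <- seq_len(nn)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(net$edges)) for (e in seq_len(nrow(net$edges))) {
      a <- find(net$edges$from[e]); b <- find(net$edges$to[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    expect_equal(length(unique(vapply(seq_len(nn), find, integer(1)))), 1L)
    # the Steiner-augmented spanning length never exceeds the MST of the
    # observed haplotypes alone
    expect_lte(paicdemog:::mst_length(net$nodes$sequence),
               paicdemog:::mst_length(sort(haps)))
    # every observed haplotype touches the network at its true minimum
    # Hamming distance to the remaining nodes
    D <- paicdemog:::hamming_matrix(net$nodes$sequence)
    for (v in which(!net$nodes$is_median)) {
      inc <- c(net$edges$weight[net$edges$from == v],
               net$edges$weight[net$edges$to == v])
      expect_equal(min(inc), min(D[v, -v]))
    }
  }
})

test_that("construction is invariant to input order", {
  set.seed(79)
  seqs <- c("AAAA", "ATTT", "TATT", "AATT", "TTTA")
  ref <- median_joining_network(seqs)
  for (rep in 1:5) {
    got <- median_joining_network(sample(seqs))
    expect_identical(got$nodes$sequence, ref$nodes$sequence)
    expect_identical(got$edges, ref$edges)
  }
})

test_that("median vectors are site-wise medians of node triples", {
  net <- median_joining_network(c("AAAAA", "AATTC", "ATATG", "TTAAA"))
  meds <- net$nodes$sequence[net$nodes$is_median]
  obs <- net$nodes$sequence
  if (length(meds)) {
    ok <- vapply(meds, function(m) {
      any(apply(combn(setdiff(obs, m), 3), 2, function(tri)
        paicdemog:::median_vector(tri[1], tri[2], tri[3]) == m))
    }, TRUE)
    expect_true(all(ok))
  }
  succeed()
})

test_that("network export writes node, edge and GraphML files", {
  aln <- seq_alignment(c(a = "AAAA", b = "AATT", c = "TTAA", d = "AAAA"))
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     population = c("p1", "p1", "p2", "p2"), group = "g1")
  tab <- collapse_haplotypes(aln, meta)
  net <- median_joining_network(tab)
  expect_equal(sum(net$nodes$frequency), 4)
  nodes <- tempfile(); edges <- tempfile(); gml <- tempfile(fileext = ".graphml")
  write_network(net, nodes, edges, gml)
  nd <- read.delim(nodes)
  expect_equal(nrow(nd), nrow(net$nodes))
  expect_true(any(grepl("p1:1;p2:1", nd$populations)))
  gtxt <- readLines(gml)
  expect_true(any(grepl("<graphml", gtxt)))
  expect_equal(sum(grepl("<edge ", gtxt)), nrow(net$edges))
})
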