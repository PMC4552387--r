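test_that("pairwise difference matrix matches the site-loop oracle", {
  expect_equal(pairwise_difference_matrix(
    seq_alignment(c(a = "AAAA", b = "AAAA")))["a", "b"], 0)
  expect_equal(pairwise_difference_matrix(
    seq_alignment(c(a = "AAAA", b = "AATT")))["a", "b"], 2)
  set.seed(3)
  for (rep in 1:20) {
    mat <- random_alignment(sample(3:9, 1), 15)
    expect_equal(unname(pairwise_difference_matrix(mat, filter = FALSE)),
                 oracle_pairwise_diff(mat))
  }
})

make_toy_design <- function(seed = 1, npop = 4, per = 3, L = 30) {
  set.seed(seed)
  mat <- random_alignment(npop * per, L)
  meta <- data.frame(sample_id = rownames(mat),
                     population = rep(paste0("p", 1:npop), each = per),
                     group = rep(c("g1", "g2"), each = npop / 2 * per))
  list(mat = mat, meta = meta)
}

test_that("three-level AMOVA equals the from-scratch sums-of-squares oracle", {
  toy <- make_toy_design(seed = 21, npop = 4, per = 3)
  d <- pairwise_difference_matrix(toy$mat, filter = FALSE)
  am <- amova3(d, toy$meta)
  want <- oracle_amova(d, toy$meta$population, toy$meta$group)
  expect_equal(unname(am$table$SS), unname(want$ss), tolerance = 1e-10)
  expect_equal(unname(am$table$variance[1:3]), unname(want$sigma), tolerance = 1e-10)
  expect_equal(sum(am$table$percent[1:3]), 100, tolerance = 1e-8)
  expect_equal(sum(am$table$df[1:3]), nrow(d) - 1)
})

test_that("AMOVA on identical sequences gives zero components and Phi = 0", {
  mat <- matrix("A", 8, 10)
  rownames(mat) <- paste0("s", 1:8)
  meta <- data.frame(sample_id = rownames(mat),
                     population = rep(c("p1", "p2", "p3", "p4"), each = 2),
                     group = rep(c("g1", "g2"), each = 4))
  am <- amova3(pairwise_difference_matrix(mat, filter = FALSE), meta)
  expect_equal(unname(am$table$SS), rep(0, 4))
  expect_equal(unname(am$phi), rep(0, 3))
})

test_that("one population per group makes Phi_CT equal the two-level Phi_ST", {
  toy <- make_toy_design(seed = 5, npop = 2, per = 4)
  d <- pairwise_difference_matrix(toy$mat, filter = FALSE)
  meta <- toy$meta
  meta$group <- meta$population  # degenerate hierarchy
  am <- amova3(d, meta)
  f <- pairwise_fst(toy$mat[1:4, ], toy$mat[5:8, ])
  expect_equal(unname(am$phi["phi_ct"]), f$fst, tolerance = 1e-10)
  expect_equal(unname(am$phi["phi_st"]), f$fst, tolerance = 1e-10)
})

test_that("fixed different haplotypes give Fst = 1; permutation p is small", {
  mx <- matrix("A", 4, 12); my <- matrix("C", 4, 12)
  f <- pairwise_fst(mx, my, permutations = 99, seed = 9)
  expect_equal(f$fst, 1)
  expect_lt(f$p_value, 0.05)
  expect_equal(f$nm, 0)
})

test_that("samples from one panmictic pool give Fst near zero", {
  set.seed(8)
  fsts <- replicate(30, {
    sm <- simulate_sample(10, 500, demog_constant(4))
    pairwise_fst(sm$seqs[1:5, ], sm$seqs[6:10, ])$fst
  })
  expect_lt(abs(mean(fsts)), 0.12)
})

test_that("random designs match the brute-force variance-component oracle", {
  set.seed(31)
  for (rep in 1:25) {
    npop <- sample(c(4, 6), 1)
    per <- sample(2:3, 1)
    toy <- make_toy_design(seed = 100 + rep, npop = npop, per = per, L = 20)
    d <- pairwise_difference_matrix(toy$mat, filter = FALSE)
    am <- amova3(d, toy$meta)
    want <- oracle_amova(d, toy$meta$population, toy$meta$group)
    expect_equal(unname(am$table$variance[1:3]), unname(want$sigma),
                 tolerance = 1e-9)
  }
})

test_that("gene-flow conversion follows the haploid island model", {
  expect_equal(nm_from_fst(0.5), 0.5)
  expect_equal(nm_from_fst(1), 0)
  expect_equal(nm_from_fst(0.2), 2.0)
  expect_equal(nm_from_fst(0), Inf)
  expect_equal(nm_from_fst(-0.1), Inf)
})

test_that("a single group is a degenerate design for the three-level AMOVA", {
  toy <- make_toy_design(seed = 2)
  meta <- toy$meta; meta$group <- "g1"
  d <- pairwise_difference_matrix(toy$mat, filter = FALSE)
  expect_error(amova3(d, meta), "degenerate")
})

test_that("permutation p-values are approximately uniform under the null", {
  # individuals drawn from one pool, so the population labels are
  # exchangeable; rejection at alpha = 0.05 should be near nominal
  set.seed(17)
  rej <- replicate(120, {
    sm <- simulate_sample(8, 300, demog_constant(3))
    f <- pairwise_fst(sm$seqs[1:4, ], sm$seqs[5:8, ], permutations = 59,
                      seed = sample.int(1e6, 1))
    f$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)
})

test_that("the gene-flow matrix carries Fst above and Dxy below the diagonal", {
  toy <- make_toy_design(seed = 23, npop = 3 * 2 / 2 * 2, per = 3)  # 6 pops? keep 4
  toy <- make_toy_design(seed = 23, npop = 4, per = 3)
  aln <- seq_alignment(toy$mat)
  gf <- geneflow_matrix(aln, toy$meta)
  expect_true(all(is.na(gf$fst[lower.tri(gf$fst)])))
  expect_true(all(is.na(gf$dxy_pct[upper.tri(gf$dxy_pct)])))
  dv <- dxy_da(toy$mat[toy$meta$population == "p1", ],
               toy$mat[toy$meta$population == "p2", ])
  expect_equal(gf$dxy_pct["p2", "p1"], dv$dxy_pct)
})
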