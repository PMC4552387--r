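lab <- function(tips, regions, paics) {
  data.frame(tip = tips, region = regions, paic = paics,
             stringsAsFactors = FALSE)
}

test_that("monophyly testing agrees with exhaustive clade enumeration", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  set.seed(111)
  for (rep in 1:15) {
    tr <- ape::rtree(12)
    clades <- oracle_clades(tr)
    for (q in 1:5) {
      tips <- sample(tr$tip.label, sample(2:6, 1))
      want <- any(vapply(clades, function(cl) identical(cl, sort(tips)), TRUE))
      expect_equal(is_monophyletic(tr, tips), want)
    }
  }
})

test_that("reciprocally monophyletic island complexes classify as H0", {
  tr <- ape::read.tree(text = "((L1,L2),(V1,V2));")
  labels <- lab(c("L1", "L2", "V1", "V2"),
                c("Luzon", "Luzon", "Visayas", "Visayas"),
                c("GreaterLuzon", "GreaterLuzon", "NegrosPanay", "NegrosPanay"))
  got <- classify_paic_pattern(tr, labels)
  expect_equal(got$hypothesis, "H0")
})

test_that("a complex split into sister region clades classifies as H2", {
  tr <- ape::read.tree(text = "(((N1,N2),(B1,B2)),(V1,V2));")
  labels <- lab(c("N1", "N2", "B1", "B2", "V1", "V2"),
                c("NLuzon", "NLuzon", "Bicol", "Bicol", "Visayas", "Visayas"),
                c("GreaterLuzon", "GreaterLuzon", "GreaterLuzon",
                  "GreaterLuzon", "NegrosPanay", "NegrosPanay"))
  got <- classify_paic_pattern(tr, labels)
  expect_equal(got$hypothesis, "H2")
})

test_that("non-sister region clades within a complex classify as H1", {
  tr <- ape::read.tree(text = "(((N1,N2),(V1,V2)),(B1,B2));")
  labels <- lab(c("N1", "N2", "V1", "V2", "B1", "B2"),
                c("NLuzon", "NLuzon", "Visayas", "Visayas", "Bicol", "Bicol"),
                c("GreaterLuzon", "GreaterLuzon", "NegrosPanay", "NegrosPanay",
                  "GreaterLuzon", "GreaterLuzon"))
  got <- classify_paic_pattern(tr, labels)
  expect_equal(got$hypothesis, "H1")
})

test_that("classification is invariant to tip order and node rotations", {
  labels <- lab(c("N1", "N2", "B1", "B2", "V1", "V2"),
                c("N", "N", "B", "B", "V", "V"),
                c("GL", "GL", "GL", "GL", "NP", "NP"))
  newicks <- c("(((N1,N2),(B1,B2)),(V1,V2));",
               "((V1,V2),((B2,B1),(N2,N1)));",
               "(((B1,B2),(N1,N2)),(V2,V1));")
  got <- vapply(newicks, function(nw)
    classify_paic_pattern(ape::read.tree(text = nw), labels)$hypothesis, "")
  expect_true(all(got == "H2"))
})

test_that("every two-complex labelled tree maps to exactly one category", {
  set.seed(113)
  for (rep in 1:25) {
    tr <- ape::rtree(8)
    labels <- lab(tr$tip.label,
                  sample(c("r1", "r2", "r3"), 8, replace = TRUE),
                  NA)
    labels$paic <- ifelse(labels$region == "r3", "P2", "P1")
    if (length(unique(labels$paic)) < 2) next
    got <- classify_paic_pattern(tr, labels)
    expect_true(got$hypothesis %in% c("H0", "H1", "H2", "other"))
    # H0 and H2 exclusivity: H0 forbids any complex split into monophyletic
    # multi-region clades, which is exactly the H2 trigger
    if (got$hypothesis == "H0") {
      split_any <- any(vapply(got$detail, function(d)
        length(d$regions) >= 2 &&
          all(vapply(d$regions, `[[`, TRUE, "monophyletic")), TRUE))
      expect_false(split_any)
    }
  }
})

test_that("outgroups are pruned and degenerate inputs rejected", {
  tr <- ape::read.tree(text = "(((L1,L2),(V1,V2)),OG);")
  labels <- lab(c("L1", "L2", "V1", "V2", "OG"),
                c("Luzon", "Luzon", "Visayas", "Visayas", "out"),
                c("GL", "GL", "NP", "NP", "outgroup"))
  got <- classify_paic_pattern(tr, labels)
  expect_equal(got$hypothesis, "H0")
  one <- lab(c("L1", "L2"), c("Luzon", "Luzon"), c("GL", "GL"))
  tr2 <- ape::read.tree(text = "(L1,L2);")
  expect_error(classify_paic_pattern(tr2, one), ">= 2 island complexes")
})

test_that("a root polytomy interleaving the complexes is reported as other", {
  tr <- ape::read.tree(text = "(L1,V1,L2,V2);")
  labels <- lab(c("L1", "L2", "V1", "V2"),
                c("Luzon", "Luzon", "Visayas", "Visayas"),
                c("GL", "GL", "NP", "NP"))
  got <- classify_paic_pattern(tr, labels)
  expect_equal(got$hypothesis, "other")
  expect_match(got$note, "polytomy")
})

test_that("classification reports serialize to JSON", {
  tr <- ape::read.tree(text = "((L1,L2),(V1,V2));")
  labels <- lab(c("L1", "L2", "V1", "V2"),
                c("Luzon", "Luzon", "Visayas", "Visayas"),
                c("GL", "GL", "NP", "NP"))
  got <- classify_paic_pattern(tr, labels)
  path <- tempfile(fileext = ".json")
  write_classification(got, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$hypothesis, "H0")
})
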