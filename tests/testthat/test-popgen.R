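meta_for <- function(ids, pop = "P1") {
  n <- length(ids)
  data.frame(specimen_id = ids, population = rep(pop, length.out = n),
             year = rep(2021L, n), habitat = rep("corn", n),
             collection_type = rep("T", n), stringsAsFactors = FALSE)
}

profile_from_counts <- function(counts, population = "P", marker = "m") {
  structure(list(population = population, marker = marker,
                 counts = counts, n_excluded = 0L,
                 frequencies = counts / sum(counts)),
            class = "population_profile")
}

test_that("profiles tally counts, exclusions and normalized frequencies", {
  ids <- paste0("s", 1:10)
  calls <- data.frame(specimen_id = ids,
                      category = c(rep("CSh1", 2), rep("CSh2", 6),
                                   rep("CSh4", 2)),
                      stringsAsFactors = FALSE)
  prof <- build_profile(calls, meta_for(ids), "COIB-category")[[1]]
  expect_equal(unname(prof$frequencies[c("CSh1", "CSh2", "CSh4")]),
               c(0.2, 0.6, 0.2))
  expect_equal(sum(prof$frequencies), 1, tolerance = 1e-12)
  # ambiguous/no_call tallied separately
  calls$category[1:3] <- c("ambiguous", "no_call", "ambiguous")
  prof2 <- build_profile(calls, meta_for(ids), "COIB-category")[[1]]
  expect_equal(sum(prof2$counts), 7L)
  expect_equal(prof2$n_excluded, 3L)
  # empty call set
  prof3 <- build_profile(calls[0, ], meta_for(character(0)), "x")
  expect_equal(length(prof3), 0L)
  # unknown specimens are a validation error
  expect_error(build_profile(calls, meta_for(ids[1:5]), "x"),
               "absent from metadata")
})

test_that("profile frequencies sum to one across random call sets", {
  set.seed(71)
  for (k in 1:10) {
    n <- sample(5:50, 1)
    ids <- paste0("s", 1:n)
    calls <- data.frame(
      specimen_id = ids,
      category = sample(c("CSh1", "CSh2", "CSh4", "ambiguous"), n, TRUE),
      stringsAsFactors = FALSE)
    pops <- sample(c("A", "B"), n, TRUE)
    meta <- meta_for(ids); meta$population <- pops
    for (p in build_profile(calls, meta, "m")) {
      if (sum(p$counts) > 0) {
        expect_equal(sum(p$frequencies), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("G statistic matches direct evaluation and is invariant to
           category order", {
  p1 <- profile_from_counts(c(a = 10L, b = 0L))
  p2 <- profile_from_counts(c(a = 0L, b = 10L))
  cmp <- compare_profiles(p1, p2, replicates = 200, seed = 5)
  expect_equal(cmp$statistic, 40 * log(2), tolerance = 1e-12)
  # reordering categories leaves G unchanged
  p1r <- profile_from_counts(c(b = 0L, a = 10L))
  p2r <- profile_from_counts(c(b = 10L, a = 0L))
  expect_equal(compare_profiles(p1r, p2r, replicates = 10, seed = 1)$statistic,
               cmp$statistic)
})

test_that("identical and proportional profiles give G = 0, permutation p
           near 1", {
  p1 <- profile_from_counts(c(a = 12L, b = 6L, c = 2L))
  cmp <- compare_profiles(p1, p1, replicates = 500, seed = 2)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_gt(cmp$p_permutation, 0.99)
  # proportional rows
  p2 <- profile_from_counts(c(a = 24L, b = 12L, c = 4L))
  expect_equal(compare_profiles(p1, p2, replicates = 10, seed = 1)$statistic,
               0, tolerance = 1e-12)
})

test_that("degenerate comparisons are flagged not-computable", {
  p1 <- profile_from_counts(c(a = 10L))
  p2 <- profile_from_counts(c(a = 7L))
  cmp <- compare_profiles(p1, p2)
  expect_false(cmp$computable)
  expect_true(is.na(cmp$p_permutation))
  expect_error(compare_profiles(p1, profile_from_counts(c(a = 1L),
                                                        marker = "other")),
               "marker")
})

test_that("permutation p is reproducible for a fixed seed", {
  p1 <- profile_from_counts(c(a = 30L, b = 12L, c = 8L))
  p2 <- profile_from_counts(c(a = 18L, b = 25L, c = 7L))
  c1 <- compare_profiles(p1, p2, replicates = 2000, seed = 42)
  c2 <- compare_profiles(p1, p2, replicates = 2000, seed = 42)
  expect_equal(c1$p_permutation, c2$p_permutation)
  expect_true(c1$p_permutation > 0 && c1$p_permutation <= 1)
})

test_that("pairwise comparisons carry Holm-adjusted p values", {
  profs <- list(profile_from_counts(c(a = 30L, b = 10L)),
                profile_from_counts(c(a = 28L, b = 12L)),
                profile_from_counts(c(a = 5L, b = 35L)))
  tab <- compare_all_profiles(profs, replicates = 500, seed = 3)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$p_holm, p.adjust(tab$p_permutation, "holm"))
  expect_true(all(tab$p_holm >= tab$p_permutation))
})

test_that("p-distances use pairwise deletion of gapped/ambiguous columns", {
  expect_equal(pdistance_matrix(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_equal(pdistance_matrix(c(x = "AAAA", y = "AAAT"))["x", "y"], 0.25)
  expect_equal(pdistance_matrix(c(x = "AA-A", y = "AATA"))["x", "y"], 0)
  expect_equal(pdistance_matrix(c(x = "AAYA", y = "AATA"))["x", "y"], 0)
  expect_error(pdistance_matrix(c(x = "--", y = "AA")), "no comparable")
  set.seed(81)
  seqs <- setNames(replicate(5, random_seq(40)), paste0("h", 1:5))
  d <- pdistance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three-taxon NJ reproduces the closed-form terminal branches", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  pat <- tree_patristic(tree, c("A", "B", "C"))
  expect_equal(pat, d, tolerance = 1e-9)
  # terminal branch lengths a = 1, b = 1, c = 3
  el <- setNames(tree$phylo$edge.length,
                 tree$phylo$tip.label[tree$phylo$edge[, 2]])
  expect_equal(unname(el[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers topology and branch lengths from additive matrices", {
  set.seed(91)
  for (k in 1:12) {
    n <- sample(4:8, 1)
    oracle <- random_additive_matrix(n)
    tree <- nj_tree(oracle$d)
    expect_true(same_topology(tree$phylo, oracle$tree))
    expect_equal(tree_patristic(tree, rownames(oracle$d)), oracle$d,
                 tolerance = 1e-9)
    # independent implementation agrees
    ape_tree <- ape::nj(oracle$d)
    expect_true(same_topology(tree$phylo, ape_tree))
  }
})

test_that("NJ output is deterministic under complete ties", {
  d <- matrix(1, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_equal(t1$newick, t2$newick)
  expect_equal(sort(t1$phylo$tip.label), paste0("t", 1:5))
})

test_that("Newick serialization uses 6-decimal branch lengths", {
  oracle <- random_additive_matrix(5)
  tree <- nj_tree(oracle$d)
  lens <- regmatches(tree$newick, gregexpr(":[0-9.-]+", tree$newick))[[1]]
  expect_true(all(grepl("^:-?[0-9]+\\.[0-9]{6}$", lens)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tree, path)
  expect_equal(readLines(path), tree$newick)
})

test_that("SNP C genotype tables tabulate into strain compositions", {
  g <- data.frame(specimen_id = paste0("s", 1:4),
                  genotype = c("C/C", "C/C", "C/R", "R/R"),
                  stringsAsFactors = FALSE)
  prof <- snp_strain_composition(g)
  expect_equal(unname(prof$frequencies), c(0.5, 0.25, 0.25))
  # all C/C: C-strain fixed
  g2 <- data.frame(specimen_id = paste0("s", 1:3), genotype = "C/C",
                   stringsAsFactors = FALSE)
  expect_equal(unname(snp_strain_composition(g2)$frequencies["C-strain"]), 1)
  # no-calls excluded; empty table allowed
  g3 <- rbind(g, data.frame(specimen_id = "s5", genotype = "no-call"))
  expect_equal(snp_strain_composition(g3)$n_excluded, 1L)
  empty <- snp_strain_composition(g[0, ])
  expect_equal(sum(empty$counts), 0L)
  expect_equal(length(empty$frequencies), 0L)
  expect_error(snp_strain_composition(
    data.frame(specimen_id = "x", genotype = "C|C")), "unknown genotype")
})
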