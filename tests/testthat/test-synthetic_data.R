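test_that("a zero-rate pool is the reference with only defining-site edits", {
  ref <- faw_reference("COI")
  pool <- make_variant_pool(ref, "CSh2", 1L, sub_rate = 0, seed = 1)
  c1164 <- 1164L - ref$coordinate_offset + 1L
  c1287 <- 1287L - ref$coordinate_offset + 1L
  expect_equal(pool, edit_seq(ref$sequence, c(c1164, c1287), c("A", "G")))
})

test_that("pools are deterministic given the seed and pairwise distinct", {
  ref <- faw_reference("COI")
  a <- make_variant_pool(ref, "CSh4", 5L, sub_rate = 0.02, seed = 9)
  b <- make_variant_pool(ref, "CSh4", 5L, sub_rate = 0.02, seed = 9)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a), 0L)
  c <- make_variant_pool(ref, "CSh4", 5L, sub_rate = 0.02, seed = 10)
  expect_false(identical(a, c))
})

test_that("every pool member classifies to the requested category", {
  ref <- faw_reference("COI")
  for (cat in c("CSh1", "CSh3", "R_COIB")) {
    pool <- make_variant_pool(ref, cat, 3L, sub_rate = 0.02,
                              seed = match(cat, c("CSh1", "CSh3", "R_COIB")))
    reads <- data.frame(id = paste0(cat, seq_along(pool)), seq = pool,
                        stringsAsFactors = FALSE)
    res <- type_coib(reads, orient = FALSE)
    expect_true(all(res$calls$category == cat), info = cat)
  }
  # Tpi pools carry the strain-defining exon states
  tref <- faw_reference("Tpi")
  for (strain in c("C", "R")) {
    pool <- make_variant_pool(tref, strain, 3L, sub_rate = 0.02,
                              indel_rate = 0.5, seed = 3)
    res <- type_tpi(data.frame(id = paste0(strain, 1:3), seq = pool,
                               stringsAsFactors = FALSE), orient = FALSE)
    expect_true(all(res$calls$strain ==
                      if (strain == "C") "C_Tpi" else "R_Tpi"))
    expect_true(all(res$calls$intron_usable))
  }
})

test_that("allele merging follows the double-trace model", {
  tref <- faw_reference("Tpi")
  win <- intron_window(tref)
  pool <- make_variant_pool(tref, "C", 4L, sub_rate = 0.05, indel_rate = 0,
                            seed = 13)
  # identical alleles pass through unchanged
  expect_equal(fawtyper:::.merge_alleles(pool[1], pool[1]), pool[1])
  # substitution heterozygote: IUPAC overlaps exactly at differing positions
  m <- fawtyper:::.merge_alleles(pool[1], pool[2])
  a <- strsplit(pool[1], "")[[1]]; b <- strsplit(pool[2], "")[[1]]
  mm <- strsplit(m, "")[[1]]
  expect_equal(mm[a == b], a[a == b])
  expect_true(all(!mm[a != b] %in% c("A", "C", "G", "T")))
  # indel heterozygote: N from the first indel difference onward
  del_at <- win[1] + 120L
  shorter <- paste0(substr(pool[1], 1, del_at - 1L),
                    substring(pool[1], del_at + 2L))
  mi <- fawtyper:::.merge_alleles(pool[1], shorter)
  expect_equal(nchar(mi), nchar(pool[1]))
  expect_true(grepl("N", mi))
  first_n <- regexpr("N", mi)[1]
  expect_true(all(strsplit(substring(mi, first_n), "")[[1]] == "N"))
  expect_equal(substr(mi, 1, first_n - 1L), substr(pool[1], 1, first_n - 1L))
})

test_that("an inter-strain pair merges to Y at gTpi183 and calls H_Tpi", {
  tref <- faw_reference("Tpi")
  cpool <- make_variant_pool(tref, "C", 1L, sub_rate = 0, seed = 1)
  rpool <- make_variant_pool(tref, "R", 1L, sub_rate = 0, seed = 1)
  merged <- fawtyper:::.merge_alleles(cpool, rpool)
  expect_equal(substr(merged, 183, 183), "Y")
  res <- type_tpi(data.frame(id = "hyb", seq = merged,
                             stringsAsFactors = FALSE))
  expect_equal(res$calls$strain, "H_Tpi")
})

test_that("substitution heterozygosity in the window makes the intron
           unusable", {
  tref <- faw_reference("Tpi")
  win <- intron_window(tref)
  base <- make_variant_pool(tref, "C", 1L, sub_rate = 0, seed = 1)
  at <- win[1] + 90L
  other <- edit_seq(base, at, if (substr(base, at, at) == "A") "G" else "A")
  merged <- fawtyper:::.merge_alleles(base, other)
  res <- type_tpi(data.frame(id = "het", seq = merged,
                             stringsAsFactors = FALSE))
  expect_equal(res$calls$strain, "C_Tpi")
  expect_false(res$calls$intron_usable)
  expect_equal(res$calls$exclusion_reason, "ambiguous-base")
})

test_that("simulated studies are byte-identical under a fixed seed", {
  cfg <- default_study_config(17, n_specimens = 6L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
  }
  # and a different seed changes the reads
  d3 <- withr::local_tempdir()
  simulate_study(default_study_config(18, n_specimens = 6L), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "coib_reads.fasta")),
                         readLines(file.path(d3, "coib_reads.fasta"))))
})

test_that("adding a population does not perturb earlier populations", {
  cfg1 <- default_study_config(23, n_specimens = 5L)
  cfg2 <- cfg1
  cfg2$populations <- cfg1$populations[1:2]
  full <- simulate_study(cfg1)
  part <- simulate_study(cfg2)
  keep <- full$metadata$population %in% c("TXlike", "FLlike")
  expect_equal(full$coib_reads[keep, ], part$coib_reads)
  expect_equal(full$truth[keep, ], part$truth)
})

test_that("a clean all-homozygote study round-trips every planted label", {
  st <- simulate_study(clean_config(5, n = 15L))
  tc <- type_coib(st$coib_reads, registry = st$pools$coib_registry)
  expect_equal(tc$calls$category, st$truth$coib_category)
  expect_equal(tc$calls$variant_label, st$truth$coib_variant)
  tt <- type_tpi(st$tpi_reads, registry = st$pools$tpi_registry)
  expect_equal(tt$calls$strain, st$truth$expected_strain)
  expect_true(all(tt$calls$intron_usable))
  expect_equal(tt$calls$intron_haplotype, st$truth$expected_intron_haplotype)
})

test_that("an all-CSh2 zero-heterozygosity study reports CSh2 frequency 1", {
  cfg <- clean_config(6, n = 10L,
                      categories = c(CSh1 = 0, CSh2 = 1, CSh3 = 0, CSh4 = 0))
  st <- simulate_study(cfg)
  tc <- type_coib(st$coib_reads, registry = st$pools$coib_registry)
  prof <- build_profile(tc$calls, st$metadata, "COIB-category")[[1]]
  expect_equal(unname(prof$frequencies["CSh2"]), 1)
})

test_that("planted rates are recovered within sampling error (smoke)", {
  cfg <- default_study_config(29, n_specimens = 150L)
  st <- simulate_study(cfg)
  # truth-table frequencies lie near the planted marginals (4 sigma)
  for (p in seq_along(cfg$populations)) {
    pop <- cfg$populations[[p]]
    probs <- planted_category_probs(pop)
    obs <- st$truth$coib_category[st$truth$population == pop$name]
    for (cat in names(probs)) {
      phat <- mean(obs == cat)
      tol <- 4 * sqrt(probs[[cat]] * (1 - probs[[cat]]) / pop$n_specimens)
      expect_lte(abs(phat - probs[[cat]]), max(tol, 1e-12))
    }
  }
  # hybrid truth rate near 0.1
  expect_lt(abs(mean(st$truth$het_type == "interstrain") - 0.1), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(population_config("x", 5,
                                 coib_category_profile = c(CSh1 = 0.5),
                                 strain_profile = c(C = 1, R = 0),
                                 intron_haplotype_profile = c(iC01 = 1),
                                 coib_variant_profiles = list()),
               "summing to 1")
  expect_error(make_variant_pool(faw_reference("COI"), "CSh9", 1),
               "unknown COIB category")
  # an impossible distinctness demand exhausts the attempt budget
  expect_error(make_variant_pool(faw_reference("COI"), "CSh1", 3L,
                                 sub_rate = 0, seed = 1, max_attempts = 5L),
               "attempt budget")
})
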