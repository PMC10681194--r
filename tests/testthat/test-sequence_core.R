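test_that("FASTA parsing yields ids, upper-cased sequences, file order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "acgt", ">s2", "TTAA", "CCGG"), path)
  reads <- read_fasta(path, gene = "COI")
  expect_equal(reads$id, c("s1", "s2"))
  expect_equal(reads$seq, c("ACGT", "TTAACCGG"))
  expect_equal(reads$gene, c("COI", "COI"))
})

test_that("FASTA write-then-read is the identity on valid IUPAC reads", {
  set.seed(11)
  reads <- data.frame(
    id = paste0("r", 1:8),
    seq = replicate(8, random_seq(sample(20:60, 1),
                                  alphabet = c("A", "C", "G", "T", "Y",
                                               "R", "W", "N"))),
    gene = "Tpi", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reads, path)
  expect_equal(read_fasta(path, gene = "Tpi"), reads)
})

test_that("non-IUPAC characters are rejected with record and position", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGX"), path)
  expect_error(read_fasta(path), "bad.*position 4")
})

test_that("identity alignment has no gaps and scores length x match", {
  set.seed(21)
  for (len in c(5, 40, 200)) {
    s <- random_seq(len)
    al <- global_align(s, s)
    expect_equal(al$score, len * 1)
    expect_equal(al$aligned_ref, s)
    expect_equal(al$aligned_read, s)
  }
})

test_that("a single deletion produces exactly one gap column in the read", {
  al <- global_align("ACGT", "ACGGT")
  expect_equal(al$aligned_ref, "ACGGT")
  expect_equal(lengths(regmatches(al$aligned_read,
                                  gregexpr("-", al$aligned_read))), 1L)
  expect_equal(gsub("-", "", al$aligned_read), "ACGT")
})

test_that("alignment degapping recovers the inputs (global alignment)", {
  set.seed(31)
  for (k in 1:20) {
    ref <- random_seq(sample(3:30, 1))
    read <- random_seq(sample(3:30, 1))
    al <- global_align(read, ref)
    expect_equal(gsub("-", "", al$aligned_ref), ref)
    expect_equal(gsub("-", "", al$aligned_read), read)
    expect_equal(nchar(al$aligned_ref), nchar(al$aligned_read))
  }
})

test_that("DP score equals the brute-force enumeration optimum", {
  set.seed(41)
  for (k in 1:60) {
    ref <- random_seq(sample(1:6, 1))
    read <- random_seq(sample(1:6, 1))
    al <- global_align(read, ref)
    expect_equal(al$score, brute_force_align_score(ref, read),
                 info = paste(ref, "vs", read))
  }
})

test_that("IUPAC letters score as matches when state sets intersect", {
  # R = {A,G} against A: full-score identity
  expect_equal(global_align("ARGT", "ACGT")$score, 2)  # R vs C mismatch
  expect_equal(global_align("RCGT", "ACGT")$score, 4)  # R vs A match
  set.seed(51)
  for (k in 1:20) {
    ref <- random_seq(sample(1:5, 1))
    read <- random_seq(sample(1:5, 1), alphabet = c("A", "C", "Y", "N", "W"))
    expect_equal(global_align(read, ref)$score,
                 brute_force_align_score(ref, read))
  }
})

test_that("reverse complement is an involution and handles IUPAC", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AYN"), "NRT")
  set.seed(61)
  for (k in 1:10) {
    s <- random_seq(30, alphabet = c("A", "C", "G", "T", "Y", "R", "N"))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("orientation detection recovers the planted orientation", {
  ref <- faw_reference("COI")
  fwd <- substr(ref$sequence, 10, 400)
  o1 <- orient_read(fwd, ref)
  expect_equal(o1$orientation, "forward")
  o2 <- orient_read(revcomp(fwd), ref)
  expect_equal(o2$orientation, "reverse-complement")
  expect_equal(o2$seq, fwd)
  # identical scores tie to forward (palindromic read)
  o3 <- orient_read("ACGT", "ACGT")
  expect_equal(o3$orientation, "forward")
})

test_that("call_site returns the reference base for an identity read", {
  for (gene in c("COI", "Tpi")) {
    ref <- faw_reference(gene)
    al <- global_align(ref$sequence, ref)
    for (s in ref$sites) {
      cs <- call_site(al, ref, s)
      expect_equal(cs$status, "unambiguous")
      col <- s$ref_position - ref$coordinate_offset + 1L
      expect_equal(cs$observed_states, substr(ref$sequence, col, col))
    }
  }
})

test_that("call_site decodes ambiguity, gaps and missing coverage", {
  ref <- faw_reference("COI")
  col <- 1164L - ref$coordinate_offset + 1L
  # IUPAC R at the site -> {A,G}, ambiguous
  read <- edit_seq(ref$sequence, col, "R")
  cs <- call_site(global_align(read, ref), ref, "mCOI1164D")
  expect_equal(cs$observed_states, c("A", "G"))
  expect_equal(cs$status, "ambiguous")
  # N at the site -> full state set, ambiguous
  readn <- edit_seq(ref$sequence, col, "N")
  csn <- call_site(global_align(readn, ref), ref, "mCOI1164D")
  expect_equal(csn$observed_states, c("A", "C", "G", "T"))
  expect_equal(csn$status, "ambiguous")
  # deletion spanning the site -> gap
  readdel <- paste0(substr(ref$sequence, 1, col - 6),
                    substring(ref$sequence, col + 5))
  csd <- call_site(global_align(readdel, ref), ref, "mCOI1164D")
  expect_equal(csd$status, "gap")
  # read that stops before the site -> uncovered (toy reference whose tail
  # cannot tie with the read suffix)
  toy <- reference_amplicon("COI", "AAAACCCCGGGGTTTT", coordinate_offset = 1L,
                            sites = list(marker_site("s12", "COI", 12L, "G",
                                                     "consistency-check")))
  cst <- call_site(global_align("AAAACC", toy), toy, "s12")
  expect_equal(cst$status, "uncovered")
  # unknown site name is a contract violation
  expect_error(call_site(global_align(read, ref), ref, "gTpi183Y"),
               "not annotated")
})

test_that("reference validation catches bad sites and non-GT donors", {
  expect_error(
    reference_amplicon("COI", "ACGTACGT", coordinate_offset = 1L,
                       sites = list(marker_site("x", "COI", 99L, "A",
                                                "consistency-check"))),
    "outside")
  expect_warning(
    reference_amplicon("Tpi", paste0(strrep("A", 10), strrep("C", 20)),
                       intron_boundary = 11L, intron_length = 10L),
    "splice donor")
})

test_that("reference FASTA + sidecar round trip preserves annotations", {
  ref <- faw_reference("Tpi")
  prefix <- file.path(withr::local_tempdir(), "tpi_ref")
  write_reference(ref, prefix)
  back <- read_reference(prefix)
  expect_equal(back$sequence, ref$sequence)
  expect_equal(names(back$sites), names(ref$sites))
  expect_equal(back$intron_boundary, ref$intron_boundary)
  expect_equal(back$intron_length, ref$intron_length)
})
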