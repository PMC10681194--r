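# Independent oracles and small fixture builders used across the suite.

# Brute-force global alignment score: enumerate every alignment path
# (diagonal / gap-in-read / gap-in-ref moves) and score each complete
# alignment directly, charging each maximal gap run gap_open + k*gap_extend
# and scoring a column as a match when the IUPAC state sets intersect.
# Independent of the DP implementation; tractable for lengths <= 6.
brute_force_align_score <- function(ref, read, match = 1, mismatch = -1,
                                    gap_open = -2, gap_extend = -0.5) {
  r <- strsplit(ref, "")[[1]]
  d <- strsplit(read, "")[[1]]
  states <- lapply(c(r, d), iupac_states)
  rs <- states[seq_along(r)]
  ds <- states[length(r) + seq_along(d)]
  best <- -Inf
  # moves: 1 = diagonal, 2 = gap in read (consume ref), 3 = gap in ref
  rec <- function(i, j, score, prev_move) {
    if (i > length(r) && j > length(d)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(r) && j <= length(d)) {
      s <- if (length(intersect(rs[[i]], ds[[j]]))) match else mismatch
      rec(i + 1L, j + 1L, score + s, 1L)
    }
    if (i <= length(r)) {
      pen <- gap_extend + if (prev_move == 2L) 0 else gap_open
      rec(i + 1L, j, score + pen, 2L)
    }
    if (j <= length(d)) {
      pen <- gap_extend + if (prev_move == 3L) 0 else gap_open
      rec(i, j + 1L, score + pen, 3L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random unrooted binary tree with known branch lengths; its patristic
# (cophenetic) distances form an additive matrix -- the simulation oracle
# for NJ consistency.
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# Patristic distance matrix of a haplotype_tree, in label order of `labels`.
tree_patristic <- function(tree, labels) {
  d <- ape::cophenetic.phylo(tree$phylo)
  d[labels, labels]
}

# Unrooted topology equality via Robinson-Foulds distance.
same_topology <- function(phy1, phy2) {
  ape::dist.topo(ape::unroot(phy1), ape::unroot(phy2))[1] == 0
}

# Tiny Tpi-like reference with a 300-bp intron (window = 180 columns) for
# window-rule tests. Deterministic.
toy_tpi_ref <- function() {
  set.seed(424242)
  exon <- random_seq(198)
  seq <- paste0(exon, "CC",  # pad to 200, then GT donor
                "GT", random_seq(296), "AG", random_seq(40))
  seq <- paste0(substr(seq, 1, 164), "C", substr(seq, 166, nchar(seq)))
  seq <- paste0(substr(seq, 1, 167), "C", substr(seq, 169, nchar(seq)))
  seq <- paste0(substr(seq, 1, 182), "C", substr(seq, 184, nchar(seq)))
  reference_amplicon("Tpi", seq, coordinate_offset = 1L,
                     sites = list(
                       marker_site("gTpi165Y", "Tpi", 165L, c("C", "T"),
                                   "consistency-check"),
                       marker_site("gTpi168Y", "Tpi", 168L, c("C", "T"),
                                   "consistency-check"),
                       marker_site("gTpi183Y", "Tpi", 183L, c("C", "T"),
                                   "strain-diagnostic")),
                     intron_boundary = 201L, intron_length = 300L,
                     provenance = "synthetic test fixture")
}

# Replace single positions of a sequence (1-based), returning the string.
edit_seq <- function(seq, at, to) {
  chars <- strsplit(seq, "")[[1]]
  chars[at] <- to
  paste(chars, collapse = "")
}

# A small zero-noise, all-homozygote single-population config.
clean_config <- function(seed, n = 12L, categories = c(CSh1 = 0.25,
                                                       CSh2 = 0.45,
                                                       CSh3 = 0.05,
                                                       CSh4 = 0.25)) {
  pop <- population_config(
    "Pop1", n, coib_category_profile = categories,
    strain_profile = c(C = 1, R = 0),
    intron_haplotype_profile = c(iC01 = 0.6, iC02 = 0.4),
    coib_variant_profiles = list(CSh1 = c("CSh1[a]" = 1),
                                 CSh2 = c("CSh2[a]" = 0.5, "CSh2[b]" = 0.5),
                                 CSh3 = c("CSh3[a]" = 1),
                                 CSh4 = c("CSh4[a]" = 1)),
    hybrid_rate = 0, heterozygosity = 0, indel_het_fraction = 0)
  simulation_config(seed, list(pop),
                    pool_spec = list(coib_n = c(CSh1 = 1L, CSh2 = 2L,
                                                CSh3 = 1L, CSh4 = 1L,
                                                R_COIB = 1L),
                                     coib_sub_rate = 0.01,
                                     tpi_n = c(C = 2L, R = 1L),
                                     tpi_sub_rate = 0.03,
                                     tpi_indel_rate = 0.5))
}
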