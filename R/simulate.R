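# Synthetic study generator.
#
# Emulates the data-generating process the typing pipeline assumes:
# specimens carry one maternal (mitochondrial) COIB allele and two Z-linked
# Tpi alleles (males are ZZ). Direct Sanger sequencing of the Tpi amplicon
# superimposes both alleles: equal positions read as the base, substitution
# differences as the covering IUPAC letter, and from the first indel
# difference onward the frame-shifted double trace is unreadable, modeled
# as N at every downstream position. Inter-strain hybrids carry one C- and
# one R-strain allele and therefore a C/T overlap (Y) at gTpi183Y.
#
# One global RNG stream is seeded from the config; per-specimen streams are
# derived by (population, counter), so adding a population does not perturb
# the draws of earlier populations.

.sample_one <- function(profile) {
  sample(names(profile), 1L, prob = profile)
}

.check_profile <- function(p, what) {
  if (length(p) == 0L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be a non-negative probability map summing to 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a pool of synthetic variant sequences for one category
#'
#' Builds `n_variants` distinct full-amplicon sequences that all carry the
#' category's defining site states, plus random additional substitutions
#' (and, for Tpi intron pools, indels) confined to the category's mutable
#' region. The first variant is always the unmutated base sequence, so with
#' zero rates and `n_variants = 1` the pool is exactly the reference with
#' only the defining-site edits.
#'
#' @param ref [reference_amplicon()] (COIB or Tpi).
#' @param category For COIB: `"R_COIB"`, `"CSh1"`..`"CSh4"`; for Tpi: the
#'   allele strain `"C"` or `"R"`.
#' @param n_variants Number of distinct sequences to generate.
#' @param sub_rate Per-position substitution probability within the mutable
#'   region.
#' @param indel_rate Probability that a variant carries one 1-3 bp indel
#'   (Tpi pools only; indels are placed strictly inside the TpiI4a200
#'   window).
#' @param seed Integer seed; the pool is deterministic given it.
#' @param max_attempts Attempt budget per variant before giving up.
#' @return Character vector of sequences (length `n_variants`).
#' @export
make_variant_pool <- function(ref, category, n_variants, sub_rate = 0.02,
                              indel_rate = 0, seed = 1L,
                              max_attempts = 200L) {
  stopifnot(n_variants >= 1L)
  base <- strsplit(ref$sequence, "")[[1]]
  if (ref$gene == "COI") {
    states <- switch(category,
                     R_COIB = c("T", "A"), CSh1 = c("A", "A"),
                     CSh2 = c("A", "G"), CSh3 = c("G", "A"),
                     CSh4 = c("G", "G"),
                     stop("unknown COIB category: ", category, call. = FALSE))
    cols <- c(.site_column(ref, "mCOI1164D"), .site_column(ref, "mCOI1287R"))
    base[cols] <- states
    mutable <- setdiff(26:(length(base) - 25L), cols)
    if (indel_rate > 0) {
      stop("indels are not simulated for the (haploid) COIB pool",
           call. = FALSE)
    }
  } else {
    st <- switch(category, C = "C", R = "T",
                 stop("Tpi pool category must be C or R", call. = FALSE))
    cols <- vapply(c("gTpi165Y", "gTpi168Y", "gTpi183Y"),
                   function(s) .site_column(ref, s), 0L)
    base[cols] <- st
    win <- intron_window(ref)
    # the two strains are distinct intron lineages: plant a fixed
    # strain-linked substitution inside the window for the R pool, so C and
    # R haplotype segments can never coincide
    if (category == "R") {
      tag_col <- win[1] + 5L
      base[tag_col] <- c(A = "G", C = "T", G = "A", T = "C")[[base[tag_col]]]
    }
    # keep random edits strictly inside the window, clear of both edges, so
    # the extracted segment carries all the variation
    mutable <- (win[1] + 9L):(win[2] - 10L)
  }
  base_seq <- paste(base, collapse = "")
  .with_seed(seed, {
    pool <- base_seq
    while (length(pool) < n_variants) {
      found <- FALSE
      for (att in seq_len(max_attempts)) {
        v <- base
        hit <- mutable[runif(length(mutable)) < sub_rate]
        for (k in hit) v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1L)
        v <- paste(v, collapse = "")
        if (indel_rate > 0 && runif(1) < indel_rate) {
          L <- sample(1:3, 1L)
          pos <- sample(mutable[mutable + L <= max(mutable)], 1L)
          if (runif(1) < 0.5) {  # deletion
            v <- paste0(substr(v, 1L, pos - 1L), substring(v, pos + L))
          } else {               # insertion
            ins <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
            v <- paste0(substr(v, 1L, pos), ins, substring(v, pos + 1L))
          }
        }
        if (!v %in% pool) { pool <- c(pool, v); found <- TRUE; break }
      }
      if (!found) {
        stop("could not generate ", n_variants,
             " distinct variants within the attempt budget; raise sub_rate",
             call. = FALSE)
      }
    }
    pool
  })
}

#' Per-population simulation settings
#'
#' @param name Population label.
#' @param n_specimens Number of specimens.
#' @param coib_category_profile Probability map over `CSh1`..`CSh4` for
#'   C-strain maternal lineages.
#' @param strain_profile Probability map over `C`/`R` (maternal strain; a
#'   non-hybrid specimen's two Z alleles share it).
#' @param intron_haplotype_profile Probability map over intron haplotype
#'   labels (restricted and renormalized to the allele's strain when
#'   drawing).
#' @param coib_variant_profiles Named list: per CSh category, a probability
#'   map over that category's variant labels.
#' @param hybrid_rate Probability a specimen is an inter-strain (C/R)
#'   hybrid.
#' @param heterozygosity Probability that a non-hybrid specimen's two Z
#'   alleles carry different intron haplotypes.
#' @param indel_het_fraction Share of heterozygous pairs drawn to differ by
#'   an indel (unequal-length haplotypes) rather than substitutions only.
#' @param year,habitat,collection_type Metadata fields (collection_type in
#'   `T`/`C`/`L`).
#' @return A `population_config` list.
#' @export
population_config <- function(name, n_specimens, coib_category_profile,
                              strain_profile, intron_haplotype_profile,
                              coib_variant_profiles, hybrid_rate = 0.1,
                              heterozygosity = 0.5, indel_het_fraction = 0.5,
                              year = 2021L, habitat = "corn",
                              collection_type = "T") {
  .check_profile(coib_category_profile, "coib_category_profile")
  .check_profile(strain_profile, "strain_profile")
  .check_profile(intron_haplotype_profile, "intron_haplotype_profile")
  for (nm in names(coib_variant_profiles)) {
    .check_profile(coib_variant_profiles[[nm]],
                   paste0("coib_variant_profiles$", nm))
  }
  stopifnot(hybrid_rate >= 0, hybrid_rate <= 1,
            heterozygosity >= 0, heterozygosity <= 1,
            indel_het_fraction >= 0, indel_het_fraction <= 1,
            collection_type %in% c("T", "C", "L"))
  structure(list(name = name, n_specimens = as.integer(n_specimens),
                 coib_category_profile = coib_category_profile,
                 strain_profile = strain_profile,
                 intron_haplotype_profile = intron_haplotype_profile,
                 coib_variant_profiles = coib_variant_profiles,
                 hybrid_rate = hybrid_rate, heterozygosity = heterozygosity,
                 indel_het_fraction = indel_het_fraction,
                 year = as.integer(year), habitat = habitat,
                 collection_type = collection_type),
            class = "population_config")
}

#' Study-wide simulation configuration
#'
#' @param seed Integer master seed; every random draw in the study derives
#'   from it.
#' @param populations List of [population_config()] objects.
#' @param pool_spec Pool sizes and mutation rates: a list with
#'   `coib_n` (named integer vector over COIB categories), `coib_sub_rate`,
#'   `tpi_n` (named over `C`/`R`), `tpi_sub_rate`, `tpi_indel_rate`.
#' @param noise_rate Per-base sequencing error probability applied to the
#'   final read (default 0: the original workflow gives no quantitative
#'   Sanger error model).
#' @param revcomp_rate Probability a read is emitted reverse-complemented.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, populations,
                              pool_spec = default_pool_spec(),
                              noise_rate = 0, revcomp_rate = 0) {
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, TRUE, "population_config")),
            noise_rate >= 0, noise_rate <= 1,
            revcomp_rate >= 0, revcomp_rate <= 1)
  structure(list(seed = as.integer(seed), populations = populations,
                 pool_spec = pool_spec, noise_rate = noise_rate,
                 revcomp_rate = revcomp_rate),
            class = "simulation_config")
}

#' Default pool specification
#'
#' Pool sizes chosen to mirror the qualitative structure of surveyed field
#' collections: several lettered variants per common CSh category, one for
#' the rare CSh3, six C-strain and two R-strain intron haplotypes (eight
#' iC labels in all).
#'
#' @return A list consumed by [simulation_config()].
#' @export
default_pool_spec <- function() {
  list(coib_n = c(CSh1 = 3L, CSh2 = 5L, CSh3 = 1L, CSh4 = 3L, R_COIB = 2L),
       coib_sub_rate = 0.01,
       tpi_n = c(C = 6L, R = 2L),
       tpi_sub_rate = 0.03, tpi_indel_rate = 0.5)
}

# Build labeled pools: COIB variant registry (CSh categories), the R_COIB
# pool, Tpi allele pools per strain, and the intron haplotype registry.
.build_pools <- function(config, coib_ref = faw_reference("COI"),
                         tpi_ref = faw_reference("Tpi")) {
  ps <- config$pool_spec
  coib_reg <- haplotype_registry("COIB")
  coib_seqs <- list()
  for (cat in names(ps$coib_n)) {
    pool <- make_variant_pool(coib_ref, cat, ps$coib_n[[cat]],
                              sub_rate = ps$coib_sub_rate,
                              seed = .derive_seed(config$seed, 11,
                                                  match(cat, names(ps$coib_n))))
    if (cat %in% .CSH_CATEGORIES) {
      labs <- character(length(pool))
      for (k in seq_along(pool)) {
        labs[k] <- .next_coib_label(coib_reg, cat)
        coib_reg <- .registry_add(coib_reg, labs[k], pool[k], category = cat,
                                  provenance = "synthetic pool")
      }
      coib_seqs[[cat]] <- setNames(pool, labs)
    } else {
      coib_seqs[[cat]] <- setNames(pool, paste0(cat, "_", seq_along(pool)))
    }
  }
  tpi_reg <- haplotype_registry("TpiI4a200")
  tpi_seqs <- list()
  win <- intron_window(tpi_ref)
  for (strain in names(ps$tpi_n)) {
    pool <- make_variant_pool(tpi_ref, strain, ps$tpi_n[[strain]],
                              sub_rate = ps$tpi_sub_rate,
                              indel_rate = ps$tpi_indel_rate,
                              seed = .derive_seed(config$seed, 13,
                                                  match(strain, names(ps$tpi_n))))
    labs <- character(length(pool))
    for (k in seq_along(pool)) {
      al <- global_align(pool[k], tpi_ref)
      seg <- .extract_window(al, win[1], win[2])$segment
      labs[k] <- .next_intron_label(tpi_reg)
      tpi_reg <- .registry_add(tpi_reg, labs[k], seg, category = strain,
                               provenance = "synthetic pool")
    }
    tpi_seqs[[strain]] <- setNames(pool, labs)
  }
  list(coib_registry = coib_reg, coib_seqs = coib_seqs,
       tpi_registry = tpi_reg, tpi_seqs = tpi_seqs,
       coib_ref = coib_ref, tpi_ref = tpi_ref)
}

# Merge two Tpi allele sequences into the read a direct Sanger trace would
# give: identical -> the allele; equal length -> positionwise IUPAC overlap;
# unequal length -> overlap up to the first indel difference, N afterwards.
.merge_alleles <- function(a1, a2, scoring = align_scoring()) {
  if (a1 == a2) return(a1)
  if (nchar(a1) == nchar(a2)) return(.merge_seqs(a1, a2))
  al <- global_align(a2, a1, scoring)  # a1 as "reference" frame
  c1 <- strsplit(al$aligned_ref, "")[[1]]
  c2 <- strsplit(al$aligned_read, "")[[1]]
  gapcols <- which(c1 == "-" | c2 == "-")
  first_gap <- gapcols[1]
  merged <- character(0)
  for (k in seq_len(first_gap - 1L)) {
    merged <- c(merged, if (c1[k] == c2[k]) c1[k] else iupac_merge(c1[k], c2[k]))
  }
  n_tail <- sum(c1[first_gap:length(c1)] != "-")
  paste0(paste(merged, collapse = ""), strrep("N", n_tail))
}

.apply_noise <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (k in hit) {
    chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
  }
  paste(chars, collapse = "")
}

# Restrict a haplotype profile to the labels of one strain and renormalize.
.strain_profile_part <- function(profile, labels) {
  p <- profile[names(profile) %in% labels]
  if (length(p) == 0L || sum(p) <= 0) {
    stop("intron haplotype profile has no mass on strain labels",
         call. = FALSE)
  }
  p / sum(p)
}

# Simulate one specimen; assumes the caller seeded the RNG.
.simulate_specimen <- function(id, pop, pools, noise_rate, revcomp_rate) {
  strain_m <- .sample_one(pop$strain_profile)
  if (strain_m == "R") {
    coib_category <- "R_COIB"
    coib_variant <- NA_character_
    pool <- pools$coib_seqs$R_COIB
    coib_seq <- pool[[sample(length(pool), 1L)]]
  } else {
    coib_category <- .sample_one(pop$coib_category_profile)
    vp <- pop$coib_variant_profiles[[coib_category]]
    coib_variant <- .sample_one(vp)
    coib_seq <- pools$coib_seqs[[coib_category]][[coib_variant]]
  }
  hybrid <- runif(1) < pop$hybrid_rate
  if (hybrid) {
    strains <- c("C", "R")
    haps <- vapply(strains, function(s) {
      p <- .strain_profile_part(pop$intron_haplotype_profile,
                                names(pools$tpi_seqs[[s]]))
      .sample_one(p)
    }, "")
  } else {
    s <- strain_m
    strains <- c(s, s)
    p <- .strain_profile_part(pop$intron_haplotype_profile,
                              names(pools$tpi_seqs[[s]]))
    het <- length(p) >= 2L && runif(1) < pop$heterozygosity
    if (het) {
      h1 <- .sample_one(p)
      pool_seqs <- pools$tpi_seqs[[s]]
      lens <- nchar(pool_seqs)
      want_indel <- runif(1) < pop$indel_het_fraction
      others <- names(p)[names(p) != h1]
      same_len <- others[lens[others] == lens[h1]]
      diff_len <- others[lens[others] != lens[h1]]
      cand <- if (want_indel && length(diff_len)) diff_len
              else if (!want_indel && length(same_len)) same_len
              else others
      h2 <- if (length(cand) == 1L) cand else .sample_one(p[cand] / sum(p[cand]))
      haps <- c(h1, h2)
    } else {
      h <- .sample_one(p)
      haps <- c(h, h)
    }
  }
  a1 <- pools$tpi_seqs[[strains[1]]][[haps[1]]]
  a2 <- pools$tpi_seqs[[strains[2]]][[haps[2]]]
  tpi_seq <- .merge_alleles(a1, a2)
  expected_strain <- if (strains[1] != strains[2]) "H_Tpi"
                     else if (strains[1] == "C") "C_Tpi" else "R_Tpi"
  identical_alleles <- a1 == a2
  het_type <- if (strains[1] != strains[2]) "interstrain"
              else if (identical_alleles) "none"
              else if (nchar(a1) != nchar(a2)) "indel" else "substitution"
  expected_usable <- identical_alleles
  expected_hap <- if (expected_usable) haps[1] else NA_character_
  coib_read <- .apply_noise(coib_seq, noise_rate)
  tpi_read <- .apply_noise(tpi_seq, noise_rate)
  coib_orient <- "forward"; tpi_orient <- "forward"
  if (revcomp_rate > 0) {
    if (runif(1) < revcomp_rate) {
      coib_read <- revcomp(coib_read); coib_orient <- "reverse-complement"
    }
    if (runif(1) < revcomp_rate) {
      tpi_read <- revcomp(tpi_read); tpi_orient <- "reverse-complement"
    }
  }
  list(coib_read = coib_read, tpi_read = tpi_read,
       truth = data.frame(
         specimen_id = id, population = pop$name,
         coib_category = coib_category, coib_variant = coib_variant,
         maternal_strain = strain_m,
         allele1_strain = strains[1], allele2_strain = strains[2],
         allele1_haplotype = haps[1], allele2_haplotype = haps[2],
         het_type = het_type, expected_strain = expected_strain,
         expected_intron_usable = expected_usable,
         expected_intron_haplotype = expected_hap,
         coib_orientation = coib_orient, tpi_orientation = tpi_orient,
         stringsAsFactors = FALSE))
}

#' Simulate a complete study
#'
#' Generates reads, metadata and a truth table for every population in the
#' configuration; fully reproducible from the config seed. The truth table's
#' `expected_*` columns are the deterministic consequences of the planted
#' alleles under the typing rules (exact at zero noise).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes `coib_reads.fasta`,
#'   `tpi_reads.fasta`, `metadata.tsv`, `truth.tsv` and the pool registries
#'   (`coib_registry.*`, `tpi_registry.*`).
#' @return Invisibly (visibly when `out_dir` is `NULL`), a list with
#'   `coib_reads`, `tpi_reads` (data frames: `id`, `seq`, `gene`),
#'   `metadata`, `truth`, `pools` and `config`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  pools <- .build_pools(config)
  coib <- list(); tpi <- list(); meta <- list(); truth <- list()
  for (p in seq_along(config$populations)) {
    pop <- config$populations[[p]]
    for (i in seq_len(pop$n_specimens)) {
      id <- sprintf("%s-%05d", gsub("[^A-Za-z0-9_.-]", "_", pop$name), i)
      sp <- .with_seed(.derive_seed(config$seed, 1000L + p, i),
                       .simulate_specimen(id, pop, pools,
                                          config$noise_rate,
                                          config$revcomp_rate))
      coib[[id]] <- sp$coib_read
      tpi[[id]] <- sp$tpi_read
      truth[[id]] <- sp$truth
      meta[[id]] <- data.frame(specimen_id = id, population = pop$name,
                               year = pop$year, habitat = pop$habitat,
                               collection_type = pop$collection_type,
                               stringsAsFactors = FALSE)
    }
  }
  out <- list(
    coib_reads = data.frame(id = names(coib), seq = unlist(coib),
                            gene = "COI", stringsAsFactors = FALSE,
                            row.names = NULL),
    tpi_reads = data.frame(id = names(tpi), seq = unlist(tpi),
                           gene = "Tpi", stringsAsFactors = FALSE,
                           row.names = NULL),
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    pools = pools, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$coib_reads, file.path(out_dir, "coib_reads.fasta"))
    write_fasta(out$tpi_reads, file.path(out_dir, "tpi_reads.fasta"))
    write_specimen_metadata(out$metadata, file.path(out_dir, "metadata.tsv"))
    .write_tsv(out$truth, file.path(out_dir, "truth.tsv"))
    write_registry(pools$coib_registry, file.path(out_dir, "coib_registry"))
    write_registry(pools$tpi_registry, file.path(out_dir, "tpi_registry"))
    return(invisible(out))
  }
  out
}

#' Default three-population study configuration
#'
#' Ships a qualitative emulation of surveyed field structure: a CSh2-
#' majority "TXlike" population, a CSh4-majority "FLlike" population and a
#' CSh2-dominated, almost R-free "AZlike" population, each with a
#' predominant variant per CSh category and an iC01-dominated intron
#' profile. All values are synthetic choices, not field estimates.
#'
#' @param seed Master seed.
#' @param n_specimens Specimens per population (length 1 or 3).
#' @param hybrid_rate,heterozygosity,indel_het_fraction,noise_rate,revcomp_rate
#'   Shared rate settings (see [population_config()], [simulation_config()]).
#' @return A [simulation_config()].
#' @export
default_study_config <- function(seed, n_specimens = 500L,
                                 hybrid_rate = 0.1, heterozygosity = 0.5,
                                 indel_het_fraction = 0.5, noise_rate = 0,
                                 revcomp_rate = 0) {
  n <- rep(n_specimens, length.out = 3L)
  variant_profiles <- list(
    CSh1 = c("CSh1[a]" = 0.15, "CSh1[b]" = 0.70, "CSh1[c]" = 0.15),
    CSh2 = c("CSh2[a]" = 0.0575, "CSh2[b]" = 0.0575, "CSh2[c]" = 0.0575,
             "CSh2[d]" = 0.0575, "CSh2[e]" = 0.77),
    CSh3 = c("CSh3[a]" = 1),
    CSh4 = c("CSh4[a]" = 0.045, "CSh4[b]" = 0.91, "CSh4[c]" = 0.045))
  intron_profile <- c(iC01 = 0.55, iC02 = 0.18, iC03 = 0.0425, iC04 = 0.0425,
                      iC05 = 0.0425, iC06 = 0.0425, iC07 = 0.05, iC08 = 0.05)
  mk <- function(name, nn, cats, strains) {
    population_config(name, nn, coib_category_profile = cats,
                      strain_profile = strains,
                      intron_haplotype_profile = intron_profile,
                      coib_variant_profiles = variant_profiles,
                      hybrid_rate = hybrid_rate,
                      heterozygosity = heterozygosity,
                      indel_het_fraction = indel_het_fraction)
  }
  pops <- list(
    mk("TXlike", n[1], c(CSh1 = 0.20, CSh2 = 0.60, CSh3 = 0.02, CSh4 = 0.18),
       c(C = 0.95, R = 0.05)),
    mk("FLlike", n[2], c(CSh1 = 0.10, CSh2 = 0.15, CSh3 = 0.02, CSh4 = 0.73),
       c(C = 0.90, R = 0.10)),
    mk("AZlike", n[3], c(CSh1 = 0.20, CSh2 = 0.65, CSh3 = 0.00, CSh4 = 0.15),
       c(C = 0.985, R = 0.015)))
  simulation_config(seed, pops, noise_rate = noise_rate,
                    revcomp_rate = revcomp_rate)
}

#' Planted marginal category probabilities for a population
#'
#' The marginal probability of each COIB category under the generator:
#' `P(CShk) = P(maternal C) * coib_category_profile[k]`,
#' `P(R_COIB) = P(maternal R)`.
#'
#' @param pop A [population_config()].
#' @return Named numeric vector over `CSh1`..`CSh4`, `R_COIB`.
#' @export
planted_category_probs <- function(pop) {
  pc <- pop$strain_profile[["C"]]
  c(pop$coib_category_profile * pc, R_COIB = unname(pop$strain_profile[["R"]]))
}
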