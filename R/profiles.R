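# Population-level haplotype/strain frequency profiles and their comparison.
#
# Profiles tally category counts per population (or population x year etc.);
# ambiguous/no-call specimens are tracked in n_excluded and never enter the
# frequencies. Profile differentiation is tested with a G-test (2 x k
# log-likelihood ratio) whose null distribution is obtained by permutation:
# specimens are reshuffled between the two populations with fixed margins,
# realized by sampling contingency tables via stats::r2dtable.

.EXCLUDED_CATEGORIES <- c("ambiguous", "no_call", "undetermined",
                          "unknown_combo", "no-call")

#' Build per-population frequency profiles from typing calls
#'
#' @param calls Data frame of per-specimen calls containing `specimen_id`
#'   and the column named by `value`.
#' @param metadata Specimen metadata ([read_specimen_metadata()]).
#' @param marker Marker tag stored on the profiles, e.g. `"COIB-category"`,
#'   `"Tpi-strain"`, `"TpiI4a200"`, `"COIB-variant"`.
#' @param value Name of the column in `calls` holding the category (default
#'   `"category"`); `NA` values and the ambiguous/no-call categories are
#'   tallied in `n_excluded`.
#' @param by Metadata grouping columns (default `"population"`).
#' @return A list of `population_profile` objects, one per group, each with
#'   `population`, `marker`, `counts` (named integer vector), `n_excluded`
#'   and `frequencies` (sum to 1 when the total is positive).
#' @export
build_profile <- function(calls, metadata, marker, value = "category",
                          by = "population") {
  stopifnot(value %in% names(calls), all(by %in% names(metadata)))
  unknown <- setdiff(calls$specimen_id, metadata$specimen_id)
  if (length(unknown)) {
    stop("specimens absent from metadata: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(calls$specimen_id, metadata$specimen_id)
  key <- do.call(paste, c(metadata[idx, by, drop = FALSE], sep = " / "))
  groups <- split(seq_len(nrow(calls)), key)
  lapply(groups, function(rows) {
    v <- calls[[value]][rows]
    excluded <- is.na(v) | v %in% .EXCLUDED_CATEGORIES
    counts <- table(v[!excluded])
    counts <- setNames(as.integer(counts), names(counts))
    total <- sum(counts)
    freqs <- if (total > 0) counts / total else numeric(0)
    structure(list(population = key[rows][1], marker = marker,
                   counts = counts, n_excluded = sum(excluded),
                   frequencies = freqs),
              class = "population_profile")
  })
}

#' @export
print.population_profile <- function(x, ...) {
  cat("Profile [", x$marker, "] ", x$population, ": n = ", sum(x$counts),
      " (+", x$n_excluded, " excluded)\n", sep = "")
  if (length(x$counts)) {
    for (k in seq_along(x$counts)) {
      cat(sprintf("  %-10s %4d  %.3f\n", names(x$counts)[k], x$counts[k],
                  x$frequencies[k]))
    }
  }
  invisible(x)
}

# G statistic for a 2 x k count table: G = 2 * sum O * ln(O / E); O = 0
# terms contribute 0.
.g_statistic <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  O <- as.numeric(tab)
  E <- as.numeric(E)
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

#' Compare two frequency profiles with a permutation G-test
#'
#' @param p1,p2 `population_profile` objects sharing a marker.
#' @param replicates Number of fixed-margin permutation replicates.
#' @param seed Integer seed for the permutation null.
#' @return An object of class `profile_comparison`: `statistic` (G), `df`,
#'   `p_asymptotic` (chi-squared), `p_permutation`
#'   (`(1 + #{G* >= G}) / (replicates + 1)`), `replicates`, `seed` and
#'   `computable`. Categories with zero combined count are dropped; with
#'   fewer than two non-empty categories the result is flagged not
#'   computable and the p values are `NA`.
#' @export
compare_profiles <- function(p1, p2, replicates = 10000L, seed = 1L) {
  stopifnot(inherits(p1, "population_profile"),
            inherits(p2, "population_profile"))
  if (!identical(p1$marker, p2$marker)) {
    stop("profiles do not share a marker", call. = FALSE)
  }
  cats <- union(names(p1$counts), names(p2$counts))
  c1 <- setNames(rep(0L, length(cats)), cats)
  c1[names(p1$counts)] <- p1$counts
  c2 <- setNames(rep(0L, length(cats)), cats)
  c2[names(p2$counts)] <- p2$counts
  keep <- (c1 + c2) > 0
  c1 <- c1[keep]; c2 <- c2[keep]
  base <- list(populations = c(p1$population, p2$population),
               counts = rbind(c1, c2), replicates = as.integer(replicates),
               seed = as.integer(seed))
  if (length(c1) < 2L || sum(c1) == 0 || sum(c2) == 0) {
    return(structure(c(base, list(statistic = NA_real_, df = NA_integer_,
                                  p_asymptotic = NA_real_,
                                  p_permutation = NA_real_,
                                  computable = FALSE)),
                     class = "profile_comparison"))
  }
  tab <- rbind(c1, c2)
  G <- .g_statistic(tab)
  df <- length(c1) - 1L
  p_asym <- stats::pchisq(G, df, lower.tail = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- r2dtable(replicates, rowSums(tab), colSums(tab))
  gs <- vapply(perm, .g_statistic, 0)
  p_perm <- (1 + sum(gs >= G - 1e-12)) / (replicates + 1)
  structure(c(base, list(statistic = G, df = df, p_asymptotic = p_asym,
                         p_permutation = p_perm, computable = TRUE)),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("G-test: ", paste(x$populations, collapse = " vs "), "\n", sep = "")
  if (isTRUE(x$computable)) {
    cat(sprintf("  G = %.4f, df = %d, p (asymptotic) = %.4g, p (permutation, %d reps) = %.4g\n",
                x$statistic, x$df, x$p_asymptotic, x$replicates,
                x$p_permutation))
  } else {
    cat("  not computable (fewer than 2 non-empty categories)\n")
  }
  invisible(x)
}

#' All pairwise profile comparisons with Holm adjustment
#'
#' @param profiles List of `population_profile` objects sharing a marker.
#' @param replicates,seed Passed to [compare_profiles()]; the seed is offset
#'   per pair for independent permutation streams.
#' @return Data frame with one row per pair: populations, G, df, raw
#'   permutation p and Holm-adjusted p.
#' @export
compare_all_profiles <- function(profiles, replicates = 10000L, seed = 1L) {
  stopifnot(length(profiles) >= 2L)
  pairs <- combn(length(profiles), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    cmp <- compare_profiles(profiles[[pairs[1, k]]], profiles[[pairs[2, k]]],
                            replicates = replicates,
                            seed = seed + k)
    data.frame(population1 = cmp$populations[1],
               population2 = cmp$populations[2],
               G = cmp$statistic, df = cmp$df,
               p_permutation = cmp$p_permutation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_permutation, method = "holm")
  out
}

#' Tabulate SNP C genotypes into a strain-composition profile
#'
#' @param genotypes Data frame with columns `specimen_id` and `genotype`,
#'   the latter in `C/C`, `C/R`, `R/R` or `no-call`.
#' @param population Population label stored on the profile.
#' @return A `population_profile` over `C-strain`, `heterozygote`,
#'   `R-strain`; no-calls go to `n_excluded`.
#' @export
snp_strain_composition <- function(genotypes, population = "all") {
  stopifnot(all(c("specimen_id", "genotype") %in% names(genotypes)))
  allowed <- c("C/C", "C/R", "R/R", "no-call")
  bad <- setdiff(unique(genotypes$genotype), allowed)
  if (length(bad)) {
    stop("unknown genotype string(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mapping <- c("C/C" = "C-strain", "C/R" = "heterozygote", "R/R" = "R-strain")
  g <- genotypes$genotype
  excluded <- g == "no-call"
  counts <- table(factor(mapping[g[!excluded]],
                         levels = c("C-strain", "heterozygote", "R-strain")))
  counts <- setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  structure(list(population = population, marker = "SNP-C",
                 counts = counts, n_excluded = sum(excluded),
                 frequencies = if (total > 0) counts / total else numeric(0)),
            class = "population_profile")
}

#' Write profiles as a tidy TSV
#'
#' @param profiles List of `population_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (length(p$counts) == 0L) {
      return(data.frame(population = p$population, marker = p$marker,
                        category = NA_character_, count = 0L,
                        frequency = NA_real_, n_excluded = p$n_excluded,
                        stringsAsFactors = FALSE))
    }
    data.frame(population = p$population, marker = p$marker,
               category = names(p$counts), count = unname(p$counts),
               frequency = unname(p$frequencies),
               n_excluded = p$n_excluded, stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}
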