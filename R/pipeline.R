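# End-to-end pipeline: (optional) simulation -> COIB typing -> Tpi typing ->
# population profiles -> pairwise G-tests -> NJ tree of observed intron
# haplotypes. Results go to files; a structured run summary (stage, counts,
# seed) is serialized alongside and logged to standard error.

.log_stage <- function(run, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  run$log <- c(run$log, msg)
  run
}

#' Run the full typing pipeline
#'
#' @param config A list, or the path of a YAML/JSON file, with elements:
#'   \describe{
#'     \item{simulate}{optional list passed to [default_study_config()]
#'       (`seed`, `n_specimens`, `hybrid_rate`, `heterozygosity`,
#'       `indel_het_fraction`, `noise_rate`, `revcomp_rate`); when present
#'       the study is simulated into `<out>/simulated/`.}
#'     \item{inputs}{otherwise required: `coib_fasta`, `tpi_fasta`,
#'       `metadata` paths.}
#'     \item{registries}{optional path prefixes `coib`, `tpi` of canonical
#'       registries ([write_registry()] layout).}
#'     \item{compare}{optional: `replicates` (default 10000), `seed`
#'       (default 1).}
#'   }
#' @param out_dir Output directory; created if needed.
#' @return An object of class `pipeline_run`: config snapshot, per-stage
#'   record counts (input, typed, excluded by reason), output paths and the
#'   run log. The same summary is written to `<out>/run_summary.json`.
#' @examples
#' cfg <- system.file("extdata", "example_pipeline.json", package = "fawtyper")
#' \donttest{
#' run <- run_pipeline(cfg, tempfile("fawrun"))
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- list(config = config, counts = list(), outputs = character(0),
              log = character(0),
              version = as.character(utils::packageVersion("fawtyper")))

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    stopifnot(!is.null(sim_args$seed))
    cfg <- do.call(default_study_config, sim_args)
    run$seed <- cfg$seed
    sim_dir <- file.path(out_dir, "simulated")
    study <- simulate_study(cfg, out_dir = sim_dir)
    run <- .log_stage(run, "simulate", "seed ", cfg$seed, ", ",
                      nrow(study$metadata), " specimens -> ", sim_dir)
    coib_reads <- study$coib_reads
    tpi_reads <- study$tpi_reads
    metadata <- study$metadata
    # the planted pool registries keep labels canonical downstream
    coib_registry <- study$pools$coib_registry
    tpi_registry <- study$pools$tpi_registry
  } else {
    inp <- config$inputs
    if (is.null(inp$coib_fasta) || is.null(inp$tpi_fasta) ||
        is.null(inp$metadata)) {
      stop("config$inputs must provide coib_fasta, tpi_fasta and metadata",
           call. = FALSE)
    }
    coib_reads <- read_fasta(inp$coib_fasta, gene = "COI")
    tpi_reads <- read_fasta(inp$tpi_fasta, gene = "Tpi")
    metadata <- read_specimen_metadata(inp$metadata)
    coib_registry <- haplotype_registry("COIB")
    tpi_registry <- haplotype_registry("TpiI4a200")
    run <- .log_stage(run, "load", nrow(coib_reads), " COIB reads, ",
                      nrow(tpi_reads), " Tpi reads, ", nrow(metadata),
                      " specimens")
  }
  if (!is.null(config$registries$coib)) {
    coib_registry <- read_registry(config$registries$coib)
  }
  if (!is.null(config$registries$tpi)) {
    tpi_registry <- read_registry(config$registries$tpi)
  }

  # --- COIB typing ---------------------------------------------------------
  coib <- type_coib(coib_reads, registry = coib_registry)
  typed <- coib$calls$category %in% c(.CSH_CATEGORIES, "R_COIB")
  run$counts$coib <- list(
    input = nrow(coib$calls), typed = sum(typed),
    excluded = as.list(table(coib$calls$category[!typed])))
  run <- .log_stage(run, "type-coib", sum(typed), "/", nrow(coib$calls),
                    " categorized")
  coib_path <- file.path(out_dir, "coib_calls.tsv")
  .write_tsv(coib$calls[setdiff(names(coib$calls), "segment")], coib_path)

  # --- Tpi typing ----------------------------------------------------------
  tpi <- type_tpi(tpi_reads, registry = tpi_registry)
  typed_t <- tpi$calls$strain %in% c("C_Tpi", "R_Tpi", "H_Tpi")
  excl_intron <- table(tpi$calls$exclusion_reason[!tpi$calls$intron_usable],
                       useNA = "no")
  run$counts$tpi <- list(
    input = nrow(tpi$calls), typed = sum(typed_t),
    excluded = as.list(table(tpi$calls$strain[!typed_t])))
  run$counts$intron <- list(
    input = nrow(tpi$calls), typed = sum(tpi$calls$intron_usable),
    excluded = as.list(excl_intron))
  run <- .log_stage(run, "type-tpi", sum(typed_t), "/", nrow(tpi$calls),
                    " strain calls; ", sum(tpi$calls$intron_usable),
                    " usable TpiI4a200 segments")
  tpi_path <- file.path(out_dir, "tpi_calls.tsv")
  .write_tsv(tpi$calls, tpi_path)

  # --- Profiles ------------------------------------------------------------
  prof_coib <- build_profile(coib$calls, metadata, "COIB-category")
  prof_strain <- build_profile(tpi$calls, metadata, "Tpi-strain",
                               value = "strain")
  prof_intron <- build_profile(tpi$calls, metadata, "TpiI4a200",
                               value = "intron_haplotype")
  profiles_path <- file.path(out_dir, "profiles.tsv")
  write_profiles(c(prof_coib, prof_strain, prof_intron), profiles_path)
  run <- .log_stage(run, "profile", length(prof_coib), " populations x 3 markers")

  # --- Pairwise comparisons ------------------------------------------------
  cmp_cfg <- config$compare
  reps <- if (is.null(cmp_cfg$replicates)) 10000L else as.integer(cmp_cfg$replicates)
  cseed <- if (is.null(cmp_cfg$seed)) 1L else as.integer(cmp_cfg$seed)
  cmp_path <- file.path(out_dir, "comparisons.tsv")
  if (length(prof_coib) >= 2L) {
    cmp <- compare_all_profiles(prof_coib, replicates = reps, seed = cseed)
    cmp$marker <- "COIB-category"
    if (length(prof_intron) >= 2L) {
      cmp2 <- compare_all_profiles(prof_intron, replicates = reps,
                                   seed = cseed + 1000L)
      cmp2$marker <- "TpiI4a200"
      cmp <- rbind(cmp, cmp2)
    }
    .write_tsv(cmp, cmp_path)
    run <- .log_stage(run, "compare", nrow(cmp), " pairwise G-tests, ",
                      reps, " permutation replicates")
  }

  # --- NJ tree of observed intron haplotypes -------------------------------
  observed <- unique(tpi$calls$intron_haplotype[tpi$calls$intron_usable])
  reg <- tpi$registry$entries
  seqs <- setNames(reg$sequence, reg$label)[observed]
  tree_path <- file.path(out_dir, "intron_haplotypes.nwk")
  if (length(seqs) >= 3L) {
    aligned <- align_haplotypes(seqs)
    d <- pdistance_matrix(aligned)
    tree <- nj_tree(d)
    write_tree(tree, tree_path)
    run <- .log_stage(run, "tree", length(seqs),
                      " haplotypes -> Neighbor-Joining tree")
  } else {
    run <- .log_stage(run, "tree", "skipped (fewer than 3 observed haplotypes)")
  }

  run$outputs <- c(coib_calls = coib_path, tpi_calls = tpi_path,
                   profiles = profiles_path,
                   comparisons = cmp_path, tree = tree_path)
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(run[c("config", "counts", "outputs", "log", "version")],
                       summary_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  run$summary_path <- summary_path
  class(run) <- "pipeline_run"
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (fawtyper ", x$version, ")\n", sep = "")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
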