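## cli: one entry point wiring the modules into the full workflow.
## Subcommands mirror the pipeline stages; every run writes its outputs
## plus a JSON manifest echoing the exact resolved configuration, the
## package version, and stage counts, so any run can be reproduced
## byte-identically from its manifest.

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

cfg_get <- function(config, field, default = NULL) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (is.null(default)) stop("config is missing required field: ", field)
  default
}

write_run_manifest <- function(out_dir, subcommand, config, counts) {
  manifest <- list(subcommand = subcommand,
                   config = config,
                   counts = counts,
                   package = "cdrh3kit",
                   version = as.character(packageVersion("cdrh3kit")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a pipeline subcommand
#'
#' Single programmatic entry point behind the command-line wrapper
#' (`inst/cli/cdrh3kit.R`). Each subcommand reads its inputs, runs the
#' corresponding module functions, writes TSV/JSON outputs into
#' `config$out_dir`, and emits `run_manifest.json` recording the resolved
#' configuration and the counts at every stage.
#'
#' Subcommands and their main config fields:
#' \describe{
#'   \item{simulate-library}{`library` (`positive`/`negative`), `n_reads`,
#'     `seed`; writes `clones.tsv`, `reads.fastq`, `truth_manifest.json`.}
#'   \item{extract}{`fastq`, `library`, filter policy fields; writes
#'     `clones.tsv`, `extraction_log.tsv`, `filter_report.tsv`.}
#'   \item{stats}{`clones`, `weighting`; writes `length_distribution.tsv`
#'     and per-length frequency matrices.}
#'   \item{enrich}{`clones_positive`, `clones_negative`, `loop_length`
#'     (positional) or pooled over all lengths; writes `enrichment.tsv`
#'     and `class_summary.tsv`.}
#'   \item{simulate-assay}{`Ki_pM`, assay condition fields, `noise_sd`,
#'     `seed`; writes `progress_curves.tsv`, `truth_manifest.json`.}
#'   \item{fit-ki}{`curves` (TSV path), condition fields; writes
#'     `ki_fit.json`.}
#'   \item{classify}{`clones_positive`, `clones_negative`, featurizer
#'     fields, `seed`; writes `classifier_report.json`.}
#' }
#'
#' @param subcommand one of `simulate-library`, `extract`, `stats`,
#'   `enrich`, `simulate-assay`, `fit-ki`, `classify`.
#' @param config a named list, or path to a YAML file with the same
#'   fields; must include `out_dir`.
#' @return invisibly, a list of the objects the subcommand produced.
#' @export
run_pipeline <- function(subcommand, config) {
  config <- resolve_config(config)
  out_dir <- cfg_get(config, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(config, "seed", 1L))

  result <- switch(
    subcommand,
    "simulate-library" = {
      lab <- cfg_get(config, "library")
      spec <- if (lab == "positive") {
        positive_library_spec(cfg_get(config, "n_reads", 7789), seed)
      } else if (lab == "negative") {
        negative_library_spec(cfg_get(config, "n_reads", 9907), seed)
      } else stop("config field 'library' must be positive or negative")
      sim <- sample_loops(spec)
      reads <- embed_and_sequence(sim$clones, read_model(), seed + 1L)
      write_clone_table(sim$clones, file.path(out_dir, "clones.tsv"))
      write_fastq(reads, file.path(out_dir, "reads.fastq"))
      write_manifest(sim$manifest,
                     file.path(out_dir, "truth_manifest.json"))
      list(counts = list(clones = nrow(sim$clones), reads = nrow(reads)),
           clones = sim$clones)
    },
    "extract" = {
      reads <- read_fastq(cfg_get(config, "fastq"))
      policy <- filter_policy(
        min_mean_quality = cfg_get(config, "min_mean_quality", 20),
        max_fraction_N = cfg_get(config, "max_fraction_N", 0),
        min_length = cfg_get(config, "min_length", 72),
        max_length = cfg_get(config, "max_length", 600))
      filt <- quality_filter(reads, policy)
      ext <- extract_from_reads(filt$kept, anchor_spec())
      clones <- aggregate_clones(ext$log, cfg_get(config, "library"))
      write_clone_table(clones, file.path(out_dir, "clones.tsv"))
      write.table(ext$log, file.path(out_dir, "extraction_log.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_filter_report(filt$report,
                          file.path(out_dir, "filter_report.tsv"))
      list(counts = list(reads_in = nrow(reads),
                         reads_kept = nrow(filt$kept),
                         by_status = as.list(table(ext$log$status)),
                         clones = nrow(clones)),
           clones = clones)
    },
    "stats" = {
      clones <- read_clone_table(cfg_get(config, "clones"))
      weighting <- cfg_get(config, "weighting", "read_weighted")
      ld <- length_distribution(clones, weighting)
      write_stats_tsv(ld, file.path(out_dir, "length_distribution.tsv"))
      for (L in as.integer(names(ld$probabilities))) {
        f <- positional_frequencies(clones, L, weighting)
        write_stats_tsv(f, file.path(out_dir,
                                     sprintf("frequencies_len%d.tsv", L)))
      }
      list(counts = list(clones = nrow(clones), mode_length = ld$mode),
           length_distribution = ld)
    },
    "enrich" = {
      pos <- read_clone_table(cfg_get(config, "clones_positive"))
      neg <- read_clone_table(cfg_get(config, "clones_negative"))
      weighting <- cfg_get(config, "weighting", "read_weighted")
      L <- config$loop_length
      if (is.null(L)) {
        e <- enrichment(pooled_frequencies(pos, weighting),
                        pooled_frequencies(neg, weighting),
                        mode = "pooled")
        write_stats_tsv(e, file.path(out_dir, "enrichment.tsv"))
      } else {
        e <- enrichment(positional_frequencies(pos, L, weighting),
                        positional_frequencies(neg, L, weighting),
                        mode = "positional")
        write_stats_tsv(e, file.path(out_dir, "enrichment.tsv"))
        write.table(class_summary(e),
                    file.path(out_dir, "class_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(counts = list(clones_positive = nrow(pos),
                         clones_negative = nrow(neg)),
           enrichment = e)
    },
    "simulate-assay" = {
      cond <- assay_condition(
        E_total_nM = cfg_get(config, "E_total_nM", 8),
        S_total_uM = cfg_get(config, "S_total_uM", 20),
        Km_uM = cfg_get(config, "Km_uM", 7.76),
        v0 = cfg_get(config, "v0", 1))
      sim <- simulate_assay(cond, cfg_get(config, "Ki_pM"),
                            noise_sd = cfg_get(config, "noise_sd", 0),
                            seed = seed)
      write_progress_curves(sim$curves,
                            file.path(out_dir, "progress_curves.tsv"))
      write_manifest(sim$manifest,
                     file.path(out_dir, "truth_manifest.json"))
      list(counts = list(curves = length(sim$curves)), sim = sim)
    },
    "fit-ki" = {
      curves <- read_progress_curves(cfg_get(config, "curves"))
      cond <- assay_condition(
        E_total_nM = cfg_get(config, "E_total_nM", 8),
        S_total_uM = cfg_get(config, "S_total_uM", 20),
        Km_uM = cfg_get(config, "Km_uM", 7.76),
        v0 = cfg_get(config, "v0", 1))
      vel <- data.frame(
        I_nM = vapply(curves, attr, numeric(1), "inhibitor_nM"),
        v = vapply(curves, initial_velocity, numeric(1)))
      fit <- fit_ki(vel, cond)
      write_ki_report(fit, file.path(out_dir, "ki_fit.json"))
      list(counts = list(curves = length(curves),
                         converged = fit$converged), fit = fit)
    },
    "classify" = {
      pos <- read_clone_table(cfg_get(config, "clones_positive"))
      neg <- read_clone_table(cfg_get(config, "clones_negative"))
      cfgf <- feature_config(
        featurizer = cfg_get(config, "featurizer", "one_hot_padded"),
        k = cfg_get(config, "k", 1L),
        include_flanks = cfg_get(config, "include_flanks", FALSE),
        variance_retained = cfg_get(config, "variance_retained", 0.95),
        embedding_file = config$embedding_file)
      report <- train_evaluate(labeled_sequences(pos, neg), cfgf,
                               seed = seed)
      write_classifier_report(report,
                              file.path(out_dir,
                                        "classifier_report.json"))
      list(counts = list(n_train = report$n_train,
                         n_test = report$n_test), report = report)
    },
    stop("unknown subcommand: ", subcommand))

  write_run_manifest(out_dir, subcommand, config, result$counts)
  invisible(result)
}
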