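#' Configure a pipeline run
#'
#' One object drives the whole simulate -> QC -> scan -> collapse ->
#' network run.  Unknown fields are rejected; every field is echoed to the
#' run manifest, so a run is fully reproducible from its manifest plus the
#' package version.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate a [simulation_config()] to generate the cohort, or
#'   `NULL` to read `input_prefix` instead.
#' @param input_prefix PLINK prefix (or dosage TSV path) of a pre-existing
#'   cohort; ignored when `simulate` is given.
#' @param input_format `"plink"` or `"dosage_tsv"`.
#' @param annotation_bed BED path with gene/promoter intervals; ignored
#'   when `simulate` is given (the simulated annotation is used).
#' @param qc_preset [qc_thresholds()] preset name, or `NULL` for defaults.
#' @param run_qc logical stage toggle; skip QC on pre-cleaned input.
#' @param screen_alpha screen retention threshold of [scan_pairs()].
#' @param alpha,m,nominal_p [threshold_set()] parameters.
#' @param seed integer seed recorded in the manifest (the simulation seed
#'   lives in `simulate`; this one seeds any future stochastic stage and is
#'   echoed for provenance).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       input_prefix = NULL,
                       input_format = c("plink", "dosage_tsv"),
                       annotation_bed = NULL,
                       qc_preset = "imputed",
                       run_qc = TRUE,
                       screen_alpha = 1e-4,
                       alpha = 0.05,
                       m = 2e8,
                       nominal_p = 1e-5,
                       seed = 1L) {
  input_format <- match.arg(input_format)
  if (is.null(simulate) && is.null(input_prefix)) {
    stop_giscan("either a simulation config or an input prefix is required",
                class = "giscan_invalid_config")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  structure(
    list(out_dir = out_dir, simulate = simulate,
         input_prefix = input_prefix, input_format = input_format,
         annotation_bed = annotation_bed, qc_preset = qc_preset,
         run_qc = isTRUE(run_qc), screen_alpha = screen_alpha,
         alpha = alpha, m = m, nominal_p = nominal_p,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys must be arguments of [run_config()]; a `simulate` block's
#' keys must be arguments of [simulation_config()], with planted
#' interactions as a list of [planted_interaction()] argument sets under
#' `planted_interactions`.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_giscan("the 'yaml' package is required to read config files",
                class = "giscan_missing_dependency")
  }
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "input_format")
  unknown <- setdiff(names(raw), c(known, "input_format"))
  if (length(unknown)) {
    stop_giscan("unknown config keys: ", paste(unknown, collapse = ", "),
                class = "giscan_invalid_config")
  }
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    sim_known <- names(formals(simulation_config))
    sim_unknown <- setdiff(names(sim), sim_known)
    if (length(sim_unknown)) {
      stop_giscan("unknown simulate keys: ",
                  paste(sim_unknown, collapse = ", "),
                  class = "giscan_invalid_config")
    }
    if (!is.null(sim$planted_interactions)) {
      sim$planted_interactions <- lapply(sim$planted_interactions, function(pi) {
        do.call(planted_interaction, pi)
      })
    }
    raw$simulate <- do.call(simulation_config, sim)
  }
  do.call(run_config, raw)
}

# strip non-serialisable structure from a config for the manifest echo
config_echo <- function(config) {
  echo <- unclass(config)
  if (!is.null(echo$simulate)) {
    sim <- unclass(echo$simulate)
    sim$planted_interactions <- lapply(sim$planted_interactions, unclass)
    echo$simulate <- sim
  }
  echo
}

#' Run the full GI pipeline
#'
#' Orchestrates simulate (or load) -> QC -> two-stage pair scan ->
#' gene-pair collapse -> network stage, writing every stage output under
#' `config$out_dir`: the cohort as PLINK bed/bim/fam plus annotation BED
#' and simulation truth (when simulating), `qc_report.tsv`, `pairs.tsv`,
#' `gis.tsv`, `gis_annotated.tsv`, `hub_genes.tsv` and a JSON
#' `manifest.json` reconciling row counts across stages.  Reruns with an
#' identical config produce byte-identical TSVs.  The hub-gene stage
#' follows the convention of counting only intragenic (gene-body to
#' gene-body) GIs at the nominal cutoff with a two-fold OR; the full GI
#' table keeps promoter-mediated GIs.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(packageVersion("giscan")),
    config = config_echo(config),
    stages = list()
  )
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop_giscan("pipeline stage '", name, "' failed: ", conditionMessage(e),
                  class = "giscan_stage_failure")
    })
    list(result = out, seconds = proc.time()[["elapsed"]] - t0)
  }
  outfile <- function(name) file.path(config$out_dir, name)

  # --- stage: cohort ---------------------------------------------------
  st <- t_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      dataset <- sim$dataset
      truth <- sim$truth
      manifest_extra <- NULL
      if (config$simulate$missing_rate > 0 ||
          config$simulate$n_hwe_violating_snps > 0 ||
          config$simulate$n_duplicate_samples > 0) {
        art <- inject_artifacts(dataset, config$simulate,
                                protect_variants = truth$causal_variant_ids)
        dataset <- art$dataset
        manifest_extra <- art$manifest
      }
      write_plink(dataset, outfile("cohort"))
      write_annotation_bed(truth$gene_models, outfile("annotation.bed"))
      if (!is.null(truth$causal)) {
        write_results_tsv(truth$causal, outfile("truth_interactions.tsv"))
      }
      write_results_tsv(
        data.frame(variant_id = names(truth$allele_freqs),
                   allele_freq = unname(truth$allele_freqs)),
        outfile("truth_allele_freqs.tsv")
      )
      list(dataset = dataset, gene_models = truth$gene_models,
           truth = truth, artifacts = manifest_extra)
    } else {
      dataset <- switch(config$input_format,
                        plink = read_plink(config$input_prefix),
                        dosage_tsv = read_dosage_tsv(config$input_prefix))
      gene_models <- read_annotation_bed(config$annotation_bed)
      list(dataset = dataset, gene_models = gene_models,
           truth = NULL, artifacts = NULL)
    }
  })
  dataset <- st$result$dataset
  gene_models <- st$result$gene_models
  manifest$stages$input <- list(
    seconds = st$seconds,
    n_samples = nrow(dataset$samples), n_variants = nrow(dataset$variants)
  )

  # --- stage: qc -------------------------------------------------------
  if (config$run_qc) {
    st <- t_stage("qc", {
      th <- if (is.null(config$qc_preset)) qc_thresholds() else
        qc_thresholds(config$qc_preset)
      apply_qc(dataset, th)
    })
    dataset <- st$result$dataset
    write_results_tsv(qc_report_table(st$result$report),
                      outfile("qc_report.tsv"))
    manifest$stages$qc <- list(
      seconds = st$seconds,
      n_samples = nrow(dataset$samples), n_variants = nrow(dataset$variants)
    )
  }

  # --- stage: scan -----------------------------------------------------
  st <- t_stage("scan", {
    assignment <- map_snps_to_genes(dataset, gene_models)
    pairs <- eligible_intergenic_pairs(assignment)
    results <- scan_pairs(dataset, pairs, screen_alpha = config$screen_alpha)
    list(assignment = assignment, results = results)
  })
  assignment <- st$result$assignment
  pair_results <- st$result$results
  write_results_tsv(pair_results, outfile("pairs.tsv"))
  manifest$stages$scan <- list(
    seconds = st$seconds,
    n_pairs = nrow(pair_results),
    n_followed_up = sum(pair_results$status %in%
                          c("ok", "non_converged", "degenerate") &
                          !is.na(pair_results$p_screen) &
                          pair_results$p_screen <= config$screen_alpha)
  )

  # --- stage: collapse -------------------------------------------------
  st <- t_stage("collapse", collapse_to_gene_pairs(pair_results, assignment))
  gis <- st$result
  write_results_tsv(gis, outfile("gis.tsv"))
  manifest$stages$collapse <- list(seconds = st$seconds, n_gis = nrow(gis))

  # --- stage: network --------------------------------------------------
  st <- t_stage("network", {
    th <- threshold_set(alpha = config$alpha, m = config$m,
                        nominal_p = config$nominal_p)
    annotated <- call_significant(gis, th)
    hub_input <- annotated[annotated$sig_nominal & annotated$intragenic, ,
                           drop = FALSE]
    hubs <- hub_degrees(twofold_filter(hub_input))
    list(annotated = annotated, hubs = hubs, thresholds = th,
         bh_cutoff = attr(annotated, "bh_cutoff"))
  })
  write_results_tsv(st$result$annotated, outfile("gis_annotated.tsv"))
  write_results_tsv(st$result$hubs, outfile("hub_genes.tsv"))
  manifest$stages$network <- list(
    seconds = st$seconds,
    n_significant_nominal = sum(st$result$annotated$sig_nominal),
    n_significant_fdr = sum(st$result$annotated$sig_fdr),
    n_significant_bonferroni = sum(st$result$annotated$sig_bonferroni),
    bh_cutoff = st$result$bh_cutoff,
    n_hub_genes = nrow(st$result$hubs)
  )

  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
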