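#' Pipeline configuration
#'
#' One object carrying every stage parameter at its published default
#' plus stage toggles, input paths and the master seed. Unknown keys are
#' rejected; the object round-trips losslessly through YAML.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    stages = list(qc = TRUE, network = TRUE, da = TRUE,
                  enrichment = FALSE, panel = TRUE, traits = TRUE),
    simulate = NULL,            # a cohort_config, or NULL to read inputs
    matrix_path = NULL, qc_path = NULL, meta_path = NULL,
    traits_path = NULL, gmt_path = NULL,
    out_dir = NULL,
    power = 7.5, deep_split = 4, min_module_size = 10,
    merge_cut_height = 0.07, missing_threshold = 0.5, z_cutoff = 3,
    n_boot = 1000, k = 5, da_alpha = 0.05,
    da_pair = NULL,             # group pair for the panel contrast
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    config_error(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` a `pipeline_config`;
#'   `write_pipeline_config` the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulate
  raw$simulate <- NULL
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(sim)) {
    # YAML maps come back as lists; restore the named-vector fields
    for (nm in c("n_samples_per_group", "age_mean", "age_sd",
                 "sex_prop_male", "module_sizes")) {
      if (!is.null(sim[[nm]])) sim[[nm]] <- unlist(sim[[nm]])
    }
    for (nm in c("trait_loadings", "module_group_shift")) {
      if (!is.null(sim[[nm]])) sim[[nm]] <- lapply(sim[[nm]], unlist)
    }
    cfg$simulate <- do.call(cohort_config, sim)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$simulate)) {
    sim <- unclass(out$simulate)
    # named vectors serialize as YAML maps, not bare sequences
    for (nm in c("n_samples_per_group", "age_mean", "age_sd", "sex_prop_male")) {
      sim[[nm]] <- as.list(sim[[nm]])
    }
    sim$trait_loadings <- lapply(sim$trait_loadings, as.list)
    sim$module_group_shift <- lapply(sim$module_group_shift, as.list)
    out$simulate <- sim
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: simulate (or load) inputs, QC
#' (LOD mask, protein filters, connectivity outlier removal, bootstrap
#' covariate adjustment), network construction, differential abundance,
#' optional gene-set enrichment, panel selection, trait association.
#' Outputs are returned and, when `out_dir` is set, written as TSV/JSON
#' alongside a run manifest (config echo, per-stage dimension
#' accounting, file checksums). A stage failure aborts with an error
#' naming the stage; outputs of completed stages are retained in the
#' error's `partial` field.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` and per-stage results (`qc`, `network`,
#'   `da`, `enrichment`, `panel`, `traits`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list()
  accounting <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "plasmanet_stage_error", partial = results)
    })
  }

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    cohort <- run_stage("simulate", generate_cohort(config$simulate))
    mat <- cohort$matrix; qc_tab <- cohort$qc
    meta <- cohort$metadata; traits <- cohort$traits
    results$cohort <- cohort
  } else {
    mat <- run_stage("inputs", read_protein_matrix(config$matrix_path))
    qc_tab <- run_stage("inputs", read_tsv_table(config$qc_path))
    meta <- run_stage("inputs", read_tsv_table(config$meta_path))
    traits <- if (!is.null(config$traits_path)) read_tsv_table(config$traits_path) else NULL
  }
  missing_meta <- setdiff(rownames(mat), meta$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("samples without metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  accounting$input <- dim(mat)

  # ---- qc ----
  if (config$stages$qc) {
    qc_res <- run_stage("qc", qc_pipeline(
      mat, qc_tab, meta, missing_threshold = config$missing_threshold,
      z_cutoff = config$z_cutoff, n_boot = config$n_boot, seed = config$seed
    ))
    mat <- qc_res$matrix
    results$qc <- qc_res
    accounting$post_qc <- dim(mat)
  }
  meta <- meta[match(rownames(mat), meta$sample_id), ]
  groups <- meta$group

  # ---- network ----
  if (config$stages$network) {
    params <- network_params(
      power = config$power, deep_split = config$deep_split,
      min_module_size = config$min_module_size,
      merge_cut_height = config$merge_cut_height
    )
    results$network <- run_stage("network", build_network(mat, params))
    accounting$modules <- nrow(glance(results$network)["n_modules"])
    accounting$n_modules <- glance(results$network)$n_modules
  }

  # ---- differential abundance ----
  if (config$stages$da) {
    results$da <- run_stage("da", anova_tukey(mat, groups))
  }

  # ---- enrichment ----
  if (isTRUE(config$stages$enrichment)) {
    if (is.null(config$gmt_path)) {
      warn("enrichment requested but no gmt_path; skipping")
    } else if (is.null(results$da)) {
      warn("enrichment skipped: differential abundance not run")
    } else {
      sets <- run_stage("enrichment", read_gmt(config$gmt_path))
      pair <- config$da_pair %||% utils::head(sort(unique(groups)), 2)
      hits <- results$da |>
        filter(.data$group_a %in% pair, .data$group_b %in% pair,
               .data$p_tukey < config$da_alpha)
      results$enrichment <- run_stage("enrichment", enrich_gene_sets(
        unique(hits$protein_id), sets, colnames(mat)
      ))
    }
  }

  # ---- panel ----
  if (config$stages$panel) {
    if (is.null(results$da)) {
      warn("panel skipped: differential abundance not run")
    } else {
      pair <- config$da_pair %||% utils::head(sort(unique(groups)), 2)
      da_pairwise <- results$da |>
        filter(.data$group_a %in% pair, .data$group_b %in% pair,
               .data$group_a != .data$group_b)
      candidates <- unique(da_pairwise$protein_id[
        !is.na(da_pairwise$p_tukey) & da_pairwise$p_tukey < config$da_alpha])
      in_pair <- groups %in% pair
      if (length(candidates) >= 2 && length(unique(groups[in_pair])) == 2) {
        results$panel <- run_stage("panel", rfecv_select(
          mat[in_pair, candidates, drop = FALSE],
          droplevels(factor(groups[in_pair])),
          k = config$k, seed = stage_seed(config$seed, "panel")
        ))
      } else {
        warn("panel skipped: fewer than 2 differentially abundant candidates")
      }
    }
  }

  # ---- traits ----
  if (config$stages$traits && !is.null(traits) && !is.null(results$network) &&
      !is.null(results$network$eigenproteins)) {
    results$traits <- run_stage("traits", module_trait_correlations(
      results$network$eigenproteins, traits, groups
    ))
  }

  manifest <- list(
    config = unclass(config), accounting = accounting,
    seed = config$seed, timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_protein_matrix(mat, file.path(config$out_dir, "matrix_adjusted.tsv"))
    if (!is.null(results$network)) {
      write_tsv_table(tidy(results$network),
                      file.path(config$out_dir, "module_assignment.tsv"))
      write_tsv_table(
        data.frame(sample_id = rownames(results$network$eigenproteins),
                   results$network$eigenproteins, check.names = FALSE),
        file.path(config$out_dir, "eigenproteins.tsv"))
    }
    if (!is.null(results$da)) {
      write_tsv_table(results$da, file.path(config$out_dir, "differential_abundance.tsv"))
    }
    if (!is.null(results$traits)) {
      write_tsv_table(results$traits, file.path(config$out_dir, "module_trait.tsv"))
    }
    if (!is.null(results$panel)) {
      jsonlite::write_json(
        list(selected = results$panel$selected,
             cv_accuracy = results$panel$cv_accuracy,
             panel_auc = results$panel$panel_auc,
             auc_ci = results$panel$auc_ci, tuned_c = results$panel$tuned_c),
        file.path(config$out_dir, "panel.json"), auto_unbox = TRUE, digits = NA)
    }
    files <- list.files(config$out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    manifest_out <- manifest
    manifest_out$config$simulate <- NULL
    jsonlite::write_json(manifest_out, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  results$manifest <- manifest
  results
}
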