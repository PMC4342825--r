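# Orchestration: wiring the simulation, quantification, stability, bias,
# variance and meta-analysis stages behind a single configurable entry
# point. Table formats are documented in inst/FORMATS.md.

#' Default pipeline configuration
#'
#' All stage parameters default to the conventional values of the
#' workflow: V cutoff 0.15, M threshold 1.5, gDNA screening threshold 1%,
#' RPKM floor 15, heat-map saturation 3.5 log2 units, 5 stability classes.
#'
#' @return nested named list of configuration defaults.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       out_dir = "refstab_out",
       stages = c("simulate", "qc", "stability", "bias", "anova", "meta"),
       inputs = list(cq_table = NULL, efficiencies = NULL, fc_matrix = NULL),
       sim = list(),
       fc_sim = list(),
       qc = list(gdna_threshold = 0.01, sd_warn = 0.5),
       genorm = list(v_cutoff = 0.15, m_threshold = 1.5, var_denom = "n-1"),
       bias = list(ref_genes = NULL, alt_sets = NULL),
       anova = list(control_condition = NULL),
       meta = list(k = 5L, saturation = 3.5, fc_tolerance = 0.25,
                   min_rpkm = 15))
}

merge_config <- function(user) {
  cfg <- default_run_config()
  if (is.null(user)) return(cfg)
  if (is.character(user) && length(user) == 1L) {
    user <- if (grepl("\\.json$", user)) jsonlite::read_json(user, simplifyVector = TRUE)
            else yaml::read_yaml(user)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]]) && key != "sim" &&
        key != "fc_sim" && key != "bias" && key != "inputs") {
      bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
      if (length(bad) > 0)
        stop(sprintf("unknown configuration key(s) under '%s': %s",
                     key, paste(bad, collapse = ", ")))
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the reference-gene stability pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic Cq and
#' fold-change data with planted truth), `qc` (replicate QC, gDNA
#' screening, Cq box statistics), `stability` (efficiency-corrected
#' quantities and geNorm analysis), `bias` (normalization-bias audit),
#' `anova` (three-level nested variance decomposition) and `meta`
#' (fold-change summaries, Ward stability classes, heat-map export) —
#' writing all artifacts plus a machine-readable run manifest into
#' `out_dir`. Stages consume the artifacts of earlier stages from
#' `out_dir`, so subsets of stages can be re-run. Identical configuration
#' and seed reproduce identical numerical outputs; timestamps live only
#' in the manifest.
#'
#' @param config `NULL` (defaults), a nested list, or the path to a
#'   YAML/JSON configuration file; unknown keys are rejected by name.
#' @param seed overrides `config$seed`.
#' @param out_dir overrides `config$out_dir`.
#' @param stages overrides `config$stages` (`"all"` selects every stage).
#' @return (invisibly) list with the written file paths and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL,
                         stages = NULL) {
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(stages)) cfg$stages <- stages
  if (identical(cfg$stages, "all")) cfg$stages <- default_run_config()$stages
  bad_stage <- setdiff(cfg$stages, default_run_config()$stages)
  if (length(bad_stage) > 0)
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  outputs <- character()
  res <- list()

  load_cq <- function() {
    if (!is.null(res$cq)) return(res$cq)
    path <- cfg$inputs$cq_table %||% p("cq_table.tsv")
    if (!file.exists(path)) stop("no Cq table available; run the 'simulate' stage or provide inputs$cq_table")
    read_cq_table(path)
  }
  load_eff <- function() {
    if (!is.null(res$efficiencies)) return(res$efficiencies)
    path <- cfg$inputs$efficiencies %||% p("efficiencies.tsv")
    if (!file.exists(path)) stop("no efficiency table available")
    read_efficiency_table(path)
  }
  load_fc <- function() {
    if (!is.null(res$fc)) return(res$fc)
    path <- cfg$inputs$fc_matrix %||% p("fc_matrix.tsv")
    if (!file.exists(path)) stop("no fold-change matrix available")
    read_matrix_tsv(path)
  }
  run_stability <- function() {
    if (!is.null(res$stability)) return(res)
    agg <- interrun_calibrate(load_cq())
    agg <- aggregate_technical_replicates(agg, sd_warn = cfg$qc$sd_warn)
    res$quantities <<- cq_to_quantity(agg, load_eff())
    res$stability <<- genorm(res$quantities,
                             v_cutoff = cfg$genorm$v_cutoff,
                             m_threshold = cfg$genorm$m_threshold,
                             var_denom = cfg$genorm$var_denom)
    res
  }

  for (stage in cfg$stages) {
    tryCatch(switch(stage,
      simulate = {
        stage_msg(stage, "generating synthetic Cq and fold-change data, seed ", cfg$seed)
        sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
        sim <- simulate_cq_dataset(sim_cfg)
        res$cq <- sim$cq
        res$truth <- sim$truth
        res$efficiencies <- efficiency_table(names(sim$truth$efficiencies),
                                             as.numeric(sim$truth$efficiencies))
        write_cq_table(sim$cq, p("cq_table.tsv"))
        utils::write.table(res$efficiencies, p("efficiencies.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_json_result(list(gene_labels = as.list(sim$truth$gene_labels),
                               run_offsets = as.list(sim$truth$run_offsets),
                               gdna_fraction = sim$truth$gdna_fraction,
                               efficiencies = as.list(sim$truth$efficiencies)),
                          p("truth.json"))
        fcsim <- do.call(simulate_fc_matrix,
                         c(cfg$fc_sim, list(seed = cfg$seed)))
        res$fc <- fcsim$fc
        res$fc_truth <- fcsim$truth
        write_matrix_tsv(fcsim$fc, p("fc_matrix.tsv"))
        write_json_result(list(class_labels = as.list(fcsim$truth$class_labels)),
                          p("fc_truth.json"))
        yaml::write_yaml(cfg[setdiff(names(cfg), "inputs")], p("config.yaml"))
        outputs <- c(outputs, "cq_table.tsv", "efficiencies.tsv", "truth.json",
                     "fc_matrix.tsv", "fc_truth.json", "config.yaml")
      },
      qc = {
        stage_msg(stage, "replicate QC, gDNA screening and Cq distributions")
        cq <- load_cq()
        agg <- aggregate_technical_replicates(cq, sd_warn = cfg$qc$sd_warn)
        utils::write.table(agg, p("cq_aggregated.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "NA")
        if ("VPA" %in% cq$assay_id) {
          res$contamination <- assess_gdna_contamination(
            cq, threshold = cfg$qc$gdna_threshold)
          utils::write.table(res$contamination, p("contamination.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             na = "NA")
          outputs <- c(outputs, "contamination.tsv")
        } else stage_msg(stage, "no VPA records; gDNA screening skipped")
        box <- summarize_cq_distribution(agg)
        res$cq_box <- box
        write_json_result(list(stats = box$stats, outliers = box$outliers),
                          p("cq_boxstats.json"))
        outputs <- c(outputs, "cq_aggregated.tsv", "cq_boxstats.json")
      },
      stability = {
        stage_msg(stage, "efficiency-corrected quantities and geNorm analysis")
        res <- run_stability()
        st <- res$stability
        write_matrix_tsv(res$quantities, p("quantity_matrix.tsv"))
        rank_df <- data.frame(rank_worst_first = seq_along(st$ranking),
                              gene = st$ranking,
                              m_at_exclusion = as.numeric(
                                st$m_at_exclusion[st$ranking]),
                              initial_M = as.numeric(st$initial_M[st$ranking]))
        utils::write.table(rank_df, p("ranking.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        v_df <- data.frame(comparison = names(st$v_series),
                           v = as.numeric(st$v_series))
        utils::write.table(v_df, p("v_series.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_json_result(list(initial_M = as.list(st$initial_M),
                               ranking = st$ranking,
                               best_pair = st$best_pair,
                               v_series = as.list(st$v_series),
                               optimal_n = st$optimal_n,
                               status = st$status,
                               flagged_genes = st$flagged_genes,
                               ties = st$ties,
                               cutoffs = list(v = st$v_cutoff,
                                              m = st$m_threshold)),
                          p("stability.json"))
        stage_msg(stage, sprintf("optimal number of reference genes: %d", st$optimal_n))
        outputs <- c(outputs, "quantity_matrix.tsv", "ranking.tsv",
                     "v_series.tsv", "stability.json")
      },
      bias = {
        stage_msg(stage, "normalization-bias audit")
        res <- run_stability()
        st <- res$stability
        ref <- cfg$bias$ref_genes %||% st$best_first[1:3]
        alts <- cfg$bias$alt_sets
        if (is.null(alts)) {
          worst <- st$ranking[1:3]
          alts <- list(worst_three = worst, worst_single = st$ranking[1])
        }
        conds <- stats::setNames(res$quantities$sample_info$condition_id,
                                 res$quantities$sample_info$sample_id)
        res$bias <- bias_report(res$quantities, ref, alts, conds)
        rows <- do.call(rbind, lapply(names(res$bias), function(nm) {
          b <- res$bias[[nm]]
          data.frame(alt_set = nm, condition_id = names(b$bias),
                     log2_bias = as.numeric(b$bias),
                     zone = as.character(b$zones), stringsAsFactors = FALSE)
        }))
        utils::write.table(rows, p("bias.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        write_json_result(list(
          reference_set = ref,
          sign_convention = attr(res$bias[[1]]$bias, "sign_convention"),
          sets = lapply(res$bias, function(b) list(
            zone_counts = as.list(b$zone_counts),
            fraction_below_1.5fold = b$profile$fraction_below_1.5fold,
            fraction_above_3fold = b$profile$fraction_above_3fold))),
          p("bias.json"))
        outputs <- c(outputs, "bias.tsv", "bias.json")
      },
      anova = {
        stage_msg(stage, "three-level nested variance decomposition")
        res <- run_stability()
        ctrl <- cfg$anova$control_condition %||%
          res$quantities$sample_info$condition_id[1]
        rel <- relative_expression_table(res$quantities, ctrl)
        res$anova <- nested_variance_components(rel)
        write_json_result(list(control_condition = ctrl,
                               status = res$anova$status,
                               table = res$anova$table),
                          p("anova.json"))
        outputs <- c(outputs, "anova.json")
      },
      meta = {
        stage_msg(stage, "cross-dataset fold-change meta-analysis")
        fc <- load_fc()
        res$fc <- fc
        summ <- gene_fc_summary(fc)
        res$meta_summary <- summ
        utils::write.table(summ, p("gene_summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "NA")
        res$classification <- classify_genes(summ, k = cfg$meta$k)
        write_json_result(list(classes = as.list(res$classification$classes),
                               centroids = res$classification$centroids,
                               k = cfg$meta$k,
                               degenerate = res$classification$degenerate),
                          p("classification.json"))
        hm <- heatmap_matrix(fc, saturation = cfg$meta$saturation)
        write_matrix_tsv(hm$matrix, p("heatmap.tsv"))
        write_json_result(hm$scale, p("heatmap_scale.json"))
        outputs <- c(outputs, "gene_summary.tsv", "classification.json",
                     "heatmap.tsv", "heatmap_scale.json")
      }),
      error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      })
  }

  manifest <- list(package = "refstab",
                   version = as.character(utils::packageVersion("refstab")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = cfg$seed,
                   stages = cfg$stages,
                   parameters = cfg[c("qc", "genorm", "anova", "meta")],
                   outputs = unique(outputs))
  write_json_result(manifest, p("manifest.json"))
  stage_msg("done", "artifacts written to ", normalizePath(cfg$out_dir))
  invisible(list(paths = file.path(cfg$out_dir, unique(outputs)),
                 results = res, config = cfg))
}
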