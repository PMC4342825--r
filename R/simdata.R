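#' Simulation configuration for synthetic Cq datasets
#'
#' Builds and validates the configuration for [simulate_cq_dataset()]. The
#' defaults emulate the design of a typical reference-gene validation study
#' in a filamentous fungus: a panel of candidate genes measured over 33
#' culture conditions in biological duplicate and technical triplicate,
#' with 8 genuinely stable genes (condition-to-condition dispersion 0.15
#' log2 units) and 4 regulated genes planted with sporadic 2 log2-unit
#' effects in a few randomly chosen conditions.
#'
#' @param n_stable_genes number of planted stable genes (>= 1).
#' @param n_regulated_genes number of planted regulated genes (>= 0);
#'   the total panel must contain at least 3 genes for stability ranking.
#' @param n_conditions number of culture conditions (>= 1).
#' @param n_bio_replicates biological replicates per condition (>= 1).
#' @param n_tech_replicates technical qPCR replicates per reaction (>= 1).
#' @param base_cq_range interval (cycles) from which each gene's calibration
#'   Cq (the Cq at unit relative quantity) is drawn uniformly.
#' @param stable_sd_log2 condition-level biological dispersion of the true
#'   log2 quantity, applied to every gene (log2 units, >= 0).
#' @param condition_effect_log2 magnitude of the planted regulation effect
#'   for regulated genes (log2 units).
#' @param n_affected_conditions number of randomly chosen conditions in
#'   which each regulated gene is up- or down-regulated.
#' @param bio_sd_log2 biological-replicate dispersion (log2 units, >= 0).
#' @param tech_sd_cycles technical replicate noise on the Cq scale (>= 0).
#' @param run_shift_sd_cycles scale of the per-run (plate) Cq offset (>= 0).
#' @param n_runs number of qPCR runs; conditions are assigned to runs
#'   round-robin.
#' @param gdna_fraction planted genomic-DNA contamination fraction per
#'   sample (0 disables the ValidPrime records; must be in `[0, 1)`).
#' @param gdna_control_cq Cq of the genomic-DNA control sample (cycles).
#' @param efficiencies per-gene amplification efficiency as a fraction
#'   (1.0 = 100%); `NULL` draws one per gene uniformly from `[0.90, 1.05]`.
#' @param seed integer seed; identical configurations (including the seed)
#'   reproduce byte-identical datasets.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cq_dataset()]
#' @export
sim_config <- function(n_stable_genes = 8L, n_regulated_genes = 4L,
                       n_conditions = 33L, n_bio_replicates = 2L,
                       n_tech_replicates = 3L, base_cq_range = c(20, 30),
                       stable_sd_log2 = 0.15, condition_effect_log2 = 2,
                       n_affected_conditions = 3L, bio_sd_log2 = 0.10,
                       tech_sd_cycles = 0.10, run_shift_sd_cycles = 0.5,
                       n_runs = 4L, gdna_fraction = 0.001,
                       gdna_control_cq = 26, efficiencies = NULL,
                       seed = 1L) {
  cfg <- list(n_stable_genes = as.integer(n_stable_genes),
              n_regulated_genes = as.integer(n_regulated_genes),
              n_conditions = as.integer(n_conditions),
              n_bio_replicates = as.integer(n_bio_replicates),
              n_tech_replicates = as.integer(n_tech_replicates),
              base_cq_range = as.numeric(base_cq_range),
              stable_sd_log2 = stable_sd_log2,
              condition_effect_log2 = condition_effect_log2,
              n_affected_conditions = as.integer(n_affected_conditions),
              bio_sd_log2 = bio_sd_log2,
              tech_sd_cycles = tech_sd_cycles,
              run_shift_sd_cycles = run_shift_sd_cycles,
              n_runs = as.integer(n_runs),
              gdna_fraction = gdna_fraction,
              gdna_control_cq = gdna_control_cq,
              efficiencies = efficiencies,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation config field '%s': %s", field, why),
         call. = FALSE)
  }
  count1 <- c("n_stable_genes", "n_conditions", "n_bio_replicates",
              "n_tech_replicates", "n_runs")
  for (f in count1) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      bad(f, "must be a count >= 1")
  }
  if (length(cfg$n_regulated_genes) != 1L || is.na(cfg$n_regulated_genes) ||
      cfg$n_regulated_genes < 0L)
    bad("n_regulated_genes", "must be a count >= 0")
  if (cfg$n_stable_genes + cfg$n_regulated_genes < 3L)
    bad("n_stable_genes", "stability ranking needs at least 3 genes in total")
  if (length(cfg$base_cq_range) != 2L || diff(cfg$base_cq_range) < 0 ||
      any(cfg$base_cq_range <= 0))
    bad("base_cq_range", "must be a non-decreasing positive interval")
  for (f in c("stable_sd_log2", "bio_sd_log2", "tech_sd_cycles",
              "run_shift_sd_cycles")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0)
      bad(f, "dispersion parameters must be >= 0")
  }
  if (cfg$n_affected_conditions < 1L)
    bad("n_affected_conditions", "must be a count >= 1")
  if (is.na(cfg$gdna_fraction) || cfg$gdna_fraction < 0 || cfg$gdna_fraction >= 1)
    bad("gdna_fraction", "must lie in [0, 1)")
  if (!is.null(cfg$efficiencies)) {
    n_genes <- cfg$n_stable_genes + cfg$n_regulated_genes
    if (!length(cfg$efficiencies) %in% c(1L, n_genes))
      bad("efficiencies", "must have length 1 or one value per gene")
    if (any(cfg$efficiencies <= 0)) bad("efficiencies", "must be > 0")
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

#' Simulate a long-format Cq dataset with planted ground truth
#'
#' Generates raw quantification-cycle records for a reference-gene
#' validation experiment. The generative model, per gene g, condition c,
#' biological replicate b and technical replicate t, is
#' \deqn{x_{gcb} = \delta_{gc} + N(0, \sigma_{cond}) + N(0, \sigma_{bio})}
#' for the true log2 relative quantity (gene baseline 0, planted regulation
#' effect \eqn{\delta_{gc}}), and
#' \deqn{Cq_{gcbt} = Cq^0_g - x_{gcb} / \log_2(1 + E_g) + r_{run(c)} + N(0, \sigma_{tech})}
#' on the cycle scale, where \eqn{Cq^0_g} is the gene's calibration Cq,
#' \eqn{E_g} its amplification efficiency and \eqn{r} the per-run offset.
#'
#' Besides the unknown samples the table carries, per run and assay, an
#' inter-run calibrator sample (a common cDNA mix), one no-template control
#' (`Cq = NA`), a genomic-DNA control, and ValidPrime (VPA) records that
#' plant the configured gDNA contamination fraction.
#'
#' A single pseudo-random stream is consumed in a fixed, documented order
#' (efficiencies, calibration Cqs, regulated-gene targets and signs,
#' condition-level noise, replicate-level noise, run offsets, technical
#' noise of unknown samples, technical noise of calibrators, technical
#' noise of VPA records), so a given config + seed always reproduces the
#' same table.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `cq` (long-format `data.frame` with columns
#'   `sample_id`, `condition_id`, `bio_replicate`, `run_id`, `assay_id`,
#'   `tech_rep`, `cq`, `sample_kind`) and `truth` (planted parameters:
#'   per-gene labels, effect matrix, true log2 quantities, run offsets,
#'   efficiencies, calibration Cqs, gDNA fraction).
#' @examples
#' sim <- simulate_cq_dataset(sim_config(n_conditions = 4, seed = 7))
#' head(sim$cq)
#' @export
simulate_cq_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_stable_genes + config$n_regulated_genes
  nc <- config$n_conditions
  nb <- config$n_bio_replicates
  nt <- config$n_tech_replicates
  genes <- sprintf("gene%02d", seq_len(ng))
  labels <- rep(c("stable", "regulated"),
                c(config$n_stable_genes, config$n_regulated_genes))
  names(labels) <- genes
  conditions <- sprintf("cond%02d", seq_len(nc))

  # RNG draw order is part of the contract (see @details).
  eff <- config$efficiencies
  if (is.null(eff)) eff <- stats::runif(ng, 0.90, 1.05)
  eff <- rep_len(eff, ng)
  names(eff) <- genes
  base_cq <- stats::runif(ng, config$base_cq_range[1], config$base_cq_range[2])
  names(base_cq) <- genes

  effects <- matrix(0, ng, nc, dimnames = list(genes, conditions))
  if (config$n_regulated_genes > 0L) {
    k <- min(config$n_affected_conditions, nc)
    for (g in which(labels == "regulated")) {
      hit <- sample.int(nc, k)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      effects[g, hit] <- sgn * config$condition_effect_log2
    }
  }
  cond_noise <- matrix(stats::rnorm(ng * nc, 0, config$stable_sd_log2), ng, nc)
  bio_noise <- array(stats::rnorm(ng * nc * nb, 0, config$bio_sd_log2),
                     dim = c(ng, nc, nb))
  true_log2q <- array(0, dim = c(ng, nc, nb),
                      dimnames = list(genes, conditions, NULL))
  for (b in seq_len(nb))
    true_log2q[, , b] <- effects + cond_noise + bio_noise[, , b]

  run_of_cond <- ((seq_len(nc) - 1L) %% config$n_runs) + 1L
  runs <- sprintf("run%02d", seq_len(config$n_runs))
  run_offsets <- stats::rnorm(config$n_runs, 0, config$run_shift_sd_cycles)
  names(run_offsets) <- runs

  grid <- expand.grid(gene = seq_len(ng), cond = seq_len(nc),
                      bio = seq_len(nb), tech = seq_len(nt),
                      KEEP.OUT.ATTRS = FALSE)
  tq <- true_log2q[cbind(grid$gene, grid$cond, grid$bio)]
  cq <- base_cq[grid$gene] - tq / log2(1 + eff[grid$gene]) +
    run_offsets[run_of_cond[grid$cond]] +
    stats::rnorm(nrow(grid), 0, config$tech_sd_cycles)
  unknown <- data.frame(
    sample_id = sprintf("%s_b%d", conditions[grid$cond], grid$bio),
    condition_id = conditions[grid$cond],
    bio_replicate = grid$bio,
    run_id = runs[run_of_cond[grid$cond]],
    assay_id = genes[grid$gene],
    tech_rep = grid$tech,
    cq = as.numeric(cq),
    sample_kind = "unknown",
    stringsAsFactors = FALSE)

  cal_grid <- expand.grid(gene = seq_len(ng), run = seq_len(config$n_runs),
                          tech = seq_len(nt), KEEP.OUT.ATTRS = FALSE)
  cal_cq <- base_cq[cal_grid$gene] + run_offsets[cal_grid$run] +
    stats::rnorm(nrow(cal_grid), 0, config$tech_sd_cycles)
  calibrators <- data.frame(
    sample_id = "IRC",
    condition_id = "IRC",
    bio_replicate = 1L,
    run_id = runs[cal_grid$run],
    assay_id = genes[cal_grid$gene],
    tech_rep = cal_grid$tech,
    cq = as.numeric(cal_cq),
    sample_kind = "interrun_calibrator",
    stringsAsFactors = FALSE)

  ntc <- data.frame(sample_id = "NTC", condition_id = "NTC",
                    bio_replicate = 1L, run_id = runs[1], assay_id = genes,
                    tech_rep = 1L, cq = NA_real_, sample_kind = "NTC",
                    stringsAsFactors = FALSE)

  gdna_assays <- c(genes, "VPA")
  gdna <- data.frame(sample_id = "gDNA", condition_id = "gDNA",
                     bio_replicate = 1L, run_id = runs[1],
                     assay_id = gdna_assays, tech_rep = 1L,
                     cq = config$gdna_control_cq, sample_kind = "gDNA_control",
                     stringsAsFactors = FALSE)

  vpa <- NULL
  cal_vpa <- NULL
  if (config$gdna_fraction > 0) {
    vpa_cq0 <- mean(base_cq) - log2(config$gdna_fraction)
    vgrid <- expand.grid(cond = seq_len(nc), bio = seq_len(nb),
                         tech = seq_len(nt), KEEP.OUT.ATTRS = FALSE)
    vcq <- vpa_cq0 + run_offsets[run_of_cond[vgrid$cond]] +
      stats::rnorm(nrow(vgrid), 0, config$tech_sd_cycles)
    vpa <- data.frame(
      sample_id = sprintf("%s_b%d", conditions[vgrid$cond], vgrid$bio),
      condition_id = conditions[vgrid$cond],
      bio_replicate = vgrid$bio,
      run_id = runs[run_of_cond[vgrid$cond]],
      assay_id = "VPA",
      tech_rep = vgrid$tech,
      cq = as.numeric(vcq),
      sample_kind = "unknown",
      stringsAsFactors = FALSE)
    cvgrid <- expand.grid(run = seq_len(config$n_runs), tech = seq_len(nt),
                          KEEP.OUT.ATTRS = FALSE)
    cal_vpa <- data.frame(
      sample_id = "IRC", condition_id = "IRC", bio_replicate = 1L,
      run_id = runs[cvgrid$run], assay_id = "VPA", tech_rep = cvgrid$tech,
      cq = vpa_cq0 + run_offsets[cvgrid$run] +
        stats::rnorm(nrow(cvgrid), 0, config$tech_sd_cycles),
      sample_kind = "interrun_calibrator", stringsAsFactors = FALSE)
  }

  cq_table <- rbind(unknown, calibrators, cal_vpa, vpa, ntc, gdna)
  rownames(cq_table) <- NULL

  truth <- list(
    gene_labels = labels,
    effects = effects,
    true_log2q = true_log2q,
    run_offsets = run_offsets,
    run_of_condition = stats::setNames(runs[run_of_cond], conditions),
    efficiencies = eff,
    calibration_cq = base_cq,
    gdna_fraction = config$gdna_fraction,
    variance_components = c(condition = config$stable_sd_log2^2,
                            replicate = config$bio_sd_log2^2),
    config = config)
  structure(list(cq = cq_table, truth = truth), class = "sim_cq_dataset")
}

#' Simulate a standard-curve dilution series
#'
#' Cq values along a serial dilution of a cDNA mix: each `step`-fold
#' dilution increases Cq by `log2(step)/log2(1 + efficiency)` cycles, plus
#' optional technical noise.
#'
#' @param efficiency amplification efficiency as a fraction (> 0).
#' @param n_points number of dilution points (>= 3 for a meaningful fit).
#' @param step fold-dilution between consecutive points (> 1).
#' @param noise_sd technical noise on the Cq scale.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param base_cq Cq of the undiluted point before noise.
#' @param assay_id assay label carried in the output.
#' @return `data.frame` with columns `assay_id`, `point`, `concentration`
#'   (relative, undiluted = 1) and `cq`.
#' @examples
#' ds <- simulate_dilution_series(1.0, n_points = 5, step = 10)
#' diff(ds$cq)  # ~3.32 cycles per 10-fold dilution at 100% efficiency
#' @export
simulate_dilution_series <- function(efficiency, n_points = 6L, step = 10,
                                     noise_sd = 0, seed = 1L, base_cq = 20,
                                     assay_id = "assay") {
  if (efficiency <= 0) stop("invalid 'efficiency': must be > 0")
  if (n_points < 3L) stop("invalid 'n_points': need at least 3 dilution points")
  if (step <= 1) stop("invalid 'step': fold-dilution must exceed 1")
  if (noise_sd < 0) stop("invalid 'noise_sd': must be >= 0")
  conc <- step^(-(seq_len(n_points) - 1L))
  cq <- base_cq - log2(conc) / log2(1 + efficiency)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    cq <- cq + stats::rnorm(n_points, 0, noise_sd)
  }
  data.frame(assay_id = assay_id, point = seq_len(n_points),
             concentration = conc, cq = cq, stringsAsFactors = FALSE)
}

#' Default stability-class parameters for fold-change simulation
#'
#' Five classes shaped like those seen when clustering candidate reference
#' genes across many RNA-seq datasets: a tight unregulated class, a
#' moderately variable class, a highly variable class, and classes biased
#' towards down- and up-regulation.
#'
#' @return `data.frame` with columns `class`, `median` and `iqr` (log2
#'   fold-change units).
#' @export
default_fc_classes <- function() {
  data.frame(class = 1:5,
             median = c(0, 0.2, 0, -0.8, 0.9),
             iqr = c(0.45, 1.2, 3.0, 1.5, 1.8))
}

#' Simulate a cross-dataset log2 fold-change matrix with planted classes
#'
#' Each gene belongs to a stability class with a target (median, IQR)
#' location; its per-condition log2 fold-changes are drawn from a normal
#' distribution whose median and IQR are jittered around the class centre
#' by `blob_sd`. Missing cells ("data not available") are inserted at the
#' requested rate.
#'
#' @param n_genes_per_class integer vector, genes per class (>= 2 classes).
#' @param class_params `data.frame` with columns `median` and `iqr`, one
#'   row per class (see [default_fc_classes()]).
#' @param n_conditions number of dataset conditions (rows).
#' @param missing_fraction fraction of cells set to `NA`, in `[0, 1)`.
#' @param blob_sd within-class scatter of the per-gene (median, IQR) target.
#' @param seed integer seed.
#' @return list with `fc` (conditions x genes matrix of log2 FC) and
#'   `truth` (per-gene class label and generative median/IQR).
#' @export
simulate_fc_matrix <- function(n_genes_per_class = c(6L, 6L, 6L, 5L, 5L),
                               class_params = default_fc_classes(),
                               n_conditions = 92L, missing_fraction = 0,
                               blob_sd = 0.1, seed = 1L) {
  if (length(n_genes_per_class) < 2L)
    stop("invalid 'n_genes_per_class': need at least 2 classes")
  if (length(n_genes_per_class) != nrow(class_params))
    stop("'n_genes_per_class' and 'class_params' must describe the same classes")
  if (is.na(missing_fraction) || missing_fraction < 0 || missing_fraction >= 1)
    stop("invalid 'missing_fraction': must lie in [0, 1)")
  set.seed(as.integer(seed))
  n_genes <- sum(n_genes_per_class)
  class_of <- rep(seq_along(n_genes_per_class), n_genes_per_class)
  genes <- sprintf("gene%02d", seq_len(n_genes))
  gene_median <- stats::rnorm(n_genes, class_params$median[class_of], blob_sd)
  gene_iqr <- pmax(stats::rnorm(n_genes, class_params$iqr[class_of], blob_sd),
                   0.02)
  gene_sigma <- gene_iqr / (2 * stats::qnorm(0.75))
  fc <- matrix(stats::rnorm(n_conditions * n_genes), n_conditions, n_genes)
  fc <- sweep(fc, 2L, gene_sigma, `*`)
  fc <- sweep(fc, 2L, gene_median, `+`)
  dimnames(fc) <- list(sprintf("condition%03d", seq_len(n_conditions)), genes)
  if (missing_fraction > 0) {
    n_missing <- round(missing_fraction * length(fc))
    fc[sample.int(length(fc), n_missing)] <- NA_real_
  }
  truth <- list(class_labels = stats::setNames(class_of, genes),
                gene_median = stats::setNames(gene_median, genes),
                gene_iqr = stats::setNames(gene_iqr, genes))
  list(fc = fc, truth = truth)
}

#' Simulate a balanced fully nested three-level dataset
#'
#' Draws log2 relative-expression values from the three-level nested
#' random-effects model used by [nested_variance_components()]:
#' gene effect + condition-within-gene effect + replicate error, each a
#' zero-mean normal with its own standard deviation.
#'
#' @param n_genes,n_conditions,n_replicates balanced design dimensions.
#' @param sd_gene,sd_condition,sd_replicate standard deviations of the
#'   three variance components (log2 units).
#' @param seed integer seed.
#' @return long `data.frame` with columns `gene`, `condition`, `replicate`,
#'   `log2_value`.
#' @export
simulate_nested_dataset <- function(n_genes = 6L, n_conditions = 8L,
                                    n_replicates = 2L, sd_gene = 0,
                                    sd_condition = 1, sd_replicate = 1,
                                    seed = 1L) {
  stopifnot(n_genes >= 2L, n_conditions >= 2L, n_replicates >= 2L,
            sd_gene >= 0, sd_condition >= 0, sd_replicate >= 0)
  set.seed(as.integer(seed))
  g_eff <- stats::rnorm(n_genes, 0, sd_gene)
  c_eff <- matrix(stats::rnorm(n_genes * n_conditions, 0, sd_condition),
                  n_genes, n_conditions)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      condition = seq_len(n_conditions),
                      gene = seq_len(n_genes), KEEP.OUT.ATTRS = FALSE)
  y <- g_eff[grid$gene] + c_eff[cbind(grid$gene, grid$condition)] +
    stats::rnorm(nrow(grid), 0, sd_replicate)
  data.frame(gene = sprintf("gene%02d", grid$gene),
             condition = sprintf("cond%02d", grid$condition),
             replicate = grid$replicate,
             log2_value = as.numeric(y),
             stringsAsFactors = FALSE)
}
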