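#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the full analysis: which architectures to scan,
#' replication levels, demographic constants, the cross and inbreeding
#' settings, and optional custom coefficient files.  Defaults reproduce the
#' study design (100-scenario grids for four autosomal architectures and the
#' X-linked single-locus case, 50 scan repeats, 50 cross replicates, 250
#' inbred lines subsampled to 64, 10,000 Monte Carlo dip draws).  A YAML file
#' with any subset of these fields can be supplied instead of arguments.
#'
#' @param n_loci Autosomal architectures to scan.
#' @param include_x_linked Also scan the X-linked single-locus grid.
#' @param n_repeats Scan repeats (high/low pairs) per scenario.
#' @param cross_replicates Simulated line pairs in the cross experiment.
#' @param cross_scenario Named list \code{d}, \code{h}, \code{A}: the
#'   scenario used for crosses (the best-fitting one).
#' @param inbreeding_lines Inbred lines per architecture.
#' @param inbreeding_A Named vector: founding allele frequency used for the
#'   inbreeding runs of each architecture.
#' @param subsample_to Inbred-line subsample size matching the experimental
#'   count.
#' @param n_mc Monte Carlo draws per dip test.
#' @param fit_threshold R-squared threshold defining a good scenario fit.
#' @param cohort_size,n_par,n_generations,assay_k,baseline Demographic and
#'   genetic constants.
#' @param seed Master seed; every stage derives substreams from it.
#' @param selection_coefficients,cross_coefficients Optional paths to custom
#'   coefficient files.
#' @param file Optional YAML file whose fields override the defaults (command
#'   line style overrides can then be applied on top via \code{...} in
#'   [run_pipeline()]).
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n_loci = c(1L, 3L, 5L, 10L),
                            include_x_linked = TRUE,
                            n_repeats = 50L,
                            cross_replicates = 50L,
                            cross_scenario = list(d = 0.5, h = 0.6, A = 0.8),
                            inbreeding_lines = 250L,
                            inbreeding_A = c(`1` = 0.8, `3` = 0.4, `5` = 0.4,
                                             `10` = 0.4),
                            subsample_to = 64L,
                            n_mc = 10000L,
                            fit_threshold = 0.80,
                            cohort_size = 200L, n_par = 30L,
                            n_generations = 4L, assay_k = 3L, baseline = 0.5,
                            seed = 1L,
                            selection_coefficients = NULL,
                            cross_coefficients = NULL,
                            file = NULL) {
  cfg <- list(n_loci = as.integer(n_loci),
              include_x_linked = include_x_linked,
              n_repeats = as.integer(n_repeats),
              cross_replicates = as.integer(cross_replicates),
              cross_scenario = cross_scenario,
              inbreeding_lines = as.integer(inbreeding_lines),
              inbreeding_A = inbreeding_A,
              subsample_to = as.integer(subsample_to),
              n_mc = as.integer(n_mc),
              fit_threshold = fit_threshold,
              cohort_size = as.integer(cohort_size),
              n_par = as.integer(n_par),
              n_generations = as.integer(n_generations),
              assay_k = as.integer(assay_k),
              baseline = baseline,
              seed = as.integer(seed),
              selection_coefficients = selection_coefficients,
              cross_coefficients = cross_coefficients)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("configuration file not found: ", file)
    over <- yaml::read_yaml(file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  counts <- c("n_repeats", "cross_replicates", "inbreeding_lines", "n_mc",
              "cohort_size", "n_par", "n_generations", "assay_k")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_table <- function(tab, path, seed, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dispersim %s table (master seed %d)", stage, seed),
             con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains every stage of the analysis: parameter scan of simulated selection,
#' scoring against the experimental selection-response model (fit surface),
#' the simulated reciprocal-cross experiment under autosomal and X-linked
#' architectures with its fixed-effect models and transfer R-squared,
#' inbreeding simulations per architecture with dip tests of the terminal
#' disperser distributions (full and subsampled), and a manifest recording
#' the configuration.  Tidy tab-separated tables are written per stage; a
#' rerun with the same configuration and seed reproduces them byte for byte.
#'
#' For each architecture, the inbreeding stage uses the scan's best-fitting
#' dominance and heritability at that architecture's configured founding
#' frequency.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for output tables (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with all stage results (\code{scan},
#'   \code{scores}, \code{crosses}, \code{cross_models}, \code{inbreeding},
#'   \code{dip_tests}, \code{manifest}).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = "dispersim-run",
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sel_model <- stage("configuration",
    reference_model("selection", file = config$selection_coefficients))
  cross_model <- stage("configuration",
    reference_model("crosses", file = config$cross_coefficients))

  # --- scan ---------------------------------------------------------------
  say("stage scan: %d autosomal + %s X-linked scenarios",
      100L * length(config$n_loci),
      if (config$include_x_linked) "100" else "no")
  scan <- stage("scan", {
    grid <- build_parameter_grid(config$n_loci)
    if (config$include_x_linked)
      grid <- rbind(grid, build_parameter_grid(1L, sex_linked = TRUE))
    run_parameter_scan(grid, n_repeats = config$n_repeats,
                       seed = derive_seed(seed, 1L),
                       baseline = config$baseline,
                       n_generations = config$n_generations,
                       cohort_size = config$cohort_size,
                       n_par = config$n_par, assay_k = config$assay_k)
  })
  write_stage_table(scan, file.path(output_dir, "scan.tsv"), seed, "scan")

  # --- score --------------------------------------------------------------
  say("stage score: fitting experimental model to %d scenarios",
      length(unique(scan$scenario)))
  scores <- stage("score", score_scan(scan, sel_model))
  write_stage_table(scores, file.path(output_dir, "fit_surface.tsv"), seed,
                    "fit surface")

  # --- crosses ------------------------------------------------------------
  say("stage crosses: %d replicates per architecture",
      config$cross_replicates)
  cs <- config$cross_scenario
  crosses <- stage("crosses", {
    out <- list()
    for (sl in c(FALSE, TRUE)) {
      tab <- run_cross_experiment(
        n_replicates = config$cross_replicates, sex_linked = sl,
        d = cs$d, h = cs$h, A = cs$A, baseline = config$baseline,
        seed = derive_seed(seed, 2L, as.integer(sl)),
        n_generations = config$n_generations,
        cohort_size = config$cohort_size, n_par = config$n_par)
      out[[if (sl) "sex_linked" else "autosomal"]] <- tab
    }
    out
  })
  cross_models <- stage("crosses", {
    rows <- list()
    for (nm in names(crosses)) {
      for (kind in c("main_effects", "interaction")) {
        fit <- fit_cross_model(crosses[[nm]], kind)
        rows[[paste(nm, kind)]] <- data.frame(architecture = nm, model = kind,
                                              fit$coefficients)
      }
      rows[[paste(nm, "transfer")]] <- data.frame(
        architecture = nm, model = "transfer_r_squared",
        term = "r_squared",
        estimate = cross_transfer_r_squared(crosses[[nm]], cross_model),
        se = NA_real_, t = NA_real_, p = NA_real_)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  write_stage_table(do.call(rbind, c(crosses, make.row.names = FALSE)),
                    file.path(output_dir, "crosses.tsv"), seed, "crosses")
  write_stage_table(cross_models, file.path(output_dir, "cross_models.tsv"),
                    seed, "cross models")

  # --- inbreeding ---------------------------------------------------------
  say("stage inbreed: %d lines per architecture", config$inbreeding_lines)
  inbreeding <- stage("inbreed", {
    archs <- lapply(config$n_loci, function(L) {
      A <- config$inbreeding_A[[as.character(L)]]
      auto <- scores[!scores$sex_linked & scores$n_loci == L &
                       scores$A == A, ]
      best <- auto[which.max(auto$r_squared), ]
      genetic_architecture(L, FALSE, d = best$d, h = best$h, A = A,
                           baseline = config$baseline)
    })
    run_inbreeding_experiment(archs, n_lines = config$inbreeding_lines,
                              seed = derive_seed(seed, 3L))
  })
  write_stage_table(inbreeding, file.path(output_dir, "inbreeding.tsv"),
                    seed, "inbreeding")

  # --- dip tests ----------------------------------------------------------
  say("stage dip: %d Monte Carlo draws per test", config$n_mc)
  dips <- stage("dip", {
    rows <- list()
    sub <- subsample_lines(inbreeding, m = config$subsample_to,
                           seed = derive_seed(seed, 4L))
    for (L in config$n_loci) {
      for (scope in c("all", "subsampled")) {
        dat <- if (scope == "all") inbreeding else sub
        sel <- dat$n_loci == L
        set.seed(derive_seed(seed, 5L, L, as.integer(scope == "all")))
        for (what in c("terminal_dispersers", "mean_allele_freq")) {
          dt <- dip_test(dat[[what]][sel], n_mc = config$n_mc)
          rows[[paste(L, scope, what)]] <- data.frame(
            n_loci = L, scope = scope, variable = what, n = dt$n,
            D = dt$statistic, p_value = dt$p_value)
        }
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  write_stage_table(dips, file.path(output_dir, "dip_tests.tsv"), seed,
                    "dip tests")

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "dispersim",
    version = as.character(utils::packageVersion("dispersim")),
    seed = seed,
    config = unclass(config),
    tables = c("scan.tsv", "fit_surface.tsv", "crosses.tsv",
               "cross_models.tsv", "inbreeding.tsv", "dip_tests.tsv"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: outputs in %s", normalizePath(output_dir))
  invisible(list(scan = scan, scores = scores, crosses = crosses,
                 cross_models = cross_models, inbreeding = inbreeding,
                 dip_tests = dips, manifest = manifest))
}
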