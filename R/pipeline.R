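#' Build a pipeline run configuration
#'
#' Collects the paths and parameters of a full analysis run. Two built-in
#' tissue profiles set the factor handling: `"semen"` pins age and the
#' sperm fraction during collinearity pruning, `"buccal"` pins age and the
#' epithelial fraction; any factor list can be supplied explicitly.
#'
#' @param cgmap_dir directory of per-sample `<sample_id>.cgmap` files.
#' @param phenotypes path to the phenotype TSV (`sample_id`, `age`,
#'   `batch`, ...).
#' @param reference path to the reference methylome TSV.
#' @param profile `"semen"` or `"buccal"`.
#' @param panel optional panel BED path (`NULL`: all observed sites).
#' @param factors optional explicit factor list (`NULL`: age + all
#'   reference cell types).
#' @param pinned factors protected from pruning (`NULL`: profile default).
#' @param min_coverage,k,prune_threshold,r_min,q_max,cap,normalize module
#'   parameters, see [aggregate_matrix()], [knn_impute()],
#'   [build_factor_matrix()], [select_sites()], [deconvolve_all()].
#' @param seed integer seed recorded in the run log (the analysis itself
#'   is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(cgmap_dir, phenotypes, reference,
                       profile = c("semen", "buccal"), panel = NULL,
                       factors = NULL, pinned = NULL,
                       min_coverage = 40, k = 5, prune_threshold = 0.7,
                       r_min = 0.5, q_max = 0.05, cap = 200,
                       normalize = TRUE, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(pinned)) {
    pinned <- switch(profile,
                     semen = c("age", "sperm"),
                     buccal = c("age", "epithelial"))
  }
  cfg <- list(cgmap_dir = cgmap_dir, phenotypes = phenotypes,
              reference = reference, profile = profile, panel = panel,
              factors = factors, pinned = pinned,
              min_coverage = min_coverage, k = k,
              prune_threshold = prune_threshold, r_min = r_min,
              q_max = q_max, cap = cap, normalize = normalize,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

validate_run_config <- function(config) {
  for (f in c("cgmap_dir", "phenotypes", "reference")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop_config(paste0("config path '", f, "' does not exist: ",
                         config[[f]]))
    }
  }
  if (!is.null(config$panel) && !file.exists(config$panel)) {
    stop_config(paste0("panel BED not found: ", config$panel))
  }
  with(config, {
    if (min_coverage < 1 || k < 1 || cap < 1) {
      stop_config("min_coverage, k and cap must be >= 1")
    }
    if (prune_threshold <= 0 || prune_threshold > 1 ||
        r_min < 0 || r_min > 1 || q_max <= 0 || q_max > 1) {
      stop_config("prune_threshold, r_min and q_max must lie in (0, 1]")
    }
  })
  invisible(config)
}

read_panel_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        col_select = 1:3, show_col_types = FALSE)
  tibble(chrom = df$chrom, pos = as.integer(df$start) + 1L)
}

#' Run the full methylome analysis pipeline
#'
#' Executes ingest (CGmap parsing, coverage-filtered aggregation, kNN
#' imputation) -> cell-type deconvolution -> factor-matrix construction
#' with collinearity pruning -> pseudoinverse multifactor fit with LOOCV
#' and in-sample evaluation -> per-site scoring and three-filter site
#' selection per factor, and writes every stage's table plus per-sign BED
#' exports and a run log into `out_dir`. Any stage failure leaves a
#' `FAILED` marker naming the stage alongside the partial outputs.
#'
#' @param config a `run_config` (or path to its YAML).
#' @param out_dir output directory (created; must be empty or absent).
#' @return Invisibly, a list with the in-memory stage results
#'   (`matrix`, `composition`, `factor_matrix`, `fit`, `loocv`,
#'   `fullfit`, `scores`, `selections`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), class = "semenmeth_pipeline_error")
  }

  tryCatch({
    log_line("semenmeth ", as.character(utils::packageVersion("semenmeth")),
             " | profile=", config$profile, " | seed=", config$seed)
    log_line("parameters: min_coverage=", config$min_coverage,
             " k=", config$k, " prune_threshold=", config$prune_threshold,
             " r_min=", config$r_min, " q_max=", config$q_max,
             " cap=", config$cap, " normalize=", config$normalize)

    stage <- "ingest"
    files <- list.files(config$cgmap_dir, pattern = "\\.cgmap$",
                        full.names = TRUE)
    if (length(files) == 0) stop_data("no .cgmap files in cgmap_dir")
    records <- stats::setNames(lapply(files, read_cgmap),
                               sub("\\.cgmap$", "", basename(files)))
    panel <- if (is.null(config$panel)) NULL else read_panel_bed(config$panel)
    mat <- aggregate_matrix(records, min_coverage = config$min_coverage,
                            panel = panel)
    log_line("ingest: ", nrow(mat$values), " samples x ", ncol(mat$values),
             " sites (", sum(is.na(mat$values)), " missing entries)")
    mat <- knn_impute(mat, k = config$k)
    write_methylation_matrix(mat, file.path(out_dir, "matrix.tsv"))

    stage <- "deconvolve"
    reference <- read_reference_matrix(config$reference)
    composition <- deconvolve_all(mat, reference,
                                  normalize = config$normalize)
    readr::write_tsv(as_tibble(composition),
                     file.path(out_dir, "composition.tsv"))
    log_line("deconvolve: ", length(cell_types(composition)),
             " cell types, median residual ",
             signif(stats::median(composition$residual), 3))

    stage <- "factors"
    phenotypes <- readr::read_tsv(config$phenotypes, show_col_types = FALSE)
    fm <- build_factor_matrix(phenotypes, composition,
                              factors = config$factors,
                              prune_threshold = config$prune_threshold,
                              pinned = config$pinned)
    readr::write_tsv(tidy(fm), file.path(out_dir, "factors.tsv"))
    readr::write_tsv(fm$pruned, file.path(out_dir, "pruning.tsv"))
    log_line("factors: retained {", paste(colnames(fm$X), collapse = ", "),
             "}; pruned {", paste(fm$pruned$factor, collapse = ", "), "}")

    stage <- "fit"
    fit <- mf_fit(mat, fm)
    cv <- loocv(mat, fm)
    full <- evaluate_fullfit(fit)
    readr::write_tsv(cv$stats, file.path(out_dir, "loocv_stats.tsv"))
    readr::write_tsv(cv$predictions,
                     file.path(out_dir, "loocv_predictions.tsv"))
    readr::write_tsv(full, file.path(out_dir, "fullfit_stats.tsv"))
    log_line("fit: LOOCV r = ",
             paste(sprintf("%s %.3f", cv$stats$factor, cv$stats$r),
                   collapse = ", "))

    stage <- "select"
    scores <- score_sites(fit)
    readr::write_tsv(as_tibble(scores), file.path(out_dir, "site_scores.tsv"))
    selections <- list()
    for (f in report_factors(fm)) {
      sel <- select_sites(scores, f, r_min = config$r_min,
                          q_max = config$q_max, cap = config$cap)
      selections[[f]] <- sel
      readr::write_tsv(tidy(sel),
                       file.path(out_dir, paste0("selection_", f, ".tsv")))
      for (sg in c("pos", "neg")) {
        ids <- sel$sites$site_id[sel$sites$sign == sg]
        if (length(ids) > 0) {
          write_sites_bed(ids, sg,
                          file.path(out_dir, paste0("sites_", f, "_", sg,
                                                    ".bed")))
        }
      }
      log_line("select: ", f, " -> ", sel$n_selected, " site(s) (",
               sel$n_pre_cap, " pre-cap; cap=", config$cap, ")")
    }
    log_line("done")

    invisible(list(matrix = mat, composition = composition,
                   factor_matrix = fm, fit = fit, loocv = cv,
                   fullfit = full, scores = scores,
                   selections = selections, out_dir = out_dir))
  }, semenmeth_parse_error = on_fail, semenmeth_data_error = on_fail,
     semenmeth_config_error = on_fail, error = on_fail)
}

#' Simulate a cohort and write its fixtures in one step
#'
#' Convenience wrapper chaining [simulation_config()], [simulate_cohort()]
#' and [export_fixtures()]; the command-line `simulate` subcommand calls
#' this.
#'
#' @param dir output directory.
#' @param ... passed to [simulation_config()] (or give `config`).
#' @param config an existing [simulation_config()].
#' @return The `synthetic_cohort`, invisibly.
#' @export
simulate_fixtures <- function(dir, ..., config = NULL) {
  if (is.null(config)) config <- simulation_config(...)
  cohort <- simulate_cohort(config)
  export_fixtures(cohort, dir)
  invisible(cohort)
}
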