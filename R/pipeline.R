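#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end run uses. Inputs are
#' either file paths (`fasta`, `annotations`, `sites`) or a generator
#' preset (`simulate`), not both.
#'
#' @param out_dir Run directory; artifacts and a log are written here.
#' @param fasta,annotations,sites Input paths (ignored when `simulate`).
#' @param simulate Optional [generator_params()] to generate inputs.
#' @param window A [window_config()].
#' @param balance_k Clusters (= retained samples) per class; `NULL`
#'   disables balancing.
#' @param seed Seed for balancing (and any other stochastic stage).
#' @param svm An [svm_config()].
#' @param do_sweep Run the per-group window-size sweep before encoding and
#'   adopt the best sizes.
#' @param sweep_sizes Candidate sizes for the sweep.
#' @param do_grid_search Tune (C, gamma) once on the full feature matrix
#'   before IFS (the default reuses `svm` as-is).
#' @param pwm_alpha,p0 PWM pseudocount and background frequency.
#' @return Object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, fasta = NULL, annotations = NULL,
                            sites = NULL, simulate = NULL,
                            window = window_config(), balance_k = 100L,
                            seed = 1L, svm = svm_config(),
                            do_sweep = FALSE,
                            sweep_sizes = seq(10L, 30L, 2L),
                            do_grid_search = FALSE,
                            pwm_alpha = 1, p0 = 0.05) {
  if (is.null(simulate) && (is.null(fasta) || is.null(sites)))
    stop("supply either input paths (fasta + sites) or a generator preset")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "GeneratorParams"))
  stopifnot(inherits(window, "WindowConfig"), inherits(svm, "SvmConfig"))
  structure(list(out_dir = out_dir, fasta = fasta,
                 annotations = annotations, sites = sites,
                 simulate = simulate, window = window,
                 balance_k = balance_k, seed = as.integer(seed), svm = svm,
                 do_sweep = do_sweep, sweep_sizes = sweep_sizes,
                 do_grid_search = do_grid_search,
                 pwm_alpha = pwm_alpha, p0 = p0),
            class = "PipelineConfig")
}

# md5 of an R object (via serialization to a temp file); used as the stage
# cache key so identical configs re-load rather than recompute.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# Run `fun` or load its cached result if the stage key is unchanged.
cached_stage <- function(run_dir, name, key, fun, log) {
  rds <- file.path(run_dir, paste0(name, ".rds"))
  keyfile <- file.path(run_dir, paste0(name, ".hash"))
  if (file.exists(rds) && file.exists(keyfile) &&
      identical(readLines(keyfile, warn = FALSE), key)) {
    log(sprintf("stage %s: cached", name))
    return(readRDS(rds))
  }
  log(sprintf("stage %s: running", name))
  out <- tryCatch(fun(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e)))
  saveRDS(out, rds, version = 2)
  writeLines(key, keyfile)
  out
}

#' Run the full prediction pipeline
#'
#' Stages, in order: build (or simulate) the dataset, balance classes by
#' clustering-based undersampling, optionally sweep per-group window
#' sizes, encode features, mRMR-rank them, run incremental feature
#' selection, and evaluate by jackknife. Every artifact plus the config
#' and seed land in the run directory, and re-running with an identical
#' config reproduces (and re-loads) every number.
#'
#' @param config A [pipeline_config()].
#' @return List with `dataset`, `windows` (the adopted [window_config()]),
#'   `features`, `ranking`, `ifs`, `eval`, and `run_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(run_dir, "run.log")
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  saveRDS(config, file.path(run_dir, "config.rds"), version = 2)
  writeLines(yaml::as.yaml(config_summary(config)),
             file.path(run_dir, "config.yaml"))
  table <- aa_property_table()
  base_key <- object_hash(config_summary(config))

  dataset <- cached_stage(run_dir, "dataset", base_key, function() {
    if (!is.null(config$simulate)) {
      sim <- generate(config$simulate, dir = file.path(run_dir, "input"))
      build_dataset(sim$proteins, sim$sites)
    } else {
      proteins <- read_fasta(config$fasta)
      if (!is.null(config$annotations))
        proteins <- read_annotations(config$annotations, proteins)
      build_dataset(proteins, read_site_table(config$sites, proteins))
    }
  }, log)

  balanced <- cached_stage(run_dir, "balanced", base_key, function() {
    if (is.null(config$balance_k)) return(dataset)
    k <- config$balance_k
    if (k >= length(dataset$positives) && k >= length(dataset$negatives)) {
      log("balancing skipped: k >= both class sizes")
      return(dataset)
    }
    encoder <- function(ws) {
      pw <- pwm_pair(dataset$positives, dataset$negatives,
                     p0 = config$p0, alpha = config$pwm_alpha)
      assemble_features(ws, config$window, pair = pw, table = table)$X
    }
    list(positives = cluster_undersample(
           dataset$positives, min(k, length(dataset$positives)),
           config$seed, encoder),
         negatives = cluster_undersample(
           dataset$negatives, min(k, length(dataset$negatives)),
           config$seed, encoder))
  }, log)
  log(sprintf("dataset: %d positives, %d negatives (balanced)",
              length(balanced$positives), length(balanced$negatives)))

  wcfg <- cached_stage(run_dir, "window_sizes", base_key, function() {
    if (!config$do_sweep) return(config$window)
    sizes <- lapply(c("F1", "F2", "F3", "F4"), function(g) {
      sw <- optimize_window_size(balanced$positives, balanced$negatives, g,
                                 sizes = config$sweep_sizes,
                                 svm = config$svm, table = table,
                                 p0 = config$p0, alpha = config$pwm_alpha)
      utils::write.table(sw$curve,
                         file.path(run_dir, paste0("sweep_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sw$best_size
    })
    window_config(sizes[[1]], sizes[[2]], sizes[[3]], sizes[[4]])
  }, log)
  log(sprintf("window sizes: F1=%d F2=%d F3=%d F4=%d",
              wcfg$w1, wcfg$w2, wcfg$w3, wcfg$w4))

  features <- cached_stage(run_dir, "features", base_key, function() {
    pw <- pwm_pair(balanced$positives, balanced$negatives,
                   p0 = config$p0, alpha = config$pwm_alpha)
    fm <- assemble_features(c(balanced$positives, balanced$negatives),
                            wcfg, pair = pw, table = table)
    write_feature_matrix(fm, file.path(run_dir, "features.csv"))
    fm
  }, log)

  svm <- cached_stage(run_dir, "svm_params", base_key, function() {
    if (!config$do_grid_search) return(config$svm)
    gs <- grid_search(features$X, features$y, config$svm)
    log(sprintf("grid search: C = %g, gamma = %g (auROC %.3f)",
                gs$C, gs$gamma, gs$auroc))
    svm_config(C = gs$C, gamma = gs$gamma, C_grid = config$svm$C_grid,
               gamma_grid = config$svm$gamma_grid)
  }, log)

  ranking <- cached_stage(run_dir, "ranking", base_key, function() {
    rk <- mrmr_rank(features$X, features$y)
    utils::write.table(
      data.frame(rank = seq_along(rk$order), feature = rk$names[rk$order],
                 relevance = rk$relevance[rk$order]),
      file.path(run_dir, "ranking.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    rk
  }, log)

  ifs_curve <- cached_stage(run_dir, "ifs", base_key, function() {
    curve <- ifs(features$X, features$y, ranking,
                 evaluator = function(Xs, ys)
                   jackknife_eval(Xs, ys, svm)$auroc)
    utils::write.table(data.frame(k = curve$k, auroc = curve$auroc),
                       file.path(run_dir, "ifs_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    curve
  }, log)
  log(sprintf("IFS: peak auROC %.3f at k = %d",
              ifs_curve$auroc[ifs_curve$best_k], ifs_curve$best_k))

  eval_full <- cached_stage(run_dir, "eval", base_key, function() {
    res <- jackknife_windows(balanced$positives, balanced$negatives, wcfg,
                             svm = svm, table = table, p0 = config$p0,
                             alpha = config$pwm_alpha)
    jsonlite::write_json(
      list(auroc = res$auroc, C = svm$C, gamma = svm$gamma,
           n = length(res$scores), best_k = ifs_curve$best_k,
           ifs_peak_auroc = ifs_curve$auroc[ifs_curve$best_k],
           roc = res$roc, scores = res$scores, labels = res$labels),
      file.path(run_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
    res
  }, log)
  log(sprintf("jackknife (leakage-free F1): auROC %.3f", eval_full$auroc))

  list(dataset = balanced, windows = wcfg, features = features,
       ranking = ranking, ifs = ifs_curve, eval = eval_full,
       run_dir = run_dir)
}

# Flat, serialization-stable summary of a config for hashing and the YAML
# sidecar (drops functions/environments, keeps every number that matters).
config_summary <- function(config) {
  sim <- config$simulate
  list(
    inputs = if (is.null(sim)) list(fasta = config$fasta,
                                    annotations = config$annotations,
                                    sites = config$sites)
             else list(simulate = unclass(sim)),
    window = unclass(config$window),
    balance_k = config$balance_k, seed = config$seed,
    svm = list(C = config$svm$C, gamma = config$svm$gamma,
               C_grid = as.numeric(config$svm$C_grid),
               gamma_grid = as.numeric(config$svm$gamma_grid)),
    do_sweep = config$do_sweep,
    sweep_sizes = as.integer(config$sweep_sizes),
    do_grid_search = config$do_grid_search,
    pwm_alpha = config$pwm_alpha, p0 = config$p0)
}
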