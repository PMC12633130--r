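# End-to-end pipeline: generate -> split -> train VAE -> train chain ->
# fidelity -> benchmark -> plan comparison, with a manifest recording
# seeds and artifact checksums so deterministic stages replay bit-exactly.

#' Pipeline configuration
#'
#' @param n Cohort size (default the reference 676).
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param outdir Output directory for artifacts.
#' @param preset `"fast"` (default; desk-scale epochs and one-point grids)
#'   or `"paper"` (full grids, long VAE schedule).
#' @param n_synth Synthetic patients for the fidelity report.
#' @param n_episodes Paired patients for the plan comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(n = 676, seed = 1, outdir = tempfile("hnctwin_run_"),
                       preset = c("fast", "paper"), n_synth = 500,
                       n_episodes = 100) {
  preset <- match.arg(preset)
  structure(list(n = n, seed = seed, outdir = outdir, preset = preset,
                 n_synth = n_synth, n_episodes = n_episodes),
            class = "run_config")
}

#' Run the full digital-twin pipeline
#'
#' Executes generate-cohort, split, train-vae, train-chain,
#' fidelity-report, benchmark, and the two-extreme-plans comparison
#' (conservative: no surgery, no induction, radiotherapy alone versus
#' aggressive: surgery, induction, chemoradiotherapy), writing every
#' artifact plus a `manifest.json` of stage seeds and file checksums.
#'
#' @param config A [run_config()].
#' @return The artifact directory path, invisibly; the manifest lists all
#'   outputs.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("hnctwin")),
                   config = unclass(config), stages = list())
  t0 <- Sys.time()
  stage <- function(name, code) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    res <- tryCatch(code, error = function(e) {
      stop_hnc("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  schema <- default_schema()
  params <- default_params(schema)
  epochs <- if (config$preset == "paper") 10000 else 300

  gen <- stage("generate-cohort", {
    g <- generate_cohort(params, config$n, seed = config$seed)
    write_cohort(g$cohort, out("cohort.csv"))
    readr::write_csv(g$truth, out("truth.csv"))
    g
  })
  sp <- stage("split", split_cohort(gen$cohort, seed = config$seed + 1))
  vae <- stage("train-vae", {
    v <- train_vae(sp$train, schema, vae_config(epochs = epochs, seed = config$seed + 2))
    readr::write_csv(v$history, out("vae_history.csv"))
    v
  })
  chain <- stage("train-chain",
                 fit_chain(sp$train, schema, grid = grid_config(config$preset),
                           seed = config$seed + 3))
  fid <- stage("fidelity-report", {
    synth <- sample_patients(vae, config$n_synth, seed = config$seed + 4)
    write_cohort(synth, out("synthetic_patients.csv"))
    f <- fidelity_report(sp$train, synth, schema)
    readr::write_csv(f$per_feature, out("fidelity.csv"))
    f
  })
  bench <- stage("benchmark", {
    models <- list(
      median_mean = baseline_median_mean(sp$train, schema),
      random = baseline_random(sp$train, schema),
      mlp = baseline_mlp(sp$train, schema, grid = grid_config(config$preset)$mlp,
                         seed = config$seed + 5),
      xgboost = chain)
    b <- benchmark(models, sp$test, schema, seed = config$seed + 6)
    readr::write_csv(b, out("benchmark.csv"))
    b
  })
  plans <- stage("env-demo", {
    cmp <- compare_plans(
      vae, chain,
      plan_a = c(definitive = "no", induction = "no", radio_chemo = "yes"),
      plan_b = c(definitive = "yes", induction = "yes",
                 radio_chemo = "yes_with_concurrent_chemotherapy"),
      n_episodes = config$n_episodes, seed = config$seed + 7)
    readr::write_csv(cmp$summary, out("plan_comparison.csv"))
    cmp
  })

  manifest$summary <- list(
    fidelity_mean_distance = fid$mean_distance,
    benchmark_targets = nrow(bench),
    plan_comparison = as.list(stats::setNames(
      plans$summary$mean_relapse_prob, plans$summary$plan))
  )
  files <- list.files(config$outdir, full.names = TRUE, pattern = "\\.csv$")
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$outdir)
}

#' Summarise a pipeline artifact directory
#'
#' Renders the fidelity mean, the benchmark table, and the plan-comparison
#' summary from a [run_pipeline()] output directory.
#'
#' @param artifact_dir Directory containing `manifest.json`.
#' @return A list with `manifest`, `fidelity`, `benchmark`,
#'   `plan_comparison`, printed as a human-readable summary.
#' @export
report_pipeline <- function(artifact_dir) {
  mf_path <- file.path(artifact_dir, "manifest.json")
  if (!file.exists(mf_path)) stop_hnc("no manifest.json in '%s'", artifact_dir)
  manifest <- jsonlite::read_json(mf_path)
  fidelity <- readr::read_csv(file.path(artifact_dir, "fidelity.csv"),
                              show_col_types = FALSE)
  bench <- readr::read_csv(file.path(artifact_dir, "benchmark.csv"),
                           show_col_types = FALSE)
  plans <- readr::read_csv(file.path(artifact_dir, "plan_comparison.csv"),
                           show_col_types = FALSE)
  cat(sprintf("hnctwin pipeline report (seed %s, preset %s)\n",
              manifest$config$seed, manifest$config$preset))
  cat(sprintf("Mean per-feature fidelity distance: %.4f\n",
              mean(fidelity$distance)))
  cat(sprintf("Benchmark (%d targets):\n", nrow(bench)))
  print(bench, n = nrow(bench))
  cat("Plan comparison:\n")
  print(plans)
  invisible(list(manifest = manifest, fidelity = fidelity, benchmark = bench,
                 plan_comparison = plans))
}
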