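# Orchestration: structured run configuration, the end-to-end pipeline
# (data -> baseline -> channel search -> evaluation -> reports), and
# rendering of the channel-reduction and metrics tables.

default_config <- function() {
  list(
    seed = 1L,
    data = list(dir = NULL, generate = TRUE, n_scenes = 52L,
                size = 64L, split = 0.75),
    search = list(pop = 4L, iters = 2L, epochs = 1L),
    evaluation = list(epochs = 1L),
    out_dir = "lodgeopt_run")
}

#' Read and validate a run configuration
#'
#' Configurations are YAML documents with sections `seed`, `data`
#' (`dir`, `generate`, `n_scenes`, `size`, `split`), `search` (`pop`,
#' `iters`, `epochs`), `evaluation` (`epochs`) and `out_dir`. Unknown
#' keys are rejected; omitted keys take desk-scale defaults. The resolved
#' configuration is written next to every run's outputs.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- default_config()
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(cfg, def, "top level")
  for (sec in c("data", "search", "evaluation"))
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], def[[sec]], sec)
  out <- utils::modifyList(def, cfg)
  stopifnot(out$search$pop >= 2, out$search$iters >= 0,
            out$search$epochs >= 1, out$data$n_scenes >= 4)
  out
}

train_and_report <- function(x, base_plan, train, val, epochs, seed) {
  plan <- decode_channels(x, base_plan)
  hw <- dim(train[[1]]$image)[1:2]
  spec <- reference_spec(plan, input_size = hw)
  net <- build_network(spec, seed = seed)
  tr <- train_network(net, train, epochs = epochs, seed = seed)
  rep <- evaluate_network(tr$net, val)
  list(metrics = rep, params = count_parameters(spec),
       flops = count_flops(spec, hw), plan = plan)
}

metrics_block <- function(label, tr) {
  data.frame(model = label,
             pa_pct = 100 * tr$metrics$pa,
             mpa_pct = 100 * tr$metrics$mpa,
             miou_pct = 100 * tr$metrics$miou,
             params_m = tr$params / 1e6,
             flops_g = tr$flops / 1e9)
}

#' Run the full pipeline
#'
#' Generates (or loads) the dataset, trains the baseline plan, runs the
#' channel search, retrains and evaluates the best plan found, and writes
#' all artifacts into the run directory: the resolved configuration
#' (`config.yaml`), the search history (`history.jsonl`), the best plan
#' (`best_plan.csv`), the channel-reduction report (`reduction_report.csv`
#' and `.txt`), and the metrics block for baseline vs best
#' (`metrics.csv`: PA, MPA, mIoU, parameters, FLOPs).
#'
#' @param config A [read_run_config()] result, a YAML path, or a list.
#' @return The run directory path (invisibly), with results attached as
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))

  # --- data ---
  data_dir <- if (is.null(cfg$data$dir))
    file.path(cfg$out_dir, "data") else cfg$data$dir
  if (isTRUE(cfg$data$generate)) {
    sp <- scene_params(size = cfg$data$size, seed = cfg$seed)
    generate_dataset(cfg$data$n_scenes, sp, data_dir,
                     split = cfg$data$split)
  }
  ds <- load_dataset(data_dir)

  base_plan <- base_channel_plan()

  # --- baseline ---
  baseline <- train_and_report(rep(0, nrow(base_plan)), base_plan,
                               ds$train, ds$val,
                               epochs = cfg$evaluation$epochs,
                               seed = cfg$seed)

  # --- search ---
  sr <- channel_search(base_plan, ds$train, ds$val,
                       n = cfg$search$pop, iters = cfg$search$iters,
                       epochs = cfg$search$epochs, seed = cfg$seed)

  # --- evaluate best ---
  best <- train_and_report(sr$best_x, base_plan, ds$train, ds$val,
                           epochs = cfg$evaluation$epochs,
                           seed = cfg$seed)

  # --- reports ---
  hist_lines <- vapply(sr$history, function(h)
    jsonlite::toJSON(h, auto_unbox = TRUE, digits = NA), character(1))
  writeLines(hist_lines, file.path(cfg$out_dir, "history.jsonl"))
  utils::write.csv(sr$best$plan, file.path(cfg$out_dir, "best_plan.csv"),
                   row.names = FALSE)
  utils::write.csv(sr$report$rows,
                   file.path(cfg$out_dir, "reduction_report.csv"),
                   row.names = FALSE)
  writeLines(format_reduction_report(sr$report),
             file.path(cfg$out_dir, "reduction_report.txt"))
  met <- rbind(metrics_block("baseline", baseline),
               metrics_block("optimized", best))
  utils::write.csv(met, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)

  res <- list(baseline = baseline, best = best, search = sr,
              metrics = met)
  out <- cfg$out_dir
  attr(out, "results") <- res
  invisible(out)
}

#' Render the report tables of a finished run
#'
#' Re-reads a run directory's artifacts and returns the reduction report
#' and metrics block; missing artifacts raise an error naming each absent
#' file.
#'
#' @param run_dir Run directory written by [run_pipeline()].
#' @return List with `reduction` (data frame), `metrics` (data frame) and
#'   `text` (aligned reduction table lines).
#' @export
render_tables <- function(run_dir) {
  need <- file.path(run_dir, c("reduction_report.csv", "metrics.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing run artifact(s): ", paste(missing, collapse = ", "))
  red <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  met <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  plan <- channel_plan(red$layer_id, red$base, red$optimized)
  list(reduction = red, metrics = met,
       text = format_reduction_report(summarize_plan(plan)))
}
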