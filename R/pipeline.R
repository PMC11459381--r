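default_run_config <- function() {
  list(seed = 1L, out_dir = "spikequant_out",
       simulate = list(),
       inputs = NULL,
       quantify = list(aggregator = "mean"),
       taxa = list(patterns = NULL),
       validate = list(distance_km = 20, hours = 6, grid = c(10, 20, 30),
                       policy = "nearest_one_to_one", plot = FALSE))
}

#' Validate a pipeline run configuration
#'
#' A run either simulates its inputs (a `simulate` section of [sim_config()]
#' overrides) or reads them from disk (an `inputs` section naming the six
#' files: counts, metadata, standards, taxonomy, copy_map, fcm).
#'
#' @param config a list, or the path of a JSON file holding one
#' @return the normalized config (invisibly usable downstream)
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      config_abort(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) config_abort("config must be a list or JSON object")
  out <- utils::modifyList(default_run_config(), config)
  if (!is.numeric(out$seed) || length(out$seed) != 1L)
    config_abort("config field 'seed' must be a single integer")
  out$seed <- as.integer(out$seed)
  if (!is.character(out$out_dir) || length(out$out_dir) != 1L)
    config_abort("config field 'out_dir' must be a single path")
  if (!is.null(out$inputs)) {
    req <- c("counts", "metadata", "standards", "taxonomy", "copy_map", "fcm")
    missing <- setdiff(req, names(out$inputs))
    if (length(missing) > 0L)
      config_abort(sprintf("config 'inputs' missing field(s): %s",
                           paste(missing, collapse = ", ")))
  }
  v <- out$validate
  if (!is.numeric(v$distance_km) || v$distance_km <= 0)
    config_abort("config field 'validate.distance_km' must be > 0")
  if (!is.numeric(v$hours) || v$hours <= 0)
    config_abort("config field 'validate.hours' must be > 0")
  if (!is.numeric(v$grid) || length(v$grid) == 0L || is.unsorted(v$grid))
    config_abort("config field 'validate.grid' must be ascending km bounds")
  if (!v$policy %in% c("nearest_one_to_one", "all_pairs"))
    config_abort("config field 'validate.policy' must be nearest_one_to_one or all_pairs")
  if (!out$quantify$aggregator %in% c("mean", "median"))
    config_abort("config field 'quantify.aggregator' must be mean or median")
  out
}

#' Run the full pipeline: simulate/ingest, quantify, taxa, validate
#'
#' Executes the stages in order, writing under `out_dir`: the simulated (or
#' digested) inputs, `abundances.tsv`, `taxon_abundances.tsv`, `pairs.tsv`,
#' `regressions.tsv`, `sensitivity.tsv`, a JSON-lines `log.jsonl` of dropouts
#' and exclusions, and `manifest.json` with provenance (config hash, input
#' digests, seed, per-stage row counts, warnings). Any stage failure writes a
#' partial manifest naming the failed stage and rethrows.
#'
#' @param config list or JSON path, see [validate_run_config()]
#' @param seed optional override of the config seed
#' @return invisibly, a list with the stage results and the manifest
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "spikequant",
                   version = as.character(utils::packageVersion("spikequant")),
                   config_hash = hash_config(cfg), seed = cfg$seed,
                   stages = list(), warnings = list())
  log_records <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$failed_stage <<- name
      manifest$created <<- iso_utc(Sys.time())
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "spikequant_stage_error")
    })
    res
  }

  # -- stage 1: simulate or ingest ------------------------------------------
  inputs <- stage("ingest", {
    if (is.null(cfg$inputs)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      ws <- write_simulation(sc, file.path(out_dir, "inputs"))
      list(counts = ws$sim$counts, metadata = ws$sim$metadata,
           standards = ws$sim$standards, taxonomy = ws$sim$taxonomy,
           copy_map = ws$sim$copy_map, fcm = ws$fcm, paths = ws$paths)
    } else {
      p <- cfg$inputs
      list(counts = read_count_table(p$counts),
           metadata = read_metadata(p$metadata),
           standards = read_standards(p$standards),
           taxonomy = read_taxonomy(p$taxonomy),
           copy_map = read_copy_map(p$copy_map),
           fcm = read_fcm(p$fcm), paths = p)
    }
  })
  manifest$input_digests <- as.list(tools::md5sum(unlist(inputs$paths)))
  manifest$stages$ingest <- list(status = "ok",
                                 rows = length(inputs$counts$sample_ids))

  # -- stage 2: quantify -----------------------------------------------------
  am <- stage("quantify", withCallingHandlers(
    build_abundance_matrix(inputs$counts, inputs$metadata, inputs$standards,
                           aggregator = cfg$quantify$aggregator),
    warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  write_abundance_table(am, file.path(out_dir, "abundances.tsv"))
  for (r in seq_len(nrow(am$dropouts)))
    log_records <- c(log_records, list(c(event = "standard_dropout",
                                         as.list(am$dropouts[r, ]))))
  for (s in am$excluded_sites)
    log_records <- c(log_records, list(list(event = "site_excluded",
                                            site_id = s)))
  manifest$stages$quantify <- list(status = "ok", rows = nrow(am$summary),
                                   dropouts = nrow(am$dropouts),
                                   excluded_sites = length(am$excluded_sites))

  # -- stage 3: taxa ---------------------------------------------------------
  ta <- stage("taxa", {
    patterns <- cfg$taxa$patterns
    if (is.null(patterns)) {
      patterns <- stats::setNames(names(inputs$copy_map), names(inputs$copy_map))
    } else patterns <- unlist(patterns)
    assignment <- assign_taxa(inputs$taxonomy, patterns)
    withCallingHandlers(
      taxon_abundances(am, assignment, inputs$copy_map),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  write_taxon_table(ta, file.path(out_dir, "taxon_abundances.tsv"))
  manifest$stages$taxa <- list(status = "ok", rows = nrow(ta$summary))

  # -- stage 4: validate -----------------------------------------------------
  val <- stage("validate", {
    v <- cfg$validate
    sites <- site_positions(inputs$metadata)
    pairs <- find_matchups(sites, inputs$fcm,
                           matchup_criteria(v$distance_km, v$hours,
                                            policy = v$policy))
    mt <- matchup_table(pairs, ta, inputs$fcm,
                        populations = names(inputs$copy_map))
    reg <- if (nrow(mt) > 0L) validate_matchups(mt, names(inputs$copy_map))
           else NULL
    sens <- sensitivity_analysis(sites, inputs$fcm, ta,
                                 distance_grid = v$grid, max_hours = v$hours,
                                 policy = v$policy,
                                 populations = names(inputs$copy_map))
    list(pairs = pairs, match_tbl = mt, regressions = reg, sensitivity = sens)
  })
  utils::write.table(val$pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(val$regressions)) {
    reg_rows <- c(list(data.frame(comparison = "pooled_cells",
                                  t(unlist(val$regressions$pooled)))),
                  lapply(names(val$regressions$per_population), function(p) {
                    r <- val$regressions$per_population[[p]]
                    if (is.null(r)) return(NULL)
                    data.frame(comparison = p, t(unlist(r)))
                  }),
                  if (!is.null(val$regressions$ratio))
                    list(data.frame(comparison = "ratio",
                                    t(unlist(val$regressions$ratio)))))
    utils::write.table(do.call(rbind, reg_rows),
                       file.path(out_dir, "regressions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(val$regressions$ratio_flag) &&
        !is.na(val$regressions$ratio_flag))
      log_records <- c(log_records, list(list(event = "ratio_flag",
                                              message = val$regressions$ratio_flag)))
  }
  utils::write.table(val$sensitivity, file.path(out_dir, "sensitivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$validate$plot) && nrow(val$match_tbl) > 0L)
    plot_matchups(val$match_tbl, file.path(out_dir, "matchups.pdf"))
  manifest$stages$validate <- list(status = "ok", rows = nrow(val$pairs))

  write_jsonl(log_records, file.path(out_dir, "log.jsonl"))
  manifest$output_digests <- as.list(tools::md5sum(
    file.path(out_dir, c("abundances.tsv", "taxon_abundances.tsv", "pairs.tsv",
                         "sensitivity.tsv"))))
  manifest$created <- iso_utc(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(abundance = am, taxa = ta, validation = val,
                 manifest = manifest))
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      config_abort(sprintf("unexpected argument: %s", args[i]))
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      config_abort(sprintf("flag --%s needs a value", key))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run` (simulate + quantify + taxa + validate),
#' `quantify`, `taxa`, `validate` — each driven by `--config config.json`
#' plus the overrides `--seed`, `--out`. `spikequant --version` prints the
#' package version. Returns (and, under Rscript, exits with) 0 on success,
#' 1 on a stage failure, 2 on a config/usage error.
#'
#' @param args character vector, defaults to the trailing command-line args
#' @return integer exit status, invisibly
#' @export
spikequant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      config_abort("usage: spikequant <simulate|run> [--config f.json] [--seed n] [--out dir]")
    if (args[1] == "--version") {
      cat(sprintf("spikequant %s\n",
                  as.character(utils::packageVersion("spikequant"))))
      return(invisible(0L))
    }
    cmd <- args[1]
    opts <- cli_args_to_list(args[-1])
    cfg <- if (!is.null(opts$config)) validate_run_config(opts$config)
           else default_run_config()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    switch(cmd,
           simulate = {
             sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
             write_simulation(sc, cfg$out_dir)
           },
           run = , quantify = , taxa = , validate = run_pipeline(cfg),
           config_abort(sprintf("unknown subcommand: %s", cmd)))
    0L
  },
  spikequant_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
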