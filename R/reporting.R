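# Configuration-driven runs and tabular reports. Figures are deliberately
# exported as tidy tables (TSV) so any plotting layer can render them.

#' Run an analysis described by a YAML configuration
#'
#' The configuration selects a model (`model: core_fixture`, or a path
#' plus `dialect`), an environment, the candidate metabolite exchanges,
#' the method and its parameters, and which tasks to run. Results are
#' written as TSV tables plus a JSON run manifest into `outdir`.
#'
#' Config keys: `model`, `dialect`, `environment` (`dilution_rate`,
#' `primary_carbon`, `uptake_cap`, `inorganics`), `metabolites`, `method`
#' (`room` / `room_het`), `beta`, `seed`, `tasks` (subset of `ancestor`,
#' `scan`, `rank`, `sweep`), `sweep_grid`, `outdir`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outdir output directory (overrides the config's `outdir`).
#' @return the manifest (named list), invisibly; files on disk.
#' @export
run_config <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  schema_check_config(cfg)
  if (is.null(outdir)) outdir <- cfg$outdir
  cf_assert(!is.null(outdir), "crossfeedr_config_error",
            "no output directory given (config key 'outdir' or argument)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  model <- if (identical(cfg$model, "core_fixture")) {
    make_core_fixture()
  } else {
    load_model(cfg$model, dialect = if (is.null(cfg$dialect)) "bigg_json"
               else cfg$dialect)
  }
  env <- if (identical(cfg$model, "core_fixture") && is.null(cfg$environment)) {
    core_fixture_env()
  } else {
    ec <- cfg$environment
    chemostat_env(
      dilution_rate = if (is.null(ec$dilution_rate)) 0.2 else ec$dilution_rate,
      primary_carbon = ec$primary_carbon,
      uptake_cap = if (is.null(ec$uptake_cap)) 10 else ec$uptake_cap,
      inorganics = unlist(ec$inorganics))
  }
  beta <- if (is.null(cfg$beta)) 0.001 else cfg$beta
  method <- if (is.null(cfg$method)) "room" else cfg$method
  tasks <- if (is.null(cfg$tasks)) c("ancestor", "scan", "rank") else
    unlist(cfg$tasks)

  t0 <- proc.time()[["elapsed"]]
  manifest <- list(package = "crossfeedr",
                   version = as.character(utils::packageVersion("crossfeedr")),
                   model = model$id,
                   model_checksum = model_checksum(model),
                   solver = "crossfeedr simplex + branch-and-bound",
                   beta = beta, method = method,
                   seed = cfg$seed,
                   config = cfg, outputs = list(), timings = list())
  tick <- function(step, t) {
    manifest$timings[[step]] <<- round(t, 3)
  }
  results <- NULL

  if ("ancestor" %in% tasks) {
    ta <- proc.time()[["elapsed"]]
    anc <- ancestral_state(model, env)
    tab <- data.frame(reaction = names(anc$values), flux = anc$values,
                      role = model$reaction_role,
                      subsystem = model$subsystem)
    f <- file.path(outdir, "ancestor_fluxes.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$ancestor_fluxes <- basename(f)
    tick("ancestor", proc.time()[["elapsed"]] - ta)
  }
  if (any(c("scan", "rank") %in% tasks)) {
    ts <- proc.time()[["elapsed"]]
    results <- compute_distances(model, env, unlist(cfg$metabolites),
                                 method = method, beta = beta)
    per <- do.call(rbind, lapply(results, function(x) data.frame(
      metabolite = x$metabolite, role = x$role, distance = x$distance,
      turned_on = length(x$classification$turned_on),
      turned_off = length(x$classification$turned_off),
      magnitude = length(x$classification$magnitude_change),
      glucose = x$glucose, secondary = x$secondary)))
    f <- file.path(outdir, "distances.tsv")
    write.table(per, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$distances <- basename(f)
    tick("scan", proc.time()[["elapsed"]] - ts)
  }
  if ("rank" %in% tasks && length(results) > 0) {
    tr <- proc.time()[["elapsed"]]
    ranking <- rank_metabolites(results)
    f <- file.path(outdir, "ranking.tsv")
    write.table(ranking, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$ranking <- basename(f)
    tick("rank", proc.time()[["elapsed"]] - tr)
  }
  if ("sweep" %in% tasks) {
    tw <- proc.time()[["elapsed"]]
    grid <- unlist(cfg$sweep_grid)
    cf_assert(length(grid) >= 2, "crossfeedr_config_error",
              "sweep task needs a 'sweep_grid' with at least two caps")
    sw <- glucose_sweep(model, env, unlist(cfg$metabolites), grid,
                        beta = beta)
    f <- file.path(outdir, "sweep.tsv")
    write.table(sw$distances, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$outputs$sweep <- basename(f)
    tick("sweep", proc.time()[["elapsed"]] - tw)
  }

  tick("total", proc.time()[["elapsed"]] - t0)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

schema_check_config <- function(cfg) {
  cf_assert(is.list(cfg), "crossfeedr_config_error",
            "configuration must be a named list / YAML mapping")
  known <- c("model", "dialect", "environment", "metabolites", "method",
             "beta", "seed", "tasks", "sweep_grid", "outdir", "solver")
  extra <- setdiff(names(cfg), known)
  cf_assert(length(extra) == 0, "crossfeedr_config_error",
            sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  cf_assert(!is.null(cfg$model), "crossfeedr_config_error",
            "config key 'model' is required")
  if (!is.null(cfg$method)) {
    cf_assert(cfg$method %in% c("room", "room_het"), "crossfeedr_config_error",
              sprintf("unknown method '%s'", cfg$method))
  }
  if (!is.null(cfg$solver)) {
    cf_assert(cfg$solver %in% c("simplex", "default"),
              "crossfeedr_config_error",
              sprintf("unknown solver name '%s'", cfg$solver))
  }
  invisible(TRUE)
}

model_checksum <- function(model) {
  Sd <- as.matrix(model$S)
  # cheap content hash without extra dependencies
  key <- paste(c(model$reaction_ids, model$metabolite_ids,
                 format(c(Sd[Sd != 0], model$lb, model$ub), digits = 17)),
               collapse = "|")
  sprintf("%08x", sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% 0xFFFFFFFF)
}

#' Summarize a completed run directory
#'
#' Reads the TSV outputs written by [run_config()] and produces summary
#' tables: a per-strain subsystem breakdown (when the model carries
#' subsystem labels), the ranking with its on/off/magnitude decomposition,
#' and the sweep table when present.
#'
#' @param outdir directory written by [run_config()].
#' @return list with `subsystems`, `ranking`, `sweep` (entries `NULL` with
#'   a warning when the run lacks them).
#' @export
report_run <- function(outdir) {
  mf <- file.path(outdir, "manifest.json")
  cf_assert(file.exists(mf), "crossfeedr_contract_error",
            sprintf("'%s' is not a completed run directory (no manifest)",
                    outdir))
  manifest <- jsonlite::read_json(mf)
  grab <- function(key) {
    f <- manifest$outputs[[key]]
    if (is.null(f)) return(NULL)
    read.delim(file.path(outdir, f), sep = "\t", stringsAsFactors = FALSE)
  }
  ranking <- grab("ranking")
  sweep <- grab("sweep")
  anc <- grab("ancestor_fluxes")
  subsystems <- NULL
  if (!is.null(anc) && "subsystem" %in% names(anc)) {
    act <- anc[abs(anc$flux) > 1e-6, ]
    subsystems <- as.data.frame(table(subsystem = act$subsystem),
                                stringsAsFactors = FALSE)
    names(subsystems)[2] <- "active_reactions"
  }
  if (is.null(sweep)) warning("run lacks a sweep table", call. = FALSE)
  list(subsystems = subsystems, ranking = ranking, sweep = sweep)
}
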