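## End-to-end orchestration: table ingestion, replicate averaging,
## per-condition fitting, enrichment summaries, reports and a run manifest.

.TABLE_COLS <- c("metabolite", "mass_level", "value", "replicate", "condition")

#' Read a measurement table
#'
#' Ingests the delimited measurement schema (`metabolite, mass_level,
#' value, replicate, condition`; `mass_level` is an explicit 0-based
#' integer). `value` holds either pre-corrected isotopologue fractions or
#' raw peak intensities (`values = "intensity"`); intensities should be
#' passed through [correctNaturalAbundance()] downstream (the pipeline does
#' this when configured). Mass levels absent for a (metabolite, replicate,
#' condition) triple are filled as 0 with a warning.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension).
#' @param values `"fraction"` (default) or `"intensity"`; recorded on the
#'   result as attribute `values`.
#' @param n_carbons optional named integer vector giving the expected
#'   carbon count per metabolite (used to pad missing trailing levels);
#'   defaults to the highest observed level.
#' @return nested list: condition -> metabolite -> numeric matrix
#'   (replicate x mass level 0..n), with attribute `values`.
#' @seealso [averageReplicates()], [generateExperiment()]
#' @export
readMeasurementTable <- function(path, values = c("fraction", "intensity"),
                                 n_carbons = NULL) {
  values <- match.arg(values)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), .TABLE_COLS)
  if (length(unknown))
    stop(sprintf("unknown column(s) in measurement table: %s",
                 paste(unknown, collapse = ", ")))
  miss <- setdiff(.TABLE_COLS, names(tab))
  if (length(miss))
    stop(sprintf("measurement table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(tab$value < 0)) stop("negative values in measurement table")
  key <- paste(tab$metabolite, tab$mass_level, tab$replicate, tab$condition,
               sep = "|")
  if (anyDuplicated(key))
    stop(sprintf("duplicate row for (metabolite, mass_level, replicate, condition) = (%s)",
                 gsub("\\|", ", ", key[duplicated(key)][1])))

  out <- list()
  for (cond in unique(tab$condition)) {
    tc <- tab[tab$condition == cond, ]
    mats <- list()
    for (met in unique(tc$metabolite)) {
      tm <- tc[tc$metabolite == met, ]
      nmax <- if (!is.null(n_carbons) && met %in% names(n_carbons))
        n_carbons[[met]] else max(tm$mass_level)
      reps <- sort(unique(tm$replicate))
      mat <- matrix(0, nrow = length(reps), ncol = nmax + 1L,
                    dimnames = list(NULL, 0:nmax))
      filled <- FALSE
      for (i in seq_along(reps)) {
        tr <- tm[tm$replicate == reps[i], ]
        if (length(tr$mass_level) < nmax + 1L) filled <- TRUE
        mat[i, tr$mass_level + 1L] <- tr$value
      }
      if (filled)
        warning(sprintf("missing mass level(s) for %s/%s filled as 0",
                        cond, met))
      mats[[met]] <- mat
    }
    out[[cond]] <- mats
  }
  attr(out, "values") <- values
  out
}

#' Average replicate MIDs into a MeasurementSet
#'
#' Arithmetic mean per mass level across replicates, renormalized onto the
#' simplex; the per-level standard deviation is retained for diagnostics.
#'
#' @param replicates named list of replicate x mass-level matrices (rows
#'   may be raw fractions; each row is normalized before averaging).
#' @param condition condition label.
#' @return a [MeasurementSet].
#' @export
averageReplicates <- function(replicates, condition = "default") {
  if (!length(replicates)) stop("no replicate data supplied")
  norm <- lapply(replicates, function(m) {
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    t(apply(m, 1, normalizeMid))
  })
  avg <- lapply(norm, function(m) normalizeMid(unname(colMeans(m))))
  new("MeasurementSet", condition = condition, mids = avg,
      replicates = norm,
      dispersion = lapply(norm, function(m) apply(m, 2, sd)))
}

## validation failures carry a dedicated condition class so the CLI can
## map them to its own exit code
.cfgStop <- function(...) {
  stop(errorCondition(sprintf(...), class = c("isofluxValidationError",
                                              "error", "condition")))
}

.validateRunConfig <- function(cfg, mode = c("fit", "simulate")) {
  mode <- match.arg(mode)
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg$network)) .cfgStop("config must name a network (path or YAML)")
  cfg$tracer_purity <- cfg$tracer_purity %||% 0.99
  cfg$p_nat <- cfg$p_nat %||% 0.0107
  cfg$correct <- isTRUE(cfg$correct)
  cfg$n_restarts <- as.integer(cfg$n_restarts %||%
                                 if (isTRUE(cfg$desk_scale)) 200L else 10000L)
  cfg$keep <- as.integer(cfg$keep %||% if (isTRUE(cfg$desk_scale)) 20L else 50L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (cfg$keep > cfg$n_restarts)
    .cfgStop("config error: keep exceeds n_restarts")
  if (cfg$tracer_purity < 0 || cfg$tracer_purity > 1)
    .cfgStop("config error: tracer_purity outside [0, 1]")
  if (mode == "fit" && is.null(cfg$measurements))
    .cfgStop("config must name a measurement table in fit mode")
  if (mode == "fit" && !file.exists(cfg$measurements))
    .cfgStop("measurement table not found: %s", cfg$measurements)
  if (is.null(cfg$out)) .cfgStop("config must name an output directory 'out'")
  cfg
}

.loadModel <- function(network) {
  if (is(network, "NetworkModel")) network else buildNetwork(network)
}

.manifest <- function(cfg, model, extra = list()) {
  digests <- list()
  for (f in c(cfg$network, cfg$measurements)) {
    if (is.character(f) && length(f) == 1 && file.exists(f))
      digests[[basename(f)]] <- unname(tools::md5sum(f))
  }
  c(list(
    package = "isoflux",
    version = as.character(packageVersion("isoflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    n_restarts = cfg$n_restarts,
    keep = cfg$keep,
    tracer = list(pool = cfg$tracer_pool, purity = cfg$tracer_purity),
    natural_abundance = list(applied = cfg$correct, p_nat = cfg$p_nat),
    tolerances = list(fixed_point = 1e-10, balance = 1e-6,
                      optimizer_objective = 1e-9),
    input_digests = digests), extra)
}

#' Run the full fitting pipeline from a configuration
#'
#' Stages, per condition found in the measurement table: optional natural
#' abundance correction of each replicate pattern, replicate averaging,
#' ensemble fitting, ensemble summary, and a labeling-enrichment table.
#' When more than one condition is present, every non-control condition is
#' compared against the control (first condition, or `cfg$control`) by
#' per-flux unpaired t-tests. All outputs are written under `cfg$out`:
#' `flux_report_<condition>.csv`, `comparison.csv`, `enrichment.csv`,
#' `manifest.yaml` and, when `cfg$trace` is TRUE,
#' `restart_trace_<condition>.csv`.
#'
#' Two runs with an identical configuration (including `seed`) produce
#' byte-identical reports; only the manifest timestamp differs.
#'
#' @param cfg a list (or path to a YAML file) with entries: `network`
#'   (path or YAML text), `measurements` (table path), `tracer_pool`,
#'   `tracer_purity`, `correct` + `p_nat`, `n_restarts`, `keep`, `seed`,
#'   `desk_scale`, `control`, `trace`, `out` (output directory).
#' @return named list of written file paths, invisibly; the fitted
#'   ensembles are attached as attribute `ensembles`.
#' @export
runFit <- function(cfg) {
  cfg <- .validateRunConfig(cfg, "fit")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    message(sprintf("[isoflux] %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  model <- stage("load network", .loadModel(cfg$network))
  if (is.null(cfg$tracer_pool))
    stop("config must name the labeled source pool 'tracer_pool'")
  tracer <- tracerSpec(cfg$tracer_pool, cfg$tracer_purity)
  nC <- setNames(pools(model)$n_carbons, poolIds(model))

  raw <- stage("read measurements",
               readMeasurementTable(cfg$measurements,
                                    values = if (cfg$correct) "intensity"
                                             else "fraction",
                                    n_carbons = nC))

  written <- character()
  ensembles <- list()
  enr_rows <- list()
  for (cond in names(raw)) {
    mats <- raw[[cond]]
    if (cfg$correct) {
      mats <- stage(sprintf("natural-abundance correction (%s)", cond),
        lapply(setNames(names(mats), names(mats)), function(m) {
          t(apply(mats[[m]], 1, correctNaturalAbundance,
                  n_carbons = ncol(mats[[m]]) - 1L, p_nat = cfg$p_nat))
        }))
    }
    ms <- stage(sprintf("replicate averaging (%s)", cond),
                averageReplicates(mats, condition = cond))
    ens <- stage(sprintf("ensemble fit (%s)", cond),
                 fitEnsemble(model, ms, tracer,
                             n_restarts = cfg$n_restarts, keep = cfg$keep,
                             base_seed = cfg$seed))
    ensembles[[cond]] <- ens
    rep_path <- file.path(cfg$out, sprintf("flux_report_%s.csv", cond))
    write.csv(summarizeEnsemble(ens), rep_path, row.names = FALSE,
              quote = FALSE)
    written <- c(written, rep_path)
    if (isTRUE(cfg$trace)) {
      tr_path <- file.path(cfg$out, sprintf("restart_trace_%s.csv", cond))
      write.csv(restartTrace(ens), tr_path, row.names = FALSE, quote = FALSE)
      written <- c(written, tr_path)
    }
    for (m in names(mids(ms)))
      enr_rows[[paste(cond, m)]] <- data.frame(
        metabolite = m, condition = cond,
        mean_enrichment = meanEnrichment(mids(ms)[[m]]),
        stringsAsFactors = FALSE)
  }

  enr_path <- file.path(cfg$out, "enrichment.csv")
  enr <- do.call(rbind, enr_rows)
  rownames(enr) <- NULL
  write.csv(enr, enr_path, row.names = FALSE, quote = FALSE)
  written <- c(written, enr_path)

  if (length(ensembles) > 1) {
    control <- cfg$control %||% names(ensembles)[1]
    if (!control %in% names(ensembles))
      stop(sprintf("control condition '%s' not present in the data", control))
    cmp <- list()
    for (cond in setdiff(names(ensembles), control)) {
      ci <- compareConditions(ensembles[[cond]], ensembles[[control]])
      ci <- cbind(condition = cond, control = control, ci)
      cmp[[cond]] <- ci
    }
    cmp_path <- file.path(cfg$out, "comparison.csv")
    write.csv(do.call(rbind, cmp), cmp_path, row.names = FALSE, quote = FALSE)
    written <- c(written, cmp_path)
  }

  man_path <- file.path(cfg$out, "manifest.yaml")
  yaml::write_yaml(.manifest(cfg, model,
                             list(conditions = as.list(names(raw)))),
                   man_path)
  written <- c(written, man_path)
  out <- as.list(written)
  attr(out, "ensembles") <- ensembles
  invisible(out)
}

#' Simulate a synthetic experiment from a configuration
#'
#' Thin orchestration over [generateExperiment()]: loads the network,
#' resolves the true fluxes (`cfg$true_fluxes` as a named list, or the
#' bundled reference scenario when the config names the bundled network),
#' and writes the measurement table plus metadata sidecar under `cfg$out`.
#'
#' @param cfg list or YAML path with `network`, `true_fluxes`,
#'   `tracer_pool`, `tracer_purity`, `sigma`, `n_replicates`, `seed`,
#'   `out`.
#' @return the written file paths, invisibly; the
#'   [SyntheticExperiment] is attached as attribute `experiment`.
#' @export
runSimulate <- function(cfg) {
  cfg <- .validateRunConfig(cfg, "simulate")
  model <- .loadModel(cfg$network)
  if (is.null(cfg$true_fluxes))
    stop("config must provide 'true_fluxes' (named reaction -> value)")
  v <- unlist(cfg$true_fluxes)
  tracer <- tracerSpec(cfg$tracer_pool %||% stop("config must name 'tracer_pool'"),
                       cfg$tracer_purity)
  exp <- generateExperiment(model, v, tracer,
                            sigma = cfg$sigma %||% 0.01,
                            n_replicates = cfg$n_replicates %||% 3L,
                            seed = cfg$seed,
                            dir = cfg$out,
                            condition = cfg$condition %||% "synthetic")
  paths <- c(measurements = file.path(cfg$out, "measurements.csv"),
             metadata = file.path(cfg$out, "experiment.yaml"))
  out <- as.list(paths)
  attr(out, "experiment") <- exp
  invisible(out)
}
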