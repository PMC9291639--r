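# Scenario fixtures, run configuration, and results serialization.

#' Packaged scenario identifiers
#'
#' @return Character vector of scenario ids shipped with the package
#'   (the ten 3x5 toxicity scenarios, two 3x3 illustration scenarios, and
#'   three 2x4 Phase I/II scenarios).
#' @export
scenario_ids <- function() {
  sort(sub("\\.json$", "",
           list.files(system.file("extdata", package = "pobench"),
                      pattern = "\\.json$")))
}

#' Load a scenario fixture or scenario file
#'
#' @param id A packaged scenario id (see [scenario_ids()]) or a path to a
#'   JSON/YAML scenario file with fields `rows`, `cols`, `tox_probs`
#'   (row-major list of rows), optional `eff_params`, `gamma` or
#'   `phi`/`psi`, `targets` (list of 1-based (k, l) pairs), optional `n`,
#'   `label`, `eff_family`.
#' @return A [combo_scenario()].
#' @examples
#' sc <- load_scenario("table2_scenario1")
#' sc$gamma
#' @export
load_scenario <- function(id) {
  path <- if (file.exists(id)) {
    id
  } else {
    system.file("extdata", paste0(id, ".json"), package = "pobench")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("unknown scenario '%s'; see scenario_ids()", id),
         call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  as_grid_matrix <- function(x) {
    if (is.matrix(x)) {
      matrix(as.numeric(x), raw$rows, raw$cols)
    } else {
      # list of rows
      matrix(unlist(x), raw$rows, raw$cols, byrow = TRUE)
    }
  }
  tox <- as_grid_matrix(raw$tox_probs)
  eff <- if (!is.null(raw$eff_params)) as_grid_matrix(raw$eff_params)
  fam <- if (!is.null(raw$eff_family)) {
    do.call(endpoint_family, c(list(name = raw$eff_family$name),
                               raw$eff_family[names(raw$eff_family) != "name"]))
  } else {
    normal_family()
  }
  targets <- if (!is.null(raw$targets)) {
    if (is.matrix(raw$targets)) raw$targets else do.call(rbind, raw$targets)
  }
  combo_scenario(
    tox = tox, eff = eff,
    gamma = raw$gamma, phi = raw$phi, psi = raw$psi,
    targets = targets, n = raw$n,
    eff_family = fam,
    label = raw$label %||% sub("\\.(json|ya?ml)$", "", basename(path))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_defaults <- function() {
  list(
    scenario = NULL,
    mode = "po",          # po | original | multi
    n = NULL,             # falls back to the scenario's n
    Z = 10000,
    seed = 1,
    gamma = NULL,         # falls back to the scenario's gamma
    rho = 0,
    shared = FALSE,
    prior_mode = "distinct_values",
    criterion = "phase12_tradeoff",
    eta1 = 0.8,
    eta2 = 0.8,
    out = NULL
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills documented defaults, and
#' applies any overrides given as named arguments (overrides win over the
#' file). Unknown keys are rejected with a field-level message.
#'
#' @param file Optional path to a YAML/JSON config file.
#' @param ... Named overrides of config fields.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(file = NULL, ...) {
  cfg <- config_defaults()
  from_file <- if (!is.null(file)) {
    if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
    else jsonlite::fromJSON(file, simplifyVector = TRUE)
  } else {
    list()
  }
  overrides <- list(...)
  for (src in list(from_file, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown config field(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(src)] <- src
  }
  if (!cfg$mode %in% c("po", "original", "multi")) {
    stop("mode must be one of po, original, multi", call. = FALSE)
  }
  if (cfg$Z < 1) stop("Z must be >= 1", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run a benchmark from a configuration
#'
#' Dispatches to [run_po_benchmark()], [run_original_benchmark()] or
#' [run_po_benchmark_multi()] according to `config$mode`.
#'
#' @param config A [load_config()] result (or a named list of its fields).
#' @return A `po_benchmark_result`.
#' @export
run_from_config <- function(config) {
  scenario <- if (inherits(config$scenario, "combo_scenario")) {
    config$scenario
  } else {
    load_scenario(config$scenario)
  }
  n <- config$n %||% scenario$n
  gamma <- config$gamma %||% scenario$gamma
  switch(config$mode,
    po = run_po_benchmark(scenario, n = n, Z = config$Z, seed = config$seed,
                          gamma = gamma, prior_mode = config$prior_mode),
    original = run_original_benchmark(scenario, n = n, Z = config$Z,
                                      seed = config$seed, gamma = gamma),
    multi = run_po_benchmark_multi(scenario, n = n, Z = config$Z,
                                   seed = config$seed,
                                   criterion = config$criterion,
                                   shared = config$shared, rho = config$rho,
                                   prior_mode = config$prior_mode,
                                   eta1 = config$eta1, eta2 = config$eta2,
                                   gamma = gamma)
  )
}

#' Write benchmark results to disk
#'
#' Writes `PREFIX_proportions.csv` (the K x L selection-proportion grid in
#' percent plus the no-selection cell, one comment header line naming the
#' package version, seed and config hash) and `PREFIX_summary.json` (PCS to
#' one decimal and at full precision, all settings, and reproducibility
#' metadata; a rerun from the embedded settings reproduces the result).
#'
#' @param result A `po_benchmark_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "po_benchmark_result"))
  version <- as.character(utils::packageVersion("pobench"))
  settings <- c(result$settings,
                list(mode = result$mode, n = result$n, Z = result$Z,
                     seed = result$seed,
                     scenario = result$scenario$label))
  cfg_hash <- rlang::hash(settings)

  csv_path <- paste0(prefix, "_proportions.csv")
  json_path <- paste0(prefix, "_summary.json")

  K <- nrow(result$proportions)
  L <- ncol(result$proportions)
  df <- data.frame(
    k = rep(seq_len(K), each = L),
    l = rep(seq_len(L), times = K),
    proportion = as.vector(t(result$proportions))
  )
  df <- rbind(df, data.frame(k = NA, l = NA,
                             proportion = result$no_selection))
  df$percent <- round(100 * df$proportion, 1)
  con <- file(csv_path, "w")
  writeLines(sprintf("# pobench %s seed=%s config=%s",
                     version, result$seed, cfg_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)

  summary <- list(
    package = "pobench",
    version = version,
    config_hash = cfg_hash,
    settings = settings,
    pcs = if (is.na(result$pcs)) NULL else round(result$pcs, 1),
    pcs_full = if (is.na(result$pcs)) NULL else result$pcs,
    no_selection = result$no_selection,
    proportions = apply(result$proportions, 1, as.list, simplify = FALSE),
    targets = if (!is.null(result$targets)) {
      apply(result$targets, 1, as.list, simplify = FALSE)
    }
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' Read a proportions CSV back into a matrix
#'
#' @param path Path to a `*_proportions.csv` written by [write_results()].
#' @return A list with `proportions` (K x L matrix) and `no_selection`.
#' @export
read_proportions <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  grid_rows <- !is.na(df$k)
  K <- max(df$k, na.rm = TRUE)
  L <- max(df$l, na.rm = TRUE)
  m <- matrix(NA_real_, K, L)
  m[cbind(df$k[grid_rows], df$l[grid_rows])] <- df$proportion[grid_rows]
  list(proportions = m,
       no_selection = if (any(!grid_rows)) df$proportion[!grid_rows] else 0)
}
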