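## Config parsing (YAML primary, JSON accepted), strict validation, result
## serialization, run manifest.

RESULTS_SCHEMA <- c("outcome_type", "maf", "effect_size", "prevalence",
                    "baseline_or", "trait_sd", "n", "alpha", "target_power",
                    "reps", "arm", "power", "mc_se", "n_required",
                    "mean_effect", "shrinkage", "n_nonconverged", "seed")

CONFIG_SCALAR_KEYS <- c("n", "maf", "true_model", "analysis_model",
                        "outcome_type", "effect_size", "prevalence",
                        "baseline_or", "trait_sd", "trait_mean", "alpha",
                        "target_power", "reps", "seed")
CONFIG_GRID_KEYS <- c("maf_grid", "effect_grid")

#' Load a scenario configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file into one
#' [scenario_config()] or, when the file contains `maf_grid` and/or
#' `effect_grid`, into the cartesian grid of scenarios. Validation is
#' strict: unknown keys are rejected and every out-of-range value is
#' reported by field name — silently defaulting a field like `prevalence`
#' would corrupt comparisons.
#'
#' Required keys: `maf` (or `maf_grid`), `effect_size` (or `effect_grid`),
#' `outcome_type`. All other keys take the [scenario_config()] defaults.
#'
#' @param path path to the config file.
#' @return a `scenario_config`, or a list of them (class `scenario_grid`)
#'   for grid configs. Grid scenarios get counter-derived child seeds via
#'   [derive_seed()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  # keep YAML 1.1 boolean-like keys ("n", "y", ...) as literal strings
  keep_literal <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path, handlers = keep_literal),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format `.", ext, "`; use YAML or JSON",
         call. = FALSE)
  )
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("config must be a mapping of named fields", call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(CONFIG_SCALAR_KEYS, CONFIG_GRID_KEYS))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_grid <- any(CONFIG_GRID_KEYS %in% names(raw))
  if (!has_grid) {
    for (req in c("maf", "effect_size", "outcome_type")) {
      if (is.null(raw[[req]])) {
        stop("missing required config field: ", req, call. = FALSE)
      }
    }
    bad_len <- names(raw)[lengths(raw) != 1L]
    if (length(bad_len)) {
      stop("config field(s) must be scalars: ",
           paste(bad_len, collapse = ", "), call. = FALSE)
    }
    return(do.call(scenario_config, raw))
  }

  maf_grid <- if (!is.null(raw$maf_grid)) raw$maf_grid else raw$maf
  effect_grid <- if (!is.null(raw$effect_grid)) raw$effect_grid else {
    raw$effect_size
  }
  if (is.null(maf_grid)) {
    stop("missing required config field: maf (or maf_grid)", call. = FALSE)
  }
  if (is.null(effect_grid)) {
    stop("missing required config field: effect_size (or effect_grid)",
         call. = FALSE)
  }
  base <- raw[setdiff(names(raw), c(CONFIG_GRID_KEYS, "maf", "effect_size"))]
  cells <- expand.grid(maf = maf_grid, effect_size = effect_grid,
                       KEEP.OUT.ATTRS = FALSE)
  grid <- lapply(seq_len(nrow(cells)), function(i) {
    args <- c(list(maf = cells$maf[i], effect_size = cells$effect_size[i]),
              base)
    cfg <- do.call(scenario_config, args)
    scenario_modify(cfg, seed = derive_seed(cfg$seed, 3L, i))
  })
  structure(grid, class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("<scenario_grid> %d scenarios\n", length(x)))
  for (cfg in x) {
    cat(sprintf("  maf = %-7g effect_size = %-7g %s seed = %d\n",
                cfg$maf, cfg$effect_size, cfg$outcome_type,
                as.integer(cfg$seed)))
  }
  invisible(x)
}

#' Write a results table to CSV
#'
#' Enforces the fixed column order shared by all commands
#' (`r paste(RESULTS_SCHEMA, collapse = ", ")`), rounds numeric columns to 6
#' significant digits, and writes a plain CSV that round-trips losslessly at
#' that precision.
#'
#' @param rows a data.frame with exactly the schema columns (any order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(RESULTS_SCHEMA, names(rows))
  extra_cols <- setdiff(names(rows), RESULTS_SCHEMA)
  if (length(missing_cols) || length(extra_cols)) {
    stop("results table does not match the schema; missing: [",
         paste(missing_cols, collapse = ", "), "], unexpected: [",
         paste(extra_cols, collapse = ", "), "]", call. = FALSE)
  }
  out <- rows[, RESULTS_SCHEMA, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  status <- try(write.csv(out, path, row.names = FALSE, quote = FALSE),
                silent = TRUE)
  if (inherits(status, "try-error")) {
    stop("cannot write results to ", path, ": ",
         attr(status, "condition")$message, call. = FALSE)
  }
  invisible(path)
}

#' Read back a results CSV
#'
#' @param path path written by [write_results()].
#' @return a data.frame in the fixed schema.
#' @export
read_results <- function(path) {
  classes <- c(outcome_type = "character", arm = "character",
               n = "integer", reps = "integer", n_required = "integer",
               n_nonconverged = "integer", seed = "integer")
  numeric_cols <- setdiff(RESULTS_SCHEMA, names(classes))
  classes[numeric_cols] <- "numeric"
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = classes[RESULTS_SCHEMA])
  stopifnot(identical(names(out), RESULTS_SCHEMA))
  out
}

## FNV-1a (32-bit) over the canonical JSON of a config; good enough to
## fingerprint runs, not a cryptographic hash.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply without double-precision overflow
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' Build a run manifest
#'
#' A small provenance record for one CLI run: a deterministic hash of the
#' canonicalized config, the top-level seed, the package version, start and
#' finish timestamps, and every output file written.
#'
#' @param config a `scenario_config` (or the first scenario of a grid).
#' @param seed the top-level seed used.
#' @param outputs character vector of output file paths.
#' @param started,finished POSIXct timestamps.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, outputs, started, finished) {
  structure(list(
    config_hash = config_hash(config),
    seed = as.integer(seed),
    tool_version = as.character(packageVersion("snpmisspec")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.character(outputs)
  ), class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
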