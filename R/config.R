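.device_keys <- c("L_nm", "R_nm", "lambda_TF_nm", "eps_NW", "mu_m2Vs",
                  "p_m3", "doping", "t_ox_nm", "eps_ox", "t_linker_nm",
                  "lambda_D_nm", "eps_sol", "N_mol", "m_star", "T_K")

.run_keys <- c("task", "mode", "structure_pdb", "peptide_sequence",
               "peptide_geometry", "pH", "euler_deg", "pka_file",
               "charges_pqr", "charges", "sweep_parameter", "sweep_from",
               "sweep_to", "sweep_points", "ph_from", "ph_to", "ph_step",
               "fit_lambda_min", "fit_lambda_max", "fit_lambda_points",
               "out_dir", "seed")

#' Read and validate a run-configuration file
#'
#' The run configuration is a flat JSON object: device parameters under
#' their [device_params()] names (omitted keys get the defaults), plus the
#' run keys `task` (`"signal"`, `"ph_response"`, `"sweep"`, `"fit_height"`,
#' `"prepare"`), `mode` (`"multi_charge"`/`"single_charge"`), an analyte
#' source (`structure_pdb`, `peptide_sequence`, `charges_pqr`, or an
#' embedded `charges` site table — an embedded table wins over a structure,
#' with a warning), `pH`, `euler_deg` (length-3 Euler angles, degrees),
#' `pka_file`, task options (`sweep_parameter`, `sweep_from`, `sweep_to`,
#' `sweep_points`; `ph_from`, `ph_to`, `ph_step`; `fit_lambda_min`,
#' `fit_lambda_max`, `fit_lambda_points`), `out_dir` and `seed`. `N_mol`
#' may be the string `"auto"` to compute the coverage from the oriented
#' bounding box. Unknown keys and out-of-range values are rejected with the
#' offending key named. Relative file paths are resolved against the
#' config file's directory.
#'
#' @param path Path to a JSON run-configuration file.
#' @return A validated list of class `run_config`.
#' @seealso [run_config()], [write_run_config()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "nanofet_input_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (k in c("structure_pdb", "pka_file", "charges_pqr")) {
    v <- raw[[k]]
    if (!is.null(v) && !file.exists(v) && file.exists(file.path(base, v))) {
      raw[[k]] <- file.path(base, v)
    }
  }
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x Named list of configuration keys (see [read_run_config()]).
#' @return A validated `run_config`.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), c(.device_keys, .run_keys))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "nanofet_validation_error")
  }
  dev <- x[intersect(names(x), .device_keys)]
  auto_n <- identical(dev$N_mol, "auto")
  if (auto_n) dev$N_mol <- NULL
  params <- do.call(device_params, dev)

  cfg <- list(
    task = match_key(x$task %||% "signal",
                     c("signal", "ph_response", "sweep", "fit_height",
                       "prepare"), "task"),
    mode = match_key(x$mode %||% "multi_charge",
                     c("multi_charge", "single_charge"), "mode"),
    structure_pdb = x$structure_pdb,
    peptide_sequence = x$peptide_sequence,
    peptide_geometry = x$peptide_geometry %||% "extended",
    charges_pqr = x$charges_pqr,
    charges = x$charges,
    pH = as.numeric(x$pH %||% 7.4),
    euler_deg = as.numeric(x$euler_deg %||% c(0, 0, 0)),
    pka_file = x$pka_file,
    sweep_parameter = x$sweep_parameter %||% "lambda_D_nm",
    sweep_from = as.numeric(x$sweep_from %||% 0.5),
    sweep_to = as.numeric(x$sweep_to %||% 10),
    sweep_points = as.integer(x$sweep_points %||% 20L),
    ph_from = as.numeric(x$ph_from %||% 0),
    ph_to = as.numeric(x$ph_to %||% 14),
    ph_step = as.numeric(x$ph_step %||% 0.1),
    fit_lambda_min = as.numeric(x$fit_lambda_min %||% 1),
    fit_lambda_max = as.numeric(x$fit_lambda_max %||% 10),
    fit_lambda_points = as.integer(x$fit_lambda_points %||% 10L),
    out_dir = x$out_dir,
    seed = as.integer(x$seed %||% 1L),
    N_mol_auto = auto_n,
    params = params
  )
  if (length(cfg$euler_deg) != 3L || any(!is.finite(cfg$euler_deg))) {
    abort("config key 'euler_deg' must be 3 finite angles in degrees",
          class = "nanofet_validation_error")
  }
  if (!is.finite(cfg$pH) || cfg$pH < 0 || cfg$pH > 14) {
    abort("config key 'pH' must lie in [0, 14]",
          class = "nanofet_validation_error")
  }
  has_src <- !is.null(cfg$charges) || !is.null(cfg$charges_pqr) ||
    !is.null(cfg$structure_pdb) || !is.null(cfg$peptide_sequence)
  if (!has_src) {
    abort(paste("config needs an analyte source: one of 'charges',",
                "'charges_pqr', 'structure_pdb', 'peptide_sequence'"),
          class = "nanofet_validation_error")
  }
  structure(cfg, class = "run_config")
}

match_key <- function(value, choices, key) {
  if (!is.character(value) || length(value) != 1L || !value %in% choices) {
    abort(paste0("config key '", key, "' must be one of: ",
                 paste(choices, collapse = ", ")),
          class = "nanofet_validation_error")
  }
  value
}

#' Serialize a run configuration to JSON
#'
#' Writes the effective configuration (all defaults filled in) so that the
#' file reproduces the run exactly; `read_run_config()` of the written file
#' round-trips to the same configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg[setdiff(names(cfg), c("params", "N_mol_auto"))]
  out <- out[!vapply(out, is.null, TRUE)]
  dev <- unclass(cfg$params)
  if (cfg$N_mol_auto) dev$N_mol <- "auto"
  out <- c(out, dev)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

resolve_analyte <- function(cfg, log) {
  str <- NULL
  if (!is.null(cfg$structure_pdb)) {
    str <- read_structure(cfg$structure_pdb)
    log("structure", paste0("pdb=", cfg$structure_pdb,
                            " atoms=", nrow(str)))
  } else if (!is.null(cfg$peptide_sequence)) {
    str <- build_peptide(cfg$peptide_sequence, cfg$peptide_geometry)
    log("structure", paste0("peptide=", cfg$peptide_sequence,
                            " geometry=", cfg$peptide_geometry))
  }
  if (!is.null(cfg$charges)) {
    if (!is.null(str) || !is.null(cfg$charges_pqr)) {
      warn("embedded 'charges' override the other analyte sources")
    }
    dist <- make_point_charges(as_tibble(cfg$charges))
    log("charges", paste0("embedded sites=", nrow(dist)))
    return(list(dist = dist, str = NULL))
  }
  if (!is.null(cfg$charges_pqr)) {
    dist <- read_pqr(cfg$charges_pqr)
    log("charges", paste0("pqr=", cfg$charges_pqr, " sites=", nrow(dist)))
    return(list(dist = dist, str = NULL))
  }
  site_pka <- if (!is.null(cfg$pka_file)) read_pka_file(cfg$pka_file)
  dist <- assign_charges(str, pH = cfg$pH, site_pka = site_pka)
  dist <- align_principal(dist)
  dist <- orient(dist, euler_deg = cfg$euler_deg)
  log("charges", paste0("sites=", nrow(dist),
                        " net_charge=", format(net_charge(dist))))
  list(dist = dist, str = str)
}

#' Execute a run configuration
#'
#' Runs the full pipeline for a configuration — analyte preparation
#' (structure, protonation, alignment, orientation), distance profile,
#' coverage, and the requested task — and writes the results, a PQR charge
#' file, a structured log and a config snapshot into the output directory.
#' Identical configurations produce byte-identical result files.
#'
#' Output files by task: `signal` writes `site_contributions.csv` and
#' `summary.txt`; `ph_response` writes `ph_response.csv` (columns `pH`,
#' `sensitivity`, `net_charge_e`); `sweep` writes `sweep.csv`
#' (`param_value`, `sensitivity`); `fit_height` writes
#' `relative_sensitivity.csv` (`lambda_D_nm`, `relative_sensitivity`) and
#' `height_fit.json`; `prepare` writes only the charge files. Every run
#' also writes `charges.pqr`, `run.log` and `config_snapshot.json`.
#'
#' @param cfg A `run_config` (or path to a config file).
#' @param out_dir Output directory; defaults to the config's `out_dir` or
#'   a temporary directory.
#' @return Invisibly, a list with `result` (the task's main object),
#'   `files` (paths written) and `config`.
#' @export
run_config <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("nanofet_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  log_lines <- character()
  log <- function(stage, msg) {
    log_lines[[length(log_lines) + 1L]] <<- paste0("stage=", stage, " ", msg)
  }
  log("init", paste0("task=", cfg$task, " mode=", cfg$mode,
                     " seed=", cfg$seed))

  src <- resolve_analyte(cfg, log)
  dist <- src$dist
  if (cfg$mode == "single_charge" && nrow(dist) > 1L) {
    dist <- single_charge(dist)
    log("mode", "single_charge collapse applied")
  }
  params <- cfg$params
  if (cfg$N_mol_auto) {
    params$N_mol <- coverage(dist, params)
    log("coverage", paste0("N_mol=", params$N_mol, " (auto)"))
  } else {
    log("coverage", paste0("N_mol=", params$N_mol, " (manual)"))
  }
  prof <- distance_profile(dist, t_linker_nm = params$t_linker_nm,
                           t_ox_nm = params$t_ox_nm)
  log("geometry", paste0("z_min_nm=", format(attr(prof, "z_min_nm"))))

  files <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    files[[length(files) + 1L]] <<- p
    p
  }
  write_pqr(dist, emit("charges.pqr"))

  result <- switch(
    cfg$task,
    prepare = {
      readr::write_csv(as_tibble(dist), emit("sites.csv"))
      dist
    },
    signal = {
      res <- nw_sensitivity(prof, params)
      readr::write_csv(tidy(res), emit("site_contributions.csv"))
      writeLines(sprintf("sensitivity=%.10g G0_S=%.10g dG_S=%.10g N_mol=%d",
                         res$sensitivity, res$G0_S, res$dG_S,
                         as.integer(params$N_mol)),
                 emit("summary.txt"))
      log("signal", sprintf("sensitivity=%.10g G0_S=%.10g",
                            res$sensitivity, res$G0_S))
      res
    },
    ph_response = {
      if (is.null(src$str)) {
        abort("task 'ph_response' needs a structure-based analyte",
              class = "nanofet_input_error")
      }
      # titration needs the oriented structure, not the raw one
      ostr <- attr(dist, "structure")
      site_pka <- if (!is.null(cfg$pka_file)) read_pka_file(cfg$pka_file)
      grid <- seq(cfg$ph_from, cfg$ph_to, by = cfg$ph_step)
      curve <- ph_response(ostr, params, pH = grid, site_pka = site_pka,
                           mode = if (cfg$mode == "single_charge") "single"
                                  else "multi")
      readr::write_csv(as_tibble(curve), emit("ph_response.csv"))
      log("ph_response", paste0("points=", nrow(curve)))
      curve
    },
    sweep = {
      grid <- seq(cfg$sweep_from, cfg$sweep_to,
                  length.out = cfg$sweep_points)
      sw <- sweep_sensitivity(prof, params, cfg$sweep_parameter, grid)
      readr::write_csv(as_tibble(sw), emit("sweep.csv"))
      log("sweep", paste0("parameter=", cfg$sweep_parameter,
                          " points=", nrow(sw)))
      sw
    },
    fit_height = {
      grid <- seq(cfg$fit_lambda_min, cfg$fit_lambda_max,
                  length.out = cfg$fit_lambda_points)
      ser <- relative_sensitivity(prof, params, grid)
      readr::write_csv(ser, emit("relative_sensitivity.csv"))
      fit <- fit_average_height(ser, params)
      jsonlite::write_json(list(l_nm = fit$l_nm, amplitude = fit$amplitude,
                                rss = fit$rss),
                           emit("height_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      log("fit_height", sprintf("l_nm=%.6g rss=%.3g", fit$l_nm, fit$rss))
      fit
    }
  )

  write_run_config(cfg, emit("config_snapshot.json"))
  writeLines(log_lines, emit("run.log"))
  invisible(list(result = result, files = unlist(files), config = cfg))
}
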