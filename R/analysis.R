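.sweepable <- c("L_nm", "R_nm", "lambda_TF_nm", "eps_NW", "mu_m2Vs", "p_m3",
                "t_ox_nm", "eps_ox", "t_linker_nm", "lambda_D_nm", "eps_sol",
                "N_mol", "m_star", "T_K")

#' Sensitivity as a function of one device parameter
#'
#' Recomputes the sensitivity over a grid of values of a single device
#' parameter, all other parameters held fixed. Parameters are swept
#' independently: in particular `lambda_TF_nm` and `p_m3` are not
#' re-coupled through [tf_length()] during a sweep.
#'
#' @param profile A [distance_profile()].
#' @param params Baseline [device_params()].
#' @param parameter Name of the parameter to sweep (any numeric field of
#'   `device_params`).
#' @param values Strictly increasing numeric grid.
#' @return A tibble of class `nw_sweep` with columns `param_value` and
#'   `sensitivity`; the parameter name and the fixed-parameter snapshot are
#'   kept as attributes.
#' @examples
#' prof <- distance_profile(
#'   make_point_charges(data.frame(x_nm = 0, y_nm = 0, z_nm = 0, charge = -1)))
#' sweep_sensitivity(prof, device_params(), "lambda_D_nm", c(0.5, 1, 2, 5, 10))
#' @export
sweep_sensitivity <- function(profile, params, parameter, values) {
  if (!parameter %in% .sweepable) {
    abort(paste0("unknown sweep parameter '", parameter, "'"),
          class = "nanofet_input_error")
  }
  if (length(values) < 1L || is.unsorted(values, strictly = TRUE)) {
    abort("`values` must be strictly increasing",
          class = "nanofet_input_error")
  }
  sens <- purrr::map_dbl(values, function(v) {
    p <- params
    p[[parameter]] <- v
    validate_device_params(p)
    nw_sensitivity(profile, p)$sensitivity
  })
  out <- tibble(param_value = as.numeric(values), sensitivity = sens)
  structure(out, parameter = parameter, params = params,
            class = c("nw_sweep", class(out)))
}

#' Sensitivity as a function of pH
#'
#' Re-titrates the charge distribution of a structure at each pH of the
#' grid (geometry fixed: the structure is used in its current orientation)
#' and evaluates the sensitivity. In `"single"` mode the net charge is
#' placed at the bounding-box center, so the signal crosses zero with the
#' net charge at the isoelectric point.
#'
#' @param str An `nw_structure`, already aligned/oriented as desired.
#' @param params [device_params()].
#' @param pH Numeric grid in `[0, 14]` (default 0-14 in steps of 0.1).
#' @param pka_table,site_pka Passed to [assign_charges()].
#' @param mode `"multi"` (discrete charges, default) or `"single"`.
#' @return A tibble of class `nw_ph_response` with columns `pH`,
#'   `sensitivity`, `net_charge_e`.
#' @export
ph_response <- function(str, params = device_params(),
                        pH = seq(0, 14, by = 0.1),
                        pka_table = default_pka_table(), site_pka = NULL,
                        mode = c("multi", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(str, "nw_structure"))
  if (any(pH < 0 | pH > 14)) {
    abort("pH grid must lie in [0, 14]", class = "nanofet_input_error")
  }
  rows <- purrr::map(pH, function(p) {
    dist <- assign_charges(str, pH = p, pka_table = pka_table,
                           site_pka = site_pka)
    if (mode == "single") dist <- single_charge(dist)
    prof <- distance_profile(dist, t_linker_nm = params$t_linker_nm,
                             t_ox_nm = params$t_ox_nm)
    tibble(pH = p,
           sensitivity = nw_sensitivity(prof, params)$sensitivity,
           net_charge_e = net_charge(dist))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, params = params, mode = mode,
            class = c("nw_ph_response", class(out)))
}

#' Relative sensitivity versus Debye length
#'
#' Computes the sensitivity of a fixed charge distribution over a grid of
#' Debye lengths and normalizes the series by its value at the largest
#' Debye length of the grid. This is the quantity whose shape encodes the
#' average charge height and that [fit_average_height()] fits.
#'
#' @param profile A [distance_profile()].
#' @param params [device_params()].
#' @param lambda_D_nm Strictly increasing grid of Debye lengths (nm).
#' @return Tibble with columns `lambda_D_nm` and `relative_sensitivity`
#'   (equal to 1 at the largest grid value).
#' @export
relative_sensitivity <- function(profile, params = device_params(),
                                 lambda_D_nm = seq(1, 10, by = 1)) {
  sw <- sweep_sensitivity(profile, params, "lambda_D_nm", lambda_D_nm)
  ref <- sw$sensitivity[which.max(sw$param_value)]
  if (!is.finite(ref) || ref == 0) {
    abort("reference sensitivity is zero; relative series undefined",
          class = "nanofet_domain_error")
  }
  tibble(lambda_D_nm = sw$param_value,
         relative_sensitivity = sw$sensitivity / ref)
}

#' Fit the average charge height from a Debye-length series
#'
#' Least-squares fit of a single effective charge height `<l>` to a
#' relative-sensitivity-versus-Debye-length series: the model curve is the
#' per-charge response of one charge at height `l`, normalized at the
#' largest Debye length of the grid, with a free global amplitude. The
#' amplitude is solved in closed form for each candidate height and the
#' height itself by bounded one-dimensional minimization seeded from a
#' grid (1-30 nm in 0.5 nm steps) to avoid local minima; the fit is
#' deterministic.
#'
#' @param series Data frame with columns `lambda_D_nm` and
#'   `relative_sensitivity` (at least 3 points), e.g. from
#'   [relative_sensitivity()].
#' @param params [device_params()] describing the device the series was
#'   computed (or measured) on.
#' @param l_range Search bounds for the height (nm).
#' @return An object of class `height_fit`: list with `l_nm` (the fitted
#'   average height), `amplitude`, `rss`, and `series` (input plus a
#'   `fitted` column). Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' prof <- distance_profile(
#'   make_point_charges(data.frame(x_nm = 0, y_nm = 0, z_nm = 3, charge = -1)),
#'   t_linker_nm = 1, t_ox_nm = 2)
#' ser <- relative_sensitivity(prof, device_params())
#' fit_average_height(ser, device_params())
#' @export
fit_average_height <- function(series, params = device_params(),
                               l_range = c(0.05, 40)) {
  series <- as_tibble(series)
  if (!all(c("lambda_D_nm", "relative_sensitivity") %in% names(series))) {
    abort("`series` needs columns lambda_D_nm and relative_sensitivity",
          class = "nanofet_input_error")
  }
  if (nrow(series) < 3L) {
    abort("need at least 3 (lambda_D, value) points",
          class = "nanofet_input_error")
  }
  y <- series$relative_sensitivity
  if (stats::sd(y) < 1e-12) {
    abort("series is flat; the height is not identifiable",
          class = "nanofet_fit_error")
  }
  lam <- series$lambda_D_nm
  lam_ref <- max(lam)

  model_curve <- function(l) {
    w <- vapply(lam, function(ld) {
      p <- params
      p$lambda_D_nm <- ld
      charge_response(l, p)
    }, 0)
    w / w[which.max(lam)]
  }
  objective <- function(l) {
    m <- model_curve(l)
    amp <- sum(m * y) / sum(m * m)
    sum((amp * m - y)^2)
  }
  seeds <- seq(max(l_range[1], 0.5), min(30, l_range[2]), by = 0.5)
  rss_seed <- vapply(seeds, objective, 0)
  best <- seeds[which.min(rss_seed)]
  lo <- max(l_range[1], best - 0.5)
  hi <- min(l_range[2], best + 0.5)
  opt <- optimize(objective, lower = lo, upper = hi, tol = 1e-8)
  l_hat <- opt$minimum
  m <- model_curve(l_hat)
  amp <- sum(m * y) / sum(m * m)
  series$fitted <- amp * m
  structure(list(l_nm = l_hat, amplitude = amp, rss = opt$objective,
                 lambda_ref_nm = lam_ref, series = series, params = params),
            class = "height_fit")
}

#' @export
print.height_fit <- function(x, ...) {
  cat(sprintf("<height_fit>  <l> = %.3f nm  (amplitude %.4f, rss %.3g, %d points)\n",
              x$l_nm, x$amplitude, x$rss, nrow(x$series)))
  invisible(x)
}
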