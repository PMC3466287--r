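#' Nanowire device and buffer parameters
#'
#' Collects every parameter of the sensitivity model with its default
#' value: wire geometry and electronic structure, oxide shell, biolinker,
#' electrolyte, and analyte coverage. Any subset can be overridden by
#' name. Note that `lambda_TF_nm` and `p_m3` are physically coupled
#' through [tf_length()] but are stored (and swept) independently, so
#' that either can be used to emulate gating; the defaults are mutually
#' consistent for `m_star = 0.37` hole masses.
#'
#' @param L_nm Wire length (nm).
#' @param R_nm Wire radius (nm).
#' @param lambda_TF_nm Thomas-Fermi screening length inside the wire (nm).
#' @param eps_NW Relative permittivity of the wire material.
#' @param mu_m2Vs Carrier mobility (m^2 V^-1 s^-1).
#' @param p_m3 Majority-carrier density (m^-3).
#' @param doping `"p"` (holes) or `"n"` (electrons).
#' @param t_ox_nm Oxide layer thickness (nm).
#' @param eps_ox Oxide relative permittivity.
#' @param t_linker_nm Biolinker layer thickness (nm).
#' @param lambda_D_nm Debye screening length of the electrolyte (nm).
#'   Supplied directly (it may differ from the bulk-buffer value because of
#'   the functionalization layer); [debye_length()] converts a buffer
#'   composition when needed.
#' @param eps_sol Solvent relative permittivity.
#' @param N_mol Number of analyte molecules on the wire (manual value;
#'   [coverage()] computes it from the bounding box instead).
#' @param m_star Carrier effective mass in electron masses (enters only
#'   the `lambda_TF_nm` / `p_m3` conversion).
#' @param T_K Temperature (K).
#' @return A validated named list of class `device_params`.
#' @examples
#' device_params(lambda_D_nm = 9.6)
#' @export
device_params <- function(L_nm = 2000, R_nm = 10, lambda_TF_nm = 2.04,
                          eps_NW = 12.0, mu_m2Vs = 1e-2, p_m3 = 1.11e24,
                          doping = c("p", "n"), t_ox_nm = 2.0, eps_ox = 3.9,
                          t_linker_nm = 1.0, lambda_D_nm = 2.0, eps_sol = 78,
                          N_mol = 4000, m_star = 0.37, T_K = 298.15) {
  doping <- match.arg(doping)
  params <- list(L_nm = L_nm, R_nm = R_nm, lambda_TF_nm = lambda_TF_nm,
                 eps_NW = eps_NW, mu_m2Vs = mu_m2Vs, p_m3 = p_m3,
                 doping = doping, t_ox_nm = t_ox_nm, eps_ox = eps_ox,
                 t_linker_nm = t_linker_nm, lambda_D_nm = lambda_D_nm,
                 eps_sol = eps_sol, N_mol = N_mol, m_star = m_star,
                 T_K = T_K)
  validate_device_params(params)
  structure(params, class = "device_params")
}

validate_device_params <- function(params) {
  pos <- c("L_nm", "R_nm", "lambda_TF_nm", "mu_m2Vs", "p_m3",
           "lambda_D_nm", "N_mol", "m_star", "T_K")
  for (k in pos) {
    v <- params[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("device parameter '", k, "' must be a positive number"),
            class = "nanofet_validation_error")
    }
  }
  for (k in c("t_ox_nm", "t_linker_nm")) {
    v <- params[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(paste0("device parameter '", k, "' must be non-negative"),
            class = "nanofet_validation_error")
    }
  }
  for (k in c("eps_NW", "eps_ox", "eps_sol")) {
    v <- params[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1) {
      abort(paste0("device parameter '", k, "' must be >= 1"),
            class = "nanofet_validation_error")
    }
  }
  if (!params$doping %in% c("p", "n")) {
    abort("device parameter 'doping' must be \"p\" or \"n\"",
          class = "nanofet_validation_error")
  }
  invisible(params)
}

#' @export
print.device_params <- function(x, ...) {
  cat("<device_params>\n")
  for (k in names(x)) cat(sprintf("  %-13s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Ionic strength of a buffer
#'
#' \eqn{I = \frac{1}{2} \sum_i c_i z_i^2} over the ion species.
#'
#' @param ions Data frame with columns `conc_mol_m3` (concentration,
#'   mol/m^3; 1 mol/m^3 = 1 mM) and `z` (integer formal charge).
#' @return Ionic strength in mol/m^3. Zero (with a warning) for an empty
#'   species list, in which case no Debye length is defined.
#' @examples
#' ionic_strength(data.frame(conc_mol_m3 = c(1, 1), z = c(1, -1)))  # 1 mM NaCl
#' @export
ionic_strength <- function(ions) {
  ions <- as_tibble(ions)
  if (!all(c("conc_mol_m3", "z") %in% names(ions))) {
    abort("`ions` needs columns conc_mol_m3 and z",
          class = "nanofet_input_error")
  }
  if (nrow(ions) == 0L) {
    warn("empty ion list: ionic strength 0, Debye length undefined")
    return(0)
  }
  if (any(ions$conc_mol_m3 < 0)) {
    abort("concentrations must be non-negative", class = "nanofet_input_error")
  }
  0.5 * sum(ions$conc_mol_m3 * ions$z^2)
}

#' Debye screening length of an electrolyte
#'
#' \eqn{\lambda_D = \sqrt{\varepsilon_0 \varepsilon_{sol} k_B T /
#' (2 N_A e^2 I)}} with the ionic strength `I` in mol/m^3.
#'
#' @param ions Either a numeric ionic strength (mol/m^3) or an ion table
#'   for [ionic_strength()].
#' @param eps_sol Solvent relative permittivity.
#' @param T_K Temperature (K).
#' @return Debye length in nm.
#' @examples
#' debye_length(1)    # 1 mM 1:1 salt, ~9.6 nm
#' debye_length(100)  # 100 mM, ~0.96 nm
#' @export
debye_length <- function(ions, eps_sol = 78, T_K = 298.15) {
  I <- if (is.numeric(ions) && length(ions) == 1L) ions else ionic_strength(ions)
  if (!is.finite(I) || I <= 0) {
    abort("ionic strength must be positive to define a Debye length",
          class = "nanofet_domain_error")
  }
  cc <- .const
  lam <- sqrt(cc$eps_0 * eps_sol * cc$k_B * T_K / (2 * cc$N_A * cc$e^2 * I))
  lam * 1e9
}

#' Thomas-Fermi screening length from the carrier density
#'
#' Screening length of the degenerate carrier gas in the wire,
#' \eqn{\lambda_{TF} = \sqrt{\varepsilon_0 \varepsilon_{NW} \pi^2 \hbar^2 /
#' (e^2 m^* (3 \pi^2 p)^{1/3})}}, so \eqn{\lambda_{TF} \propto p^{-1/6}}.
#' [carrier_density()] is the exact algebraic inverse. With the default
#' effective mass of 0.37 electron masses (silicon hole conductivity mass)
#' the default density 1.11e24 m^-3 maps to the default screening length
#' of about 2.04 nm.
#'
#' @param p_m3 Carrier density (m^-3).
#' @param eps_NW Wire relative permittivity.
#' @param m_star Carrier effective mass in electron masses.
#' @return Screening length in nm.
#' @examples
#' tf_length(1.11e24, 12.0, 0.37)
#' @export
tf_length <- function(p_m3, eps_NW = 12.0, m_star = 0.37) {
  if (any(!is.finite(p_m3)) || any(p_m3 <= 0)) {
    abort("carrier density must be positive", class = "nanofet_domain_error")
  }
  cc <- .const
  lam2 <- cc$eps_0 * eps_NW * pi^2 * cc$hbar^2 /
    (cc$e^2 * m_star * cc$m_e * (3 * pi^2 * p_m3)^(1 / 3))
  sqrt(lam2) * 1e9
}

#' @rdname tf_length
#' @param lambda_TF_nm Thomas-Fermi screening length (nm).
#' @return `carrier_density()`: carrier density in m^-3.
#' @export
carrier_density <- function(lambda_TF_nm, eps_NW = 12.0, m_star = 0.37) {
  if (any(!is.finite(lambda_TF_nm)) || any(lambda_TF_nm <= 0)) {
    abort("screening length must be positive", class = "nanofet_domain_error")
  }
  cc <- .const
  lam2 <- (lambda_TF_nm * 1e-9)^2
  k <- cc$eps_0 * eps_NW * pi^2 * cc$hbar^2 / (cc$e^2 * m_star * cc$m_e * lam2)
  k^3 / (3 * pi^2)
}

# log of K0 via the exponentially scaled Bessel function (stable for
# large arguments, where K0 itself underflows)
log_k0 <- function(z) {
  log(besselK(z, 0, expon.scaled = TRUE)) - z
}

#' Electrolyte screening factor of a discrete charge
#'
#' Attenuation applied to a charge at total distance `l` from the wire
#' surface, from the cylindrical screened-Poisson solution:
#' \eqn{\Gamma(l) = \frac{(R + l) K_0((R + l)/\lambda_D)}
#' {R K_0(R/\lambda_D)}}, normalized to 1 at the wire surface. It decays
#' essentially as \eqn{e^{-l/\lambda_D}} (times a slowly varying
#' cylindrical correction) and lies in \eqn{[0, 1]} throughout the
#' physical parameter range of the device (it is monotone decreasing in
#' `l` whenever \eqn{R/\lambda_D \gtrsim 0.42}, which holds for any
#' realistic wire/buffer combination).
#'
#' @param l_nm Distance(s) from the nanowire surface in nm (vectorized,
#'   must be non-negative). This is the total distance of [distance_profile()],
#'   i.e. it includes the oxide and linker thicknesses.
#' @param params [device_params()] (uses `R_nm` and `lambda_D_nm`).
#' @return Values in `[0, 1]`.
#' @examples
#' screening_factor(c(0, 3, 10), device_params())
#' @export
screening_factor <- function(l_nm, params = device_params()) {
  if (any(!is.finite(l_nm)) || any(l_nm < 0)) {
    abort("distances must be finite and non-negative",
          class = "nanofet_domain_error")
  }
  R <- params$R_nm
  lam <- params$lambda_D_nm
  rc <- R + l_nm
  exp(log(rc / R) + log_k0(rc / lam) - log_k0(R / lam))
}

#' Dimensionless response functions of the wire
#'
#' The two dimensionless factors that multiply the screening factor in the
#' sensitivity expression; they arise from the solution of the Poisson
#' equation in cylindrical coordinates for the three-layer device
#' (Thomas-Fermi wire, unscreened oxide shell, Debye electrolyte):
#' * `wire`: the response of the carrier gas, depending on both
#'   `lambda_TF_nm` and `lambda_D_nm` (and the geometry/permittivities);
#' * `electrolyte`: the interface factor
#'   \eqn{K_0(a/\lambda_D)/K_1(a/\lambda_D)} at the outer oxide radius
#'   \eqn{a = R + t_{ox}}, depending only on `lambda_D_nm`.
#'
#' Their product times [screening_factor()] gives the full per-charge
#' response; the factorization itself is a convention.
#'
#' @param params [device_params()].
#' @return Named list with elements `wire` and `electrolyte`.
#' @export
poisson_factors <- function(params = device_params()) {
  R <- params$R_nm
  a <- R + params$t_ox_nm
  lTF <- params$lambda_TF_nm
  lD <- params$lambda_D_nm
  x <- R / lTF
  # I1/I0 ratio via scaled Bessels: stable for any x
  t_ratio <- besselI(x, 1, expon.scaled = TRUE) /
    besselI(x, 0, expon.scaled = TRUE)
  k0a_s <- besselK(a / lD, 0, expon.scaled = TRUE)
  k1a_s <- besselK(a / lD, 1, expon.scaled = TRUE)
  electrolyte <- k0a_s / k1a_s
  # K0(R/lD)/K0(a/lD) with the exponential restored (a >= R)
  k_Ra <- besselK(R / lD, 0, expon.scaled = TRUE) / k0a_s *
    exp((a - R) / lD)
  denom <- 1 +
    (params$eps_NW * R * log(a / R) / (params$eps_ox * lTF)) * t_ratio +
    (params$eps_NW * lD / (params$eps_sol * lTF)) * t_ratio *
      (R / a) * electrolyte
  wire <- (params$eps_NW * lD / (params$eps_sol * lTF)) * t_ratio *
    (R / a) * k_Ra / denom
  list(wire = wire, electrolyte = electrolyte)
}

# full dimensionless per-charge response: Gamma(l) * wire * electrolyte
charge_response <- function(l_nm, params) {
  f <- poisson_factors(params)
  screening_factor(l_nm, params) * f$wire * f$electrolyte
}

#' Base conductance of the nanowire
#'
#' Drude conductance of the unperturbed wire,
#' \eqn{G_0 = e \, p \, \mu \, \pi R^2 / L}.
#'
#' @param params [device_params()].
#' @return Conductance in siemens.
#' @examples
#' base_conductance(device_params())  # ~2.8e-7 S
#' @export
base_conductance <- function(params = device_params()) {
  cc <- .const
  cc$e * params$p_m3 * params$mu_m2Vs * pi * (params$R_nm * 1e-9)^2 /
    (params$L_nm * 1e-9)
}

#' Sensitivity of the nanowire to a bound charge distribution
#'
#' Evaluates the relative conductance change
#' \deqn{\Delta G / G_0 = \mp \frac{2}{e \, p \, R} \sum_j \sigma_j
#'   \Gamma(l_j) \, F_{wire} F_{electrolyte},}
#' upper sign for p-type (a negative analyte accumulates holes and raises
#' the conductance; n-type flips the sign). Each discrete charge
#' contributes the surface density \eqn{\sigma_j = N_{mol} q_j e /
#' A_{wire}} with \eqn{A_{wire} = 2\pi (R + t_{ox}) L}, so the sum is
#' linear in the charges and consistent with total-charge normalization.
#' Distances `l_j` are re-derived from the profile's offsets plus the
#' current `t_linker_nm`/`t_ox_nm` of `params`, so sweeping the spacer
#' thicknesses moves the charges with them.
#'
#' @param profile A [distance_profile()] (charge distribution with
#'   `dz_nm`).
#' @param params [device_params()]; `N_mol` is taken from here (see
#'   [coverage()]).
#' @return An object of class `nw_sensitivity`: list with `sensitivity`
#'   (\eqn{\Delta G/G_0}), `dG_S`, `G0_S`, `N_mol`, and `sites`, a tibble
#'   with the per-site breakdown (`site`, `charge`, `l_nm`, `gamma`,
#'   `contribution`; contributions sum to the sensitivity). Supports
#'   [tidy()], [glance()] and `print()`.
#' @examples
#' prof <- distance_profile(
#'   make_point_charges(data.frame(x_nm = 0, y_nm = 0, z_nm = 0, charge = -1)))
#' nw_sensitivity(prof, device_params())
#' @export
nw_sensitivity <- function(profile, params = device_params()) {
  stopifnot(inherits(profile, "charge_distribution"))
  if (!"dz_nm" %in% names(profile)) {
    abort("`profile` must come from distance_profile()",
          class = "nanofet_input_error")
  }
  validate_device_params(params)
  l_nm <- profile$dz_nm + params$t_linker_nm + params$t_ox_nm
  sgn <- if (params$doping == "p") +1 else -1
  a_wire_m2 <- 2 * pi * (params$R_nm + params$t_ox_nm) * 1e-9 *
    params$L_nm * 1e-9
  w <- if (nrow(profile) > 0L) charge_response(l_nm, params) else numeric()
  prefac <- sgn * 2 * params$N_mol /
    (params$p_m3 * (params$R_nm * 1e-9) * a_wire_m2)
  contrib <- -prefac * profile$charge * w
  sens <- sum(contrib)
  g0 <- base_conductance(params)
  structure(list(
    sensitivity = sens,
    dG_S = sens * g0,
    G0_S = g0,
    N_mol = params$N_mol,
    sites = tibble(site = profile$site, class = profile$class,
                   charge = profile$charge, l_nm = l_nm,
                   gamma = if (length(w)) screening_factor(l_nm, params)
                           else numeric(),
                   contribution = contrib),
    params = params
  ), class = "nw_sensitivity")
}

#' @export
print.nw_sensitivity <- function(x, ...) {
  cat(sprintf("<nw_sensitivity>  dG/G0 = %.6g  (G0 = %.4g S, dG = %.4g S)\n",
              x$sensitivity, x$G0_S, x$dG_S))
  cat(sprintf("  %d site(s), N_mol = %s, %s-type wire\n",
              nrow(x$sites), format(x$N_mol), x$params$doping))
  invisible(x)
}
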