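#' Tidy a sensitivity result
#'
#' @param x An `nw_sensitivity` object.
#' @param ... Unused.
#' @return The per-site breakdown as a tibble: `site`, `class`, `charge`,
#'   `l_nm`, `gamma`, `contribution` (contributions sum to the
#'   sensitivity).
#' @method tidy nw_sensitivity
#' @export
tidy.nw_sensitivity <- function(x, ...) {
  x$sites
}

#' One-row summary of a sensitivity result
#'
#' @param x An `nw_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with `sensitivity`, `dG_S`, `G0_S`, `N_mol`,
#'   `n_sites`, `net_charge_e`.
#' @method glance nw_sensitivity
#' @export
glance.nw_sensitivity <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, dG_S = x$dG_S, G0_S = x$G0_S,
         N_mol = x$N_mol, n_sites = nrow(x$sites),
         net_charge_e = sum(x$sites$charge))
}

#' Tidy an average-height fit
#'
#' @param x A `height_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per fitted term (`l_nm`, `amplitude`).
#' @method tidy height_fit
#' @export
tidy.height_fit <- function(x, ...) {
  tibble(term = c("l_nm", "amplitude"),
         estimate = c(x$l_nm, x$amplitude))
}

#' One-row summary of an average-height fit
#'
#' @param x A `height_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `l_nm`, `rss`, `n`, `lambda_ref_nm`.
#' @method glance height_fit
#' @export
glance.height_fit <- function(x, ...) {
  tibble(l_nm = x$l_nm, rss = x$rss, n = nrow(x$series),
         lambda_ref_nm = x$lambda_ref_nm)
}
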