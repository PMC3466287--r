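# Independent numerical oracle for the cylindrical screened-Poisson
# problem: conservative finite differences on the radial equation
#   d/dr ( r eps(r) phi'(r) ) - r q(r) phi(r) = -r S(r)
# with Thomas-Fermi screening inside the wire (r < R), no screening in the
# oxide shell (R < r < R + t_ox), Debye screening in the electrolyte, and
# a unit sheet source at r_c = R + l. Returns the dimensionless per-charge
# response (the quantity the analytic Gamma x wire x electrolyte product
# predicts), computed purely numerically.
numeric_charge_response <- function(l_nm, params, h = 0.005, pad = 12) {
  R <- params$R_nm
  a <- R + params$t_ox_nm
  rc <- R + l_nm
  stopifnot(l_nm >= params$t_ox_nm)  # charge must sit in the electrolyte
  rmax <- rc + pad * params$lambda_D_nm
  n <- ceiling(rmax / h)
  faces <- (0:n) * h
  cent <- (faces[-1] + faces[-(n + 1)]) / 2
  epsr <- function(r) {
    ifelse(r < R, params$eps_NW, ifelse(r < a, params$eps_ox, params$eps_sol))
  }
  scr <- ifelse(cent < R, params$eps_NW / params$lambda_TF_nm^2,
                ifelse(cent < a, 0, params$eps_sol / params$lambda_D_nm^2))
  ef <- epsr(faces)
  lower <- faces[2:n] * ef[2:n] / h^2
  main <- -(faces[2:(n + 1)] * ef[2:(n + 1)] + faces[1:n] * ef[1:n]) / h^2 -
    cent * scr
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, main, lower))
  rhs <- numeric(n)
  ic <- min(n, max(1L, floor(rc / h) + 1L))
  rhs[ic] <- -rc / h
  phi <- as.numeric(Matrix::solve(A, rhs))
  inside <- cent < R
  (params$eps_NW / (params$lambda_TF_nm^2 * R)) *
    sum(phi[inside] * cent[inside] * h)
}

analytic_charge_response <- function(l_nm, params) {
  f <- poisson_factors(params)
  screening_factor(l_nm, params) * f$wire * f$electrolyte
}
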