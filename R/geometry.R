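# standard atomic masses (u) for the mass-weighted center of mass;
# principal axes themselves use unit-weight coordinates.
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971)

atom_masses <- function(elements) {
  m <- unname(.atomic_mass[toupper(elements)])
  m[is.na(m)] <- 12.011
  m
}

coords_matrix <- function(str) {
  cbind(str$x, str$y, str$z)
}

apply_transform <- function(x, rot, center) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.nw_structure <- function(x, rot, center) {
  p <- sweep(coords_matrix(x), 2, center) %*% t(rot)
  x$x <- p[, 1]; x$y <- p[, 2]; x$z <- p[, 3]
  x
}

#' @export
apply_transform.charge_distribution <- function(x, rot, center) {
  # center is given in Angstrom (structure frame); sites live in nm
  if (nrow(x) > 0L) {
    p <- sweep(cbind(x$x_nm, x$y_nm, x$z_nm), 2, center / 10) %*% t(rot)
    x$x_nm <- p[, 1]; x$y_nm <- p[, 2]; x$z_nm <- p[, 3]
  }
  str <- attr(x, "structure")
  if (!is.null(str)) {
    attr(x, "structure") <- apply_transform(str, rot, center)
  }
  x
}

#' Align a structure to its principal axes
#'
#' Moves the mass-weighted center of mass to the coordinate origin and
#' rotates the molecule so that its principal axes (from the unit-weight
#' coordinate covariance) map to the coordinate axes, largest extent along
#' x and smallest along z. The sign of each axis is fixed deterministically
#' by requiring a positive third moment of the coordinates along it
#' (falling back to a non-negative first-atom coordinate when the skewness
#' is degenerate); the third axis is the cross product of the first two, so
#' the rotation is always proper. For a `charge_distribution` carrying its
#' source structure, the alignment is computed from the atoms and applied
#' jointly to atoms and charge sites.
#'
#' @param x An `nw_structure` or `charge_distribution`.
#' @return The aligned object, same type as the input.
#' @export
align_principal <- function(x) {
  str <- if (inherits(x, "charge_distribution")) attr(x, "structure") else x
  if (is.null(str)) {
    if (nrow(x) == 0L) return(x)
    p <- cbind(x$x_nm, x$y_nm, x$z_nm) * 10  # treat sites as unit-mass atoms
    tr <- principal_transform(p, rep(1, nrow(p)))
  } else {
    tr <- principal_transform(coords_matrix(str), atom_masses(str$element))
  }
  apply_transform(x, tr$rot, tr$center)
}

principal_transform <- function(p, mass) {
  center <- colSums(p * mass) / sum(mass)
  q <- sweep(p, 2, center)
  if (nrow(p) < 2L || max(abs(q)) < 1e-12) {
    return(list(rot = diag(3), center = center))
  }
  cv <- crossprod(q) / nrow(q)  # unit-weight covariance about the COM
  eg <- eigen(cv, symmetric = TRUE)
  axes <- eg$vectors[, order(eg$values, decreasing = TRUE), drop = FALSE]
  for (k in 1:2) {
    proj <- q %*% axes[, k]
    s3 <- sum(proj^3)
    if (abs(s3) > 1e-9) {
      if (s3 < 0) axes[, k] <- -axes[, k]
    } else if (proj[1] < 0) {
      axes[, k] <- -axes[, k]
    }
  }
  a3 <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
          axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
          axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  list(rot = rbind(axes[, 1], axes[, 2], a3), center = center)
}

#' Rotation matrix from Euler angles
#'
#' Builds the proper rotation `Rz(z) Ry(y) Rx(x)` (extrinsic rotations
#' about the fixed x, then y, then z axes), angles in degrees.
#'
#' @param euler_deg Numeric length-3 vector of angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(euler_deg) {
  stopifnot(is.numeric(euler_deg), length(euler_deg) == 3L)
  a <- euler_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rotate a structure or charge distribution about the origin
#'
#' Applies a rigid rotation to the positions (charges are unchanged). This
#' is how a binding orientation towards the nanowire surface is set up: the
#' wire surface is the plane the molecule is later offset onto, with z
#' increasing away from the wire.
#'
#' @param x An `nw_structure` or `charge_distribution` (the attached
#'   structure, if any, is rotated jointly).
#' @param euler_deg Euler angles in degrees, see [rotation_matrix()].
#' @param rotation A 3x3 proper rotation matrix; overrides `euler_deg`.
#' @return The rotated object.
#' @examples
#' dist <- assign_charges(build_peptide("KKAAAAAAAADD"))
#' flipped <- orient(align_principal(dist), euler_deg = c(180, 0, 0))
#' @export
orient <- function(x, euler_deg = NULL, rotation = NULL) {
  rot <- if (!is.null(rotation)) rotation else rotation_matrix(euler_deg)
  if (!is.matrix(rot) || !all(dim(rot) == c(3L, 3L)) ||
      max(abs(crossprod(rot) - diag(3))) > 1e-6 ||
      abs(det(rot) - 1) > 1e-6) {
    abort("`rotation` must be a proper 3x3 rotation matrix",
          class = "nanofet_input_error")
  }
  apply_transform(x, rot, c(0, 0, 0))
}

#' Distances of the discrete charges from the nanowire surface
#'
#' Offsets the charge distribution so that its lowest site touches the top
#' of the biofunctionalization layer and computes, per site, the total
#' distance from the semiconductor nanowire surface
#' \eqn{l_j = (z_j - z_{min}) + t_{linker} + t_{ox}}. Removing the offset
#' `z_min` means any free space below the molecule has no effect on the
#' result; translating the distribution in z leaves the profile unchanged.
#'
#' @param dist A `charge_distribution` with at least one site.
#' @param t_linker_nm Biolinker (functionalization layer) thickness in nm.
#' @param t_ox_nm Oxide layer thickness in nm.
#' @return The distribution with extra columns `dz_nm` (height above the
#'   lowest site) and `l_nm` (total distance from the wire surface), plus
#'   attributes `z_min_nm`, `t_linker_nm`, `t_ox_nm`. Class
#'   `distance_profile`.
#' @export
distance_profile <- function(dist, t_linker_nm = 1, t_ox_nm = 2) {
  stopifnot(inherits(dist, "charge_distribution"))
  if (nrow(dist) < 1L) {
    abort("distance profile needs at least one charge site",
          class = "nanofet_input_error")
  }
  stopifnot(t_linker_nm >= 0, t_ox_nm >= 0)
  z_min <- min(dist$z_nm)
  out <- dist
  out$dz_nm <- dist$z_nm - z_min
  out$l_nm <- out$dz_nm + t_linker_nm + t_ox_nm
  attr(out, "z_min_nm") <- z_min
  attr(out, "t_linker_nm") <- t_linker_nm
  attr(out, "t_ox_nm") <- t_ox_nm
  if (!inherits(out, "distance_profile")) {
    class(out) <- c("distance_profile", class(out))
  }
  out
}

#' Number of molecules covering the nanowire
#'
#' Assuming complete, uniform coverage, the number of bound analyte
#' molecules is the outer wire surface area \eqn{2\pi (R + t_{ox}) L}
#' divided by the area of the bounding-box face oriented towards the wire
#' (the x-y extents of the all-atom bounding box in the current
#' orientation), rounded down. A manual override is supported because it is
#' debatable whether the molecule count should change with orientation.
#'
#' @param x An `nw_structure` or a `charge_distribution`; for the latter
#'   the attached all-atom structure is used when present, otherwise the
#'   charge sites themselves (with a message).
#' @param params [device_params()] list (wire radius, length, oxide
#'   thickness).
#' @param N_mol Optional manual molecule count; returned as-is when given.
#' @return Integer molecule count.
#' @examples
#' pep <- align_principal(build_peptide("KKAAAAAAAADD"))
#' coverage(pep, device_params())
#' @export
coverage <- function(x, params = device_params(), N_mol = NULL) {
  if (!is.null(N_mol)) {
    stopifnot(is.numeric(N_mol), length(N_mol) == 1L, N_mol > 0)
    return(as.integer(N_mol))
  }
  box <- bounding_box_nm(x)
  ext <- box$max - box$min
  a_face <- ext[1] * ext[2]
  if (!is.finite(a_face) || a_face <= 0) {
    abort(paste("molecule footprint has zero area in this orientation;",
                "set N_mol manually"), class = "nanofet_input_error")
  }
  a_wire <- 2 * pi * (params$R_nm + params$t_ox_nm) * params$L_nm
  n <- floor(a_wire / a_face)
  if (n > .Machine$integer.max) {
    abort(paste("molecule footprint is implausibly small for this wire;",
                "set N_mol manually"), class = "nanofet_input_error")
  }
  as.integer(n)
}

bounding_box_nm <- function(x) {
  if (inherits(x, "charge_distribution")) {
    str <- attr(x, "structure")
    if (!is.null(str)) {
      p <- coords_matrix(str) / 10
    } else {
      inform("no atomic structure attached; bounding box from charge sites")
      p <- cbind(x$x_nm, x$y_nm, x$z_nm)
    }
  } else if (inherits(x, "nw_structure")) {
    p <- coords_matrix(x) / 10
  } else {
    abort("`x` must be a structure or charge distribution",
          class = "nanofet_input_error")
  }
  if (nrow(p) == 0L) abort("empty object has no bounding box")
  list(min = apply(p, 2, min), max = apply(p, 2, max))
}

#' Collapse a distribution to a single point charge
#'
#' The single-charge approximation places the net charge of the analyte at
#' the geometrical center of its enclosing bounding box (all-atom box when
#' the structure is attached, charge-site box otherwise). Useful when no
#' particular binding orientation is favoured.
#'
#' @param dist A `charge_distribution` with at least one site.
#' @return A one-site `charge_distribution` (class `"FIXED"`), with the
#'   source structure and pH carried over.
#' @export
single_charge <- function(dist) {
  stopifnot(inherits(dist, "charge_distribution"))
  if (nrow(dist) < 1L) {
    abort("cannot collapse an empty distribution",
          class = "nanofet_input_error")
  }
  if (nrow(dist) == 1L) return(dist)
  box <- bounding_box_nm(dist)
  ctr <- (box$min + box$max) / 2
  new_charge_distribution(
    tibble(site = "TOTAL", class = "FIXED",
           chain = NA_character_, resno = NA_integer_,
           x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3],
           pKa = NA_real_, charge = net_charge(dist)),
    pH = attr(dist, "pH"), structure = attr(dist, "structure"))
}
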