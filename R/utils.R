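# internal helpers shared across modules

`%||%` <- rlang::`%||%`

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize angles to the storage convention
#'
#' Maps angles in degrees onto the half-open interval \[-180, 180).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length on \[-180, 180).
#' @export
#' @examples
#' norm_angle(c(0, 180, -180, 270, 360))
norm_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

abort_domain <- function(msg) rlang::abort(msg, class = "coilr_domain_error")
abort_validation <- function(msg) rlang::abort(msg, class = "coilr_validation_error")
abort_analysis <- function(msg) rlang::abort(msg, class = "coilr_analysis_error")
abort_io <- function(msg) rlang::abort(msg, class = "coilr_io_error")

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number, got %s", name,
                         paste(utils::head(format(x), 3), collapse = ", ")))
  }
  if (x < min || x > max) {
    abort_domain(sprintf("`%s` = %s is outside [%s, %s]", name, format(x),
                         format(min), format(max)))
  }
  if (!allow_zero && x == 0) {
    abort_domain(sprintf("`%s` must be non-zero", name))
  }
  invisible(x)
}

# rowwise cross product for n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

# Natural-extension reference frame placement, vectorized over rows.
# Places atom D bonded to C, with |CD| = bond, angle(B,C,D) = ang (deg) and
# dihedral(A,B,C,D) = tors (deg).
nerf_place <- function(A, B, C, bond, ang, tors) {
  ang <- deg2rad(ang)
  tors <- deg2rad(tors)
  b1 <- normalize_rows(B - A)
  b2 <- normalize_rows(C - B)
  n <- normalize_rows(cross3(b1, b2))
  m <- cross3(n, b2)
  d1 <- -bond * cos(ang)
  d2 <- bond * sin(ang) * cos(tors)
  d3 <- bond * sin(ang) * sin(tors)
  C + d1 * b2 + d2 * m + d3 * n
}

dihedral_angle <- function(p0, p1, p2, p3) {
  if (is.null(dim(p0))) {
    p0 <- rbind(p0); p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3)
  }
  b0 <- p0 - p1
  b1 <- normalize_rows(p2 - p1)
  b2 <- p3 - p2
  v <- b0 - rowSums(b0 * b1) * b1
  w <- b2 - rowSums(b2 * b1) * b1
  x <- rowSums(v * w)
  y <- rowSums(cross3(b1, v) * w)
  rad2deg(atan2(y, x))
}

bond_angle <- function(p0, p1, p2) {
  if (is.null(dim(p0))) {
    p0 <- rbind(p0); p1 <- rbind(p1); p2 <- rbind(p2)
  }
  a <- normalize_rows(p0 - p1)
  b <- normalize_rows(p2 - p1)
  rad2deg(acos(pmin(1, pmax(-1, rowSums(a * b)))))
}

# arbitrary rigid-body transform, used in tests and by the analysis modules
rigid_transform <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}

rotation_about_z <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}
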