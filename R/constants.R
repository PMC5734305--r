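# Minor-helix constants and ideal-backbone geometry.
#
# The secondary-structure constants below define the minor helix that is
# wound along the super-helical path. The per-residue phase advance is
# expressed in the rotating (Crick) frame, so a heptad spans exactly two
# minor-helix turns and register positions keep a fixed Crick angle along
# the chain, which is what produces continuous a/d hydrophobic seams.

#' Secondary-structure constants used by the builders
#'
#' Returns the minor-helix constants for one fold: rise per residue along
#' the super-helical path (Angstrom), the CA minor-helix radius (Angstrom)
#' and the per-residue Crick-phase advance (degrees, in the rotating frame;
#' negative = left-handed minor helix). Collagen values describe a
#' polyproline-II-like strand with 7/2-inspired symmetry (3.5 residues per
#' left-handed turn). Both sets can be overridden per call in the builders.
#'
#' @param fold `"coiled_coil"` or `"collagen"`.
#' @return A named list with `rise`, `minor_radius`, `twist` and
#'   `pitch_ceiling` (the |pitch| above which a model is treated as
#'   uncoiled).
#' @export
#' @examples
#' fold_constants("coiled_coil")$twist # 720/7 degrees per residue
fold_constants <- function(fold = c("coiled_coil", "collagen")) {
  fold <- match.arg(fold)
  if (fold == "coiled_coil") {
    list(rise = 1.495, minor_radius = 2.26, twist = 720 / 7,
         pitch_ceiling = 1000)
  } else {
    list(rise = 2.86, minor_radius = 1.63, twist = -720 / 7,
         pitch_ceiling = 1000)
  }
}

# ideal backbone torsions used to derive per-atom minor-helix offsets
IDEAL_TORSIONS <- list(
  coiled_coil = list(phi = -57.8, psi = -47.0, omega = 180),
  collagen    = list(phi = -75.0, psi = 155.0, omega = 180)
)

IDEAL_BONDS <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231)
IDEAL_ANGLES <- list(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
                     ca_c_o = 120.8)

# Build an ideal straight chain (backbone only) from internal coordinates.
# Returns a list of n x 3 matrices N, CA, C, O.
build_ideal_chain <- function(torsions, n = 13) {
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(IDEAL_BONDS$n_ca, 0, 0)
  th <- deg2rad(IDEAL_ANGLES$n_ca_c)
  C[1, ] <- CA[1, ] + IDEAL_BONDS$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1) + 1L) {
    N[i, ] <- nerf_place(rbind(N[i - 1, ]), rbind(CA[i - 1, ]), rbind(C[i - 1, ]),
                         IDEAL_BONDS$c_n, IDEAL_ANGLES$ca_c_n, torsions$psi)
    CA[i, ] <- nerf_place(rbind(CA[i - 1, ]), rbind(C[i - 1, ]), rbind(N[i, ]),
                          IDEAL_BONDS$n_ca, IDEAL_ANGLES$c_n_ca, torsions$omega)
    C[i, ] <- nerf_place(rbind(C[i - 1, ]), rbind(N[i, ]), rbind(CA[i, ]),
                         IDEAL_BONDS$ca_c, IDEAL_ANGLES$n_ca_c, torsions$phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(rbind(N[i, ]), rbind(CA[i, ]), rbind(C[i, ]),
                         IDEAL_BONDS$c_o, IDEAL_ANGLES$ca_c_o,
                         torsions$psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Fit the screw axis of a regular helix from an ordered set of points.
# Uses chord-difference vectors (which are perpendicular to the axis) to get
# the direction, then a linear (Kasa) circle fit of the projected points for
# the center. Returns direction (unit, pointing along increasing index),
# center point, radius, twist per step (deg, signed) and rise per step.
fit_screw_axis <- function(pts) {
  n <- nrow(pts)
  if (n < 5) abort_analysis("need at least 5 points to fit a helix axis")
  v <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
  a <- v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  crosses <- cross3(a[-nrow(a), , drop = FALSE], a[-1, , drop = FALSE])
  crosses <- normalize_rows(crosses)
  # sign-align to the first cross
  s <- sign(crosses %*% crosses[1, ])
  u <- colMeans(crosses * as.vector(s))
  u <- u / sqrt(sum(u^2))
  if (sum(colMeans(v) * u) < 0) u <- -u
  # basis perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  px <- rel %*% e1
  py <- rel %*% e2
  pz <- rel %*% u
  # Kasa circle fit: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(px, py, 1)
  b <- -(px^2 + py^2)
  sol <- qr.solve(A, b)
  cx <- -sol[1] / 2
  cy <- -sol[2] / 2
  radius <- sqrt(cx^2 + cy^2 - sol[3])
  phase <- atan2(py - cy, px - cx)
  dphase <- diff(phase)
  dphase <- atan2(sin(dphase), cos(dphase))
  twist <- rad2deg(mean(dphase))
  rise <- mean(diff(pz))
  center <- ctr + as.vector(cx) * e1 + as.vector(cy) * e2
  list(direction = u, center = center, radius = radius,
       twist = twist, rise = rise,
       basis = list(e1 = e1, e2 = e2),
       phase = as.vector(phase), z = as.vector(pz - mean(pz)))
}

# Per-atom minor-helix offsets relative to CA, derived once per fold from an
# ideal straight chain: radius about the local helix axis, phase offset
# (deg) and axial offset (Angstrom). Cached in the package environment.
.coilr_cache <- new.env(parent = emptyenv())

backbone_offsets <- function(fold = c("coiled_coil", "collagen")) {
  fold <- match.arg(fold)
  key <- paste0("offsets_", fold)
  if (!is.null(.coilr_cache[[key]])) return(.coilr_cache[[key]])
  chain <- build_ideal_chain(IDEAL_TORSIONS[[fold]], n = 13)
  fit <- fit_screw_axis(chain$CA[3:11, , drop = FALSE])
  mid <- 7L
  u <- fit$direction
  e1 <- fit$basis$e1
  e2 <- fit$basis$e2
  ref <- list()
  ca_rel <- chain$CA[mid, ] - fit$center
  ca_phase <- atan2(sum(ca_rel * e2), sum(ca_rel * e1))
  ca_z <- sum(ca_rel * u)
  ca_r <- sqrt(sum(ca_rel^2) - ca_z^2)
  for (at in c("N", "CA", "C", "O")) {
    rel <- chain[[at]][mid, ] - fit$center
    zq <- sum(rel * u)
    rq <- sqrt(max(sum(rel^2) - zq^2, 0))
    phq <- atan2(sum(rel * e2), sum(rel * e1))
    ref[[at]] <- c(
      radius = rq,
      dphase = norm_angle(rad2deg(phq - ca_phase)),
      dz = zq - ca_z
    )
  }
  out <- list(atoms = ref, ca_radius = ca_r,
              ideal_twist = fit$twist, ideal_rise = fit$rise)
  .coilr_cache[[key]] <- out
  out
}
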