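# Re-measurement of Crick parameters from coordinates: geometric evaluation
# of a built (or read-in) backbone.

# Heptad-window path points: a 7-residue boxcar over CA positions cancels a
# 102.86 deg/residue minor helix exactly (the 7 phases form a complete set
# of 7th roots of unity), leaving points on the super-helical path.
path_points <- function(ca, window = 7L) {
  n <- nrow(ca)
  if (n < window + 1) abort_analysis(sprintf(
    "need at least %d CA atoms (>= 2 heptads) per chain, got %d", window + 1, n))
  k <- n - window + 1L
  t(vapply(seq_len(k), function(i) colMeans(ca[i:(i + window - 1L), , drop = FALSE]),
           numeric(3)))
}

# residuals of the Crick CA forward model against observed CA coordinates;
# par = (ox, oy, ax, ay, r0, P, psi_ref, phi0, z0) in the pre-aligned frame
crick_ca_residuals <- function(par, ca_obs, n, t_ref, orientation) {
  d <- c(par[3], par[4], 1)
  d <- d / sqrt(sum(d^2))
  e1f <- c(1, 0, 0) - d[1] * d
  e1f <- e1f / sqrt(sum(e1f^2))
  e2f <- c(d[2] * e1f[3] - d[3] * e1f[2],
           d[3] * e1f[1] - d[1] * e1f[3],
           d[1] * e1f[2] - d[2] * e1f[1])
  ca_mod <- crick_chain_coords(n, abs(par[5]), par[6],
                               rad2deg(par[7]), rad2deg(par[8]), par[9],
                               orientation, t_ref, atoms = "CA")$CA
  lab <- ca_mod %*% rbind(e1f, e2f, d)
  lab <- sweep(lab, 2, -c(par[1], par[2], 0))
  as.vector(lab - ca_obs)
}

#' Fit super-helical parameters to a structure
#'
#' Recovers radius, pitch, interface angle and super-helical rotation from
#' coordinates by (1) extracting heptad-window path points from each chain's
#' CA trace, (2) aligning the assembly to its principal axis, and (3)
#' refining a full Crick CA model per chain by Levenberg-Marquardt least
#' squares with the axis free to tilt and translate. If the coarse stage
#' finds |pitch| above `pitch_ceiling`, the chain is reported as uncoiled
#' (`supercoiled = FALSE`, pitch `NA`) and only radius/phase are reported.
#'
#' @param model A model tibble with at least CA atoms.
#' @param chains Character vector of chain ids to fit (default: all).
#' @param register Heptad register string for the selected chains (used to
#'   pick the reference 'a' residue for the interface angle). Default
#'   assumes the register starts at 'a' on residue 1.
#' @param pitch_ceiling |pitch| (Angstrom) above which no supercoiling is
#'   reported.
#' @return A `coilr_fit` object: a tibble with one row per chain (`chain`,
#'   `radius`, `pitch`, `pitch_angle`, `interface_angle`,
#'   `super_helical_rotation`, `z_shift`, `orientation`, `supercoiled`,
#'   `rmsd`, `n_residues`) carrying the per-residue Crick angles as the
#'   `crick_angles` attribute. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' spec <- assembly_spec(oligomer_state = 2, helices = p)
#' fit <- measure_parameters(build_assembly(spec)$model)
#' fit$radius
measure_parameters <- function(model, chains = NULL, register = NULL,
                               pitch_ceiling = NULL) {
  model <- as_model(model)
  pitch_ceiling <- pitch_ceiling %||% fold_constants("coiled_coil")$pitch_ceiling
  sel <- chains %||% unique(model$chain)
  missing <- setdiff(sel, unique(model$chain))
  if (length(missing) > 0) {
    abort_analysis(sprintf("chain(s) not in model: %s",
                           paste(missing, collapse = ", ")))
  }
  ca_by_chain <- lapply(sel, function(ch) {
    ca <- model[model$chain == ch & model$atom == "CA", ]
    ca <- ca[order(ca$res_num), ]
    as.matrix(ca[, c("x", "y", "z")])
  })
  names(ca_by_chain) <- sel
  pts_list <- lapply(ca_by_chain, path_points)
  allpts <- do.call(rbind, pts_list)
  ctr <- colMeans(allpts)
  # global axis: average of the chains' path chords (sign-aligned to the
  # first chain). For symmetric bundles the radial components cancel,
  # which is far more robust than a principal axis of the point cloud
  # when chains sweep short, strongly inclined arcs.
  chords <- t(vapply(pts_list, function(p) p[nrow(p), ] - p[1, ], numeric(3)))
  signs <- sign(chords %*% chords[1, ])
  signs[signs == 0] <- 1
  u <- colSums(chords * as.vector(signs))
  u <- u / sqrt(sum(u^2))
  # orient the axis along the first chain's residue progression
  first <- ca_by_chain[[1]]
  if (sum((first[nrow(first), ] - first[1, ]) * u) < 0) u <- -u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1g <- ref - sum(ref * u) * u
  e1g <- e1g / sqrt(sum(e1g^2))
  e2g <- c(u[2] * e1g[3] - u[3] * e1g[2],
           u[3] * e1g[1] - u[1] * e1g[3],
           u[1] * e1g[2] - u[2] * e1g[1])
  to_frame <- function(m) sweep(m, 2, ctr) %*% cbind(e1g, e2g, u)
  t_ref <- 0
  if (!is.null(register) && nzchar(register)) {
    regc <- strsplit(tolower(register), "")[[1]]
    fa <- which(regc == "a")[1]
    if (!is.na(fa)) t_ref <- fa - 1
  }
  rows <- list()
  crick_tbl <- list()
  for (ch in sel) {
    ca <- to_frame(ca_by_chain[[ch]])
    pts <- to_frame(pts_list[[ch]])
    n <- nrow(ca)
    ascending <- ca[n, 3] > ca[1, 3]
    orientation <- if (ascending) "parallel" else "antiparallel"
    # coarse stage: radius and azimuthal advance of the path points
    r_init <- mean(sqrt(pts[, 1]^2 + pts[, 2]^2))
    phase <- atan2(pts[, 2], pts[, 1])
    dph <- diff(phase)
    dph <- atan2(sin(dph), cos(dph))
    dz <- diff(pts[, 3])
    slope <- sum(dph * dz) / sum(dz * dz)      # dtheta/dz, rad per Angstrom
    # a chain whose path points collapse onto the global axis has no
    # measurable superhelix (single straight helix)
    supercoiled <- r_init > 0.5 && is.finite(slope) &&
      abs(2 * pi / slope) <= pitch_ceiling
    rise <- fold_constants("coiled_coil")$rise
    if (!supercoiled) {
      # uncoiled: radius of the minor helix axis about the global axis
      rows[[ch]] <- tibble::tibble(
        chain = ch, radius = r_init, pitch = NA_real_, pitch_angle = NA_real_,
        interface_angle = NA_real_, super_helical_rotation = NA_real_,
        z_shift = NA_real_, orientation = orientation,
        supercoiled = FALSE, rmsd = NA_real_, n_residues = n)
      next
    }
    p_init <- 2 * pi / slope
    z0_init <- if (ascending) ca[1, 3] else ca[n, 3]
    # multi-start over the Crick phase (the residual surface is sinusoidal
    # in psi_ref), each with an axis-fixed 5-parameter fit first and a
    # full 9-parameter refinement second: the axis-fixed fit is immune to
    # the radius/tilt degeneracy of strongly inclined chains
    best <- NULL
    for (psi0 in deg2rad(c(20, 110, -160, -70))) {
      par0 <- c(0, 0, 0, 0, r_init, p_init, psi0, phase[1], z0_init)
      fixed_axis <- minpack.lm::nls.lm(
        par = par0[5:9],
        fn = function(th, ...) crick_ca_residuals(c(0, 0, 0, 0, th), ...),
        ca_obs = ca, n = n, t_ref = t_ref, orientation = orientation,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      for (start in list(par0, c(0, 0, 0, 0, fixed_axis$par))) {
        fit <- minpack.lm::nls.lm(
          par = start, fn = crick_ca_residuals, ca_obs = ca, n = n,
          t_ref = t_ref, orientation = orientation,
          control = minpack.lm::nls.lm.control(maxiter = 200))
        if (is.null(best) || fit$deviance < best$deviance) best <- fit
      }
    }
    par <- unname(best$par)
    resid <- crick_ca_residuals(par, ca, n, t_ref, orientation)
    rmsd <- sqrt(mean(matrix(resid^2, ncol = 3) %*% c(1, 1, 1)))
    alpha <- pitch_angle(abs(par[5]), par[6])
    # per-residue Crick angles implied by the fitted reference
    w1 <- fold_constants("coiled_coil")$twist
    crick <- norm_angle(rad2deg(par[7]) + w1 * ((seq_len(n) - 1) - t_ref))
    crick_tbl[[ch]] <- tibble::tibble(chain = ch, res_num = seq_len(n),
                                      crick_angle = crick)
    rows[[ch]] <- tibble::tibble(
      chain = ch, radius = abs(par[5]), pitch = par[6], pitch_angle = alpha,
      interface_angle = norm_angle(rad2deg(par[7])),
      super_helical_rotation = norm_angle(rad2deg(par[8])),
      z_shift = par[9], orientation = orientation,
      supercoiled = TRUE, rmsd = rmsd, n_residues = n)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "crick_angles") <- dplyr::bind_rows(crick_tbl)
  class(out) <- c("coilr_fit", class(out))
  out
}

#' @export
print.coilr_fit <- function(x, ...) {
  cat("# super-helical parameter fit\n")
  NextMethod()
}

#' Tidy a super-helical parameter fit
#'
#' @param x A `coilr_fit` from [measure_parameters()].
#' @param ... Unused.
#' @return A tibble in long format: one row per chain and parameter.
#' @export
tidy.coilr_fit <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("chain", "radius", "pitch", "pitch_angle",
                             "interface_angle", "super_helical_rotation",
                             "z_shift")],
    -"chain", names_to = "parameter", values_to = "estimate")
}

#' Glance at a super-helical parameter fit
#'
#' @param x A `coilr_fit` from [measure_parameters()].
#' @param ... Unused.
#' @return A one-row tibble with chain count, mean fit RMSD and whether all
#'   chains were supercoiled.
#' @export
glance.coilr_fit <- function(x, ...) {
  tibble::tibble(
    n_chains = nrow(x),
    mean_rmsd = mean(x$rmsd, na.rm = TRUE),
    all_supercoiled = all(x$supercoiled)
  )
}
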