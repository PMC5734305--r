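# Crick-style parametric geometry: super-helical paths and minor-helix
# backbone construction.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1_COLLAGEN <- c(AA1, O = "HYP")
AA3_TO_1 <- stats::setNames(names(AA1_COLLAGEN), AA1_COLLAGEN)

seq_to_res3 <- function(sequence, collagen = FALSE) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  lut <- if (collagen) AA1_COLLAGEN else AA1
  bad <- setdiff(letters1, names(lut))
  if (length(bad) > 0) {
    extra <- if (!collagen && "O" %in% bad)
      " ('O' = hydroxyproline is allowed in the collagen build mode only)" else ""
    abort_validation(sprintf("invalid sequence character(s): %s%s",
                             paste(unique(bad), collapse = ", "), extra))
  }
  unname(lut[letters1])
}

#' One helix's Crick parameters
#'
#' Bundles the structural parameters of a single helix (or collagen strand)
#' of an assembly: super-helical radius and pitch, interface angle (the
#' Crick angle at the reference register-'a' position), super-helical
#' rotation, z-shift, orientation, and the sequence with its heptad
#' register. All parameters are defined relative to the super-helical axis,
#' so helices of an assembly are fully decoupled from one another.
#'
#' @param radius Super-helical radius in Angstrom (> 0).
#' @param pitch Super-helical pitch in Angstrom (non-zero). The sign encodes
#'   handedness: negative = left-handed supercoil, the default sense for
#'   heptad-based coiled coils.
#' @param interface_angle Crick angle (degrees) of the first register-'a'
#'   residue, measured from the direction pointing at the super-helical
#'   axis; normalized to \[-180, 180).
#' @param super_helical_rotation Angular offset of this helix about the
#'   super-helical axis (degrees); see [default_shr()] for the symmetric
#'   default. Normalized to \[-180, 180).
#' @param z_shift Translation along the super-helical axis (Angstrom),
#'   applied after any orientation reversal.
#' @param orientation `"parallel"` or `"antiparallel"`. An antiparallel
#'   helix runs N-to-C down the axis, residue 1 at the top of its z-range.
#' @param sequence One-letter amino-acid sequence (may be `""` for a
#'   backbone-only poly-Ala build).
#' @param register String over a–g, same length as `sequence`, or `""`
#'   (collagen strands carry no heptad register).
#' @param helix_index 1-based index of the helix within its assembly.
#' @return A list of class `coilr_helix_params`.
#' @export
#' @examples
#' helix_params(radius = 4.9, pitch = -180, interface_angle = 26,
#'              sequence = "IAALKQE", register = "abcdefg")
helix_params <- function(radius,
                         pitch,
                         interface_angle = 26,
                         super_helical_rotation = 0,
                         z_shift = 0,
                         orientation = c("parallel", "antiparallel"),
                         sequence = "",
                         register = "",
                         helix_index = 1L) {
  check_number(radius, "radius")
  if (radius <= 0) abort_domain(sprintf("`radius` must be > 0, got %s", radius))
  check_number(pitch, "pitch", allow_zero = FALSE)
  check_number(interface_angle, "interface_angle")
  check_number(super_helical_rotation, "super_helical_rotation")
  check_number(z_shift, "z_shift")
  orientation <- match.arg(orientation)
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort_validation("`sequence` must be a single string")
  }
  sequence <- toupper(sequence)
  register <- tolower(register)
  if (nzchar(register)) {
    if (nchar(register) != nchar(sequence)) {
      abort_validation(sprintf(
        "register length (%d) does not match sequence length (%d)",
        nchar(register), nchar(sequence)))
    }
    regc <- strsplit(register, "")[[1]]
    bad <- setdiff(regc, letters[1:7])
    if (length(bad) > 0) {
      abort_validation(sprintf("register characters must be a-g, got: %s",
                               paste(unique(bad), collapse = ", ")))
    }
  }
  if (!is.numeric(helix_index) || helix_index < 1) {
    abort_domain(sprintf("`helix_index` must be >= 1, got %s", helix_index))
  }
  structure(
    list(radius = radius,
         pitch = pitch,
         interface_angle = norm_angle(interface_angle),
         super_helical_rotation = norm_angle(super_helical_rotation),
         z_shift = z_shift,
         orientation = orientation,
         sequence = sequence,
         register = register,
         helix_index = as.integer(helix_index)),
    class = "coilr_helix_params")
}

#' Default super-helical rotation for a symmetric bundle
#'
#' The ideal angular offset of helix `i` about the super-helical axis in a
#' symmetric n-helix bundle: `(i - 1) * 360 / n` degrees. Helix 1 of any
#' bundle sits at 0 degrees; helix 3 of a tetramer at 180 degrees. Reported
#' on \[0, 360); use [norm_angle()] for the \[-180, 180) storage convention.
#'
#' @param i Helix index, `1 <= i <= n`.
#' @param n Oligomeric state, `n >= 2`.
#' @return Angle in degrees on \[0, 360).
#' @export
#' @examples
#' default_shr(3, 4) # 180
default_shr <- function(i, n) {
  check_number(n, "n")
  check_number(i, "i")
  if (n < 2 || n != round(n)) {
    abort_domain(sprintf("oligomer state `n` must be an integer >= 2, got %s", n))
  }
  if (i < 1 || i > n || i != round(i)) {
    abort_domain(sprintf("helix index `i` must be an integer in [1, %d], got %s", n, i))
  }
  ((i - 1) * 360 / n) %% 360
}

#' Pitch angle of a superhelix
#'
#' The inclination of the super-helical path relative to the assembly axis,
#' `alpha = atan(2 * pi * radius / pitch)`, in degrees. The sign follows
#' the pitch sign (negative = left-handed supercoil).
#'
#' @param radius Super-helical radius, Angstrom (> 0).
#' @param pitch Super-helical pitch, Angstrom (non-zero).
#' @return Pitch angle in degrees.
#' @export
#' @examples
#' pitch_angle(5, 2 * pi * 5) # 45
pitch_angle <- function(radius, pitch) {
  check_number(radius, "radius")
  if (radius <= 0) abort_domain(sprintf("`radius` must be > 0, got %s", radius))
  check_number(pitch, "pitch", allow_zero = FALSE)
  rad2deg(atan(2 * pi * radius / pitch))
}

#' Point on a helix's super-helical path
#'
#' Evaluates the circular-helix path that a helix's minor axis follows:
#' azimuth `theta = shr + 2 * pi * (z - z_shift) / pitch` at distance
#' `radius` from the z-axis.
#'
#' @param z Height(s) along the super-helical axis, Angstrom.
#' @param params A [helix_params()] object.
#' @return A tibble with columns `x`, `y`, `z` (one row per element of `z`).
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = 140)
#' superhelix_point(c(0, 35), p)
superhelix_point <- function(z, params) {
  stopifnot(inherits(params, "coilr_helix_params"))
  theta <- deg2rad(params$super_helical_rotation) +
    2 * pi * (z - params$z_shift) / params$pitch
  tibble::tibble(x = params$radius * cos(theta),
                 y = params$radius * sin(theta),
                 z = z)
}

# Core coordinate generator shared by the builders and the parameter-fitting
# code. Returns a list of n x 3 matrices, one per backbone atom type.
crick_chain_coords <- function(n, radius, pitch, interface_angle, shr,
                               z_shift, orientation, t_ref,
                               fold = "coiled_coil", constants = NULL,
                               atoms = BACKBONE_ATOMS) {
  consts <- constants %||% fold_constants(fold)
  offs <- backbone_offsets(fold)
  alpha <- atan(2 * pi * radius / abs(pitch))
  h <- consts$rise * cos(alpha)                 # axial rise per residue
  dtheta <- sign(pitch) * 2 * pi * h / abs(pitch)  # superhelix phase/residue
  eps <- if (orientation == "parallel") 1 else -1
  w1 <- consts$twist                            # minor phase advance deg/res
  shr_rad <- deg2rad(shr)
  t <- seq_len(n) - 1
  out <- list()
  for (at in atoms) {
    o <- offs$atoms[[at]]
    rq <- consts$minor_radius + (o[["radius"]] - offs$atoms[["CA"]][["radius"]])
    dt <- o[["dz"]] / consts$rise
    u <- t + eps * dt
    # shr is the azimuth where the chain crosses its z_shift plane (residue
    # 1 for parallel, residue n for antiparallel chains), so a symmetric
    # bundle stays symmetric for any mix of orientations
    theta <- if (orientation == "parallel") shr_rad + dtheta * u
             else shr_rad + dtheta * (n - 1 - u)
    zc <- z_shift + h * (if (orientation == "parallel") u else (n - 1 - u))
    ct <- cos(theta); st <- sin(theta)
    # unit tangent of the path with respect to chain progression
    Tg <- cbind(-radius * st * (eps * dtheta),
                 radius * ct * (eps * dtheta),
                 rep(eps * h, n)) / consts$rise
    e1 <- cbind(-ct, -st, rep(0, n))            # toward the superhelix axis
    e2 <- cross3(Tg, e1)
    psi <- deg2rad(interface_angle + w1 * (t - t_ref) + o[["dphase"]])
    axis_pt <- cbind(radius * ct, radius * st, zc)
    out[[at]] <- axis_pt + rq * (cos(psi) * e1 + sin(psi) * e2)
  }
  out
}

build_backbone_chain <- function(params, n_residues, fold, chain_id = "A",
                                 constants = NULL) {
  stopifnot(inherits(params, "coilr_helix_params"))
  collagen <- fold == "collagen"
  min_res <- if (collagen) 3L else 4L
  if (is.null(n_residues)) {
    n_residues <- nchar(params$sequence)
  }
  if (!is.numeric(n_residues) || n_residues < min_res) {
    abort_domain(sprintf(
      "`n_residues` must be >= %d for a %s chain, got %s",
      min_res, if (collagen) "collagen" else "helical", format(n_residues)))
  }
  n <- as.integer(n_residues)
  res3 <- if (nzchar(params$sequence)) {
    s3 <- seq_to_res3(params$sequence, collagen = collagen)
    if (length(s3) < n) {
      abort_validation(sprintf("sequence has %d residues but %d requested",
                               length(s3), n))
    }
    s3[seq_len(n)]
  } else {
    rep(if (collagen) "GLY" else "ALA", n)
  }
  t_ref <- 0
  if (nzchar(params$register)) {
    regc <- strsplit(params$register, "")[[1]]
    first_a <- which(regc == "a")[1]
    if (!is.na(first_a)) t_ref <- first_a - 1
  }
  coords <- crick_chain_coords(
    n, params$radius, params$pitch, params$interface_angle,
    params$super_helical_rotation, params$z_shift, params$orientation,
    t_ref, fold = fold, constants = constants)
  atoms <- BACKBONE_ATOMS
  df <- tibble::tibble(
    chain = chain_id,
    res_num = rep(seq_len(n), each = length(atoms)),
    res_name = rep(res3, each = length(atoms)),
    atom = rep(atoms, times = n)
  )
  xyz <- matrix(NA_real_, nrow(df), 3)
  for (k in seq_along(atoms)) {
    idx <- seq(k, nrow(df), by = length(atoms))
    xyz[idx, ] <- coords[[atoms[k]]]
  }
  df$element <- substr(df$atom, 1, 1)
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  as_model(df)
}

#' Build an alpha-helical backbone along a super-helical path
#'
#' Places CA atoms on a minor helix (radius 2.26 A, 1.495 A rise per
#' residue, 102.86 deg Crick-phase advance per residue in the rotating
#' frame) wound about the super-helical path defined by `params`, and adds
#' N, C and O by ideal alpha-helix internal geometry. An antiparallel helix
#' runs top-down: residue 1 sits at the high-z end.
#'
#' @param params A [helix_params()] object.
#' @param n_residues Number of residues (>= 4). Defaults to the sequence
#'   length.
#' @param chain_id Chain identifier for the output records.
#' @param constants Optional override of [fold_constants()] values (list
#'   with any of `rise`, `minor_radius`, `twist`).
#' @return A single-chain backbone model tibble (see [as_model()]).
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' build_helix_backbone(p)
build_helix_backbone <- function(params, n_residues = NULL, chain_id = "A",
                                 constants = NULL) {
  build_backbone_chain(params, n_residues, "coiled_coil", chain_id, constants)
}

#' Build one collagen strand along the triple-helical path
#'
#' Same super-helical machinery as [build_helix_backbone()] but with
#' polyproline-II-like minor-helix constants (2.86 A rise per residue,
#' left-handed 3.5-residue turn). Collagen sequences may contain `O`
#' (hydroxyproline, residue name HYP).
#'
#' @inheritParams build_helix_backbone
#' @param n_residues Number of residues (>= 3).
#' @return A single-chain backbone model tibble.
#' @export
build_collagen_strand <- function(params, n_residues = NULL, chain_id = "A",
                                  constants = NULL) {
  build_backbone_chain(params, n_residues, "collagen", chain_id, constants)
}
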