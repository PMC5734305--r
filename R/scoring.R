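# Soft-core inter-chain interaction energy: steric + desolvation + charge.
#
# The functional forms are documented stand-ins in the spirit of soft
# docking potentials: a finite quadratic repulsion inside the contact
# distance with a short-ranged linear well just past contact; a
# desolvation reward for buried hydrophobic-hydrophobic pairs;
# and a distance-shifted screened formal-charge term. All constants live in
# scoring_constants() and the per-atom table in extdata/atom_params.tsv, so
# swapping in a published parameter set changes data, not code. Energies
# are reported in arbitrary units (a.u.).

#' Per-atom scoring parameters
#'
#' Reads the versioned plain-text parameter table shipped with the package:
#' one row per (residue, heavy atom) with vdW radius (Angstrom), a
#' hydrophobic flag (side-chain carbons) and formal charge (e; +1 on Lys
#' NZ and Arg CZ, -1 on the carboxylate carbon of Asp/Glu as the midpoint
#' convention, His neutral).
#'
#' @return A tibble with columns `res_name`, `atom`, `element`, `radius`,
#'   `hydrophobic`, `charge`.
#' @export
atom_params <- function() {
  if (is.null(.coilr_cache$atom_params)) {
    path <- system.file("extdata", "atom_params.tsv", package = "coilr")
    .coilr_cache$atom_params <- tibble::as_tibble(
      utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
  }
  .coilr_cache$atom_params
}

#' Constants of the soft-core potential
#'
#' @param steric_rep Repulsion strength at zero distance (a.u.).
#' @param steric_well Depth of the steric attractive well (a.u. per pair),
#'   with its bottom at the contact distance (the sum of the two atom
#'   radii, tabulated on the pair-minimum convention).
#' @param steric_range Distance (Angstrom) past contact over which the
#'   steric well decays linearly to zero.
#' @param desolv_well Depth of the hydrophobic desolvation well (a.u. per
#'   hydrophobic-hydrophobic pair).
#' @param desolv_range Decay range of the desolvation term past contact
#'   (Angstrom).
#' @param charge_scale Screened-charge prefactor (a.u. Angstrom / e^2).
#' @param charge_clamp Distance floor (Angstrom) for the charge term.
#' @param cutoff Pair cutoff in Angstrom; every term reaches exactly zero
#'   there.
#' @return A named list of constants.
#' @export
scoring_constants <- function(steric_rep = 100,
                              steric_well = 0.15,
                              steric_range = 2,
                              desolv_well = 0.35,
                              desolv_range = 2.5,
                              charge_scale = 80,
                              charge_clamp = 2,
                              cutoff = 10) {
  list(steric_rep = steric_rep, steric_well = steric_well,
       steric_range = steric_range, desolv_well = desolv_well,
       desolv_range = desolv_range, charge_scale = charge_scale,
       charge_clamp = charge_clamp, cutoff = cutoff)
}

# match per-atom parameters for a model, erroring on uncovered atoms
match_atom_params <- function(model, params = atom_params()) {
  key_m <- paste(model$res_name, model$atom)
  key_p <- paste(params$res_name, params$atom)
  idx <- match(key_m, key_p)
  if (anyNA(idx)) {
    missing <- unique(key_m[is.na(idx)])
    abort_validation(sprintf(
      "no scoring parameters for atom(s): %s",
      paste(utils::head(missing, 8), collapse = ", ")))
  }
  params[idx, ]
}

# core pair evaluation on coordinate/parameter vectors; used by
# interaction_energy() and by the optimizer's cached fast path
pair_energy_terms <- function(xyz, chain, radius, hydrophobic, charge,
                              consts) {
  cutoff <- consts$cutoff
  n <- nrow(xyz)
  steric <- desolv <- chargeE <- 0
  npairs <- 0L
  chains <- unique(chain)
  for (a in seq_along(chains)) {
    for (b in seq_along(chains)) {
      if (b <= a) next
      ia <- which(chain == chains[a])
      ib <- which(chain == chains[b])
      # prune by bounding distance on z then full distances
      dx <- outer(xyz[ia, 1], xyz[ib, 1], "-")
      dy <- outer(xyz[ia, 2], xyz[ib, 2], "-")
      dz <- outer(xyz[ia, 3], xyz[ib, 3], "-")
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      within <- d < cutoff
      if (!any(within)) next
      idx <- which(within, arr.ind = TRUE)
      di <- d[within]
      ri <- radius[ia][idx[, 1]] + radius[ib][idx[, 2]]
      npairs <- npairs + length(di)
      # soft-core steric: quadratic repulsion inside contact, short
      # linear well just past contact (zero well before the cutoff)
      inside <- di < ri
      e_st <- numeric(length(di))
      e_st[!inside] <- -consts$steric_well *
        pmax(0, 1 - (di[!inside] - ri[!inside]) / consts$steric_range)
      e_st[inside] <- consts$steric_rep * (1 - di[inside] / ri[inside])^2 -
        consts$steric_well
      steric <- steric + sum(e_st)
      hh <- hydrophobic[ia][idx[, 1]] & hydrophobic[ib][idx[, 2]]
      if (any(hh)) {
        ramp <- pmin(1, pmax(0, 1 - (di[hh] - ri[hh]) / consts$desolv_range))
        desolv <- desolv - consts$desolv_well * sum(ramp)
      }
      qq <- charge[ia][idx[, 1]] * charge[ib][idx[, 2]]
      nz <- qq != 0
      if (any(nz)) {
        dcl <- pmax(di[nz], consts$charge_clamp)
        chargeE <- chargeE +
          sum(consts$charge_scale * qq[nz] * (1 / dcl - 1 / cutoff))
      }
    }
  }
  list(steric = steric, desolvation = desolv, charge = chargeE,
       total = steric + desolv + chargeE, pairs = npairs)
}

#' Inter-chain interaction energy of a model
#'
#' Sums the soft-core potential over all heavy-atom pairs on different
#' chains within the cutoff; intra-chain pairs are excluded entirely. The
#' breakdown satisfies `total == steric + desolvation + charge` exactly,
#' every term reaches exactly zero at the cutoff (the energy is continuous
#' in the coordinates), and the total is additive over unordered chain
#' pairs.
#'
#' @param model An all-atom model tibble with at least two chains.
#' @param params Per-atom parameter table (default [atom_params()]).
#' @param constants Potential constants (default [scoring_constants()]).
#' @param cutoff Pair cutoff in Angstrom (overrides `constants$cutoff`).
#' @return A `coilr_energy` list: `steric`, `desolvation`, `charge`,
#'   `total` (a.u.) and `pairs` (pairs evaluated). Has tidy()/glance()
#'   methods.
#' @export
#' @examples
#' p <- helix_params(radius = 4.9, pitch = -180,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' m <- place_sidechains(
#'   build_assembly(assembly_spec(oligomer_state = 2, helices = p))$model)
#' interaction_energy(m)$total
interaction_energy <- function(model, params = atom_params(),
                               constants = scoring_constants(),
                               cutoff = NULL) {
  model <- as_model(model)
  if (dplyr::n_distinct(model$chain) < 2) {
    abort_analysis("interaction energy needs at least 2 chains")
  }
  if (!is.null(cutoff)) constants$cutoff <- cutoff
  p <- match_atom_params(model, params)
  res <- pair_energy_terms(model_xyz(model), model$chain,
                           p$radius, p$hydrophobic > 0, p$charge, constants)
  structure(res, class = "coilr_energy")
}

#' @export
print.coilr_energy <- function(x, ...) {
  cat(sprintf(
    "# inter-chain interaction energy (a.u.)\n  steric %.3f + desolvation %.3f + charge %.3f = total %.3f  (%d pairs)\n",
    x$steric, x$desolvation, x$charge, x$total, x$pairs))
  invisible(x)
}

#' @export
tidy.coilr_energy <- function(x, ...) {
  tibble::tibble(term = c("steric", "desolvation", "charge", "total"),
                 energy = c(x$steric, x$desolvation, x$charge, x$total))
}

#' @export
glance.coilr_energy <- function(x, ...) {
  tibble::tibble(total = x$total, pairs = x$pairs)
}
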