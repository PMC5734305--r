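# Metropolis Monte Carlo optimization of structural parameters against the
# inter-chain interaction energy, and oligomer-state scanning.

#' Optimizer configuration
#'
#' @param steps Number of Monte Carlo steps (>= 1).
#' @param temperature Metropolis temperature in energy a.u.
#' @param cooling `"constant"` or `"linear"` (linear ramp to zero over the
#'   run).
#' @param reset_every Restart the walker from the best-so-far state every
#'   this many steps (basin-hopping-style ratchet; `Inf` disables it and
#'   leaves a pure Metropolis chain).
#' @param step_sizes Gaussian proposal widths per parameter: radius (A),
#'   pitch magnitude (A), interface angle (deg).
#' @param bounds List of length-2 numeric bounds per parameter (pitch as
#'   magnitude; the sign of the starting pitch is preserved).
#' @param seed Integer RNG seed; every run is fully reproducible given the
#'   seed.
#' @param max_residues Residue cap for an optimization request, counted
#'   over all chains (default 300).
#' @return A list of class `coilr_optimizer_config`.
#' @export
optimizer_config <- function(steps = 500,
                             temperature = 8,
                             cooling = c("constant", "linear"),
                             reset_every = 300,
                             step_sizes = c(radius = 0.3, pitch = 10,
                                            interface_angle = 8),
                             bounds = list(radius = c(3.5, 14),
                                           pitch = c(80, 500),
                                           interface_angle = c(-90, 90)),
                             seed = 1L,
                             max_residues = 300L) {
  if (steps < 1) abort_domain("`steps` must be >= 1")
  if (any(step_sizes <= 0)) abort_domain("step sizes must be > 0")
  if (any(!vapply(bounds, function(b) all(is.finite(b)), logical(1)))) {
    abort_domain("bounds must be finite")
  }
  structure(list(steps = as.integer(steps), temperature = temperature,
                 cooling = match.arg(cooling), reset_every = reset_every,
                 step_sizes = step_sizes,
                 bounds = bounds, seed = as.integer(seed),
                 max_residues = as.integer(max_residues)),
            class = "coilr_optimizer_config")
}

#' Metropolis Monte Carlo kernel
#'
#' Generic Metropolis sampler over a bounded parameter vector: each step
#' perturbs one uniformly chosen parameter by a Gaussian step, clamps it to
#' its bounds, and accepts when the objective does not increase, otherwise
#' with probability `exp(-dE / T)`. At `T = 0` only downhill moves are
#' accepted. Exposed so the acceptance rule can be checked on frozen toy
#' objectives independently of the modeling pipeline.
#'
#' @param objective Function of the parameter vector returning a scalar
#'   energy.
#' @param x0 Named numeric start vector.
#' @param step_sizes Positive proposal widths, same length as `x0`.
#' @param bounds List of length-2 bounds, same length as `x0`.
#' @param steps Number of steps.
#' @param temperature Metropolis temperature (a.u.).
#' @param cooling `"constant"` or `"linear"`.
#' @param seed Optional integer seed (set before sampling when given).
#' @param reset_every Optional best-so-far restart period (see
#'   [optimizer_config()]); `Inf` keeps the chain a pure Metropolis
#'   sampler.
#' @return A list: `par` (final), `energy`, `best_par`, `best_energy`,
#'   `initial_energy`, `trace` (tibble: step, parameter, proposal, delta_e,
#'   accepted, energy, best_energy), `evaluations`.
#' @export
#' @examples
#' res <- metropolis_run(function(x) (x - 2)^2, c(p = 5),
#'                       step_sizes = 0.5, bounds = list(c(-10, 10)),
#'                       steps = 200, temperature = 0.1, seed = 7)
#' abs(res$best_par - 2) < 0.5
metropolis_run <- function(objective, x0, step_sizes, bounds, steps,
                           temperature, cooling = "constant", seed = NULL,
                           reset_every = Inf) {
  if (!is.null(seed)) set.seed(seed)
  x <- x0
  e <- objective(x)
  init_e <- e
  best <- x
  best_e <- e
  np <- length(x0)
  step_v <- param_v <- prop_v <- de_v <- en_v <- best_v <- numeric(steps)
  acc_v <- logical(steps)
  for (s in seq_len(steps)) {
    if (is.finite(reset_every) && s %% reset_every == 0 && e > best_e) {
      x <- best
      e <- best_e
    }
    temp <- if (cooling == "linear") {
      temperature * (1 - (s - 1) / steps)
    } else temperature
    j <- if (np == 1L) 1L else sample.int(np, 1L)
    prop <- x
    prop[j] <- min(max(x[j] + stats::rnorm(1, 0, step_sizes[j]),
                       bounds[[j]][1]), bounds[[j]][2])
    ep <- objective(prop)
    de <- ep - e
    accept <- de <= 0 ||
      (temp > 0 && stats::runif(1) < exp(-de / temp))
    if (accept) {
      x <- prop
      e <- ep
      if (e < best_e) {
        best_e <- e
        best <- x
      }
    }
    step_v[s] <- s; param_v[s] <- j; prop_v[s] <- prop[j]
    de_v[s] <- de; acc_v[s] <- accept; en_v[s] <- e; best_v[s] <- best_e
  }
  list(par = x, energy = e, best_par = best, best_energy = best_e,
       initial_energy = init_e,
       trace = tibble::tibble(step = step_v,
                              parameter = names(x0)[param_v] %||% param_v,
                              proposal = prop_v, delta_e = de_v,
                              accepted = acc_v, energy = en_v,
                              best_energy = best_v),
       evaluations = steps + 1L)
}

# objective: rebuild the basic-mode assembly at the proposed parameters and
# score it. Equivalent to
#   interaction_energy(place_sidechains(build_assembly(s)$model,
#                                       max_passes = 0))$total
# but works on coordinate matrices with metadata precomputed once, so a
# Monte Carlo step costs a rebuild, not a tibble assembly. Side chains are
# placed at the primary rotamer (no clash cycling): the soft-core potential
# is finite in clashes and the objective stays a deterministic function of
# the parameters alone. The equivalence is asserted in the test-suite.
basic_mode_objective <- function(spec, constants = scoring_constants()) {
  base <- spec$helices[[1]]
  psign <- sign(base$pitch)
  fold <- spec$fold
  n_chain <- spec$oligomer_state
  shr <- vapply(spec$helices, function(h) h$super_helical_rotation, numeric(1))
  template <- place_sidechains(build_assembly(spec)$model, max_passes = 0)
  p <- match_atom_params(template)
  radius_v <- p$radius
  hydro_v <- p$hydrophobic > 0
  charge_v <- p$charge
  chain_v <- template$chain
  nres <- nchar(base$sequence)
  res3 <- seq_to_res3(base$sequence, collagen = fold == "collagen")
  regc <- strsplit(base$register, "")[[1]]
  t_ref <- if (length(regc) > 0 && any(regc == "a")) {
    which(regc == "a")[1] - 1
  } else 0
  # precompute, per chain, the output row of every atom and the residue
  # indices of each residue type
  row_of <- function(ch, rnum, at) {
    which(template$chain == ch & template$res_num == rnum &
            template$atom == at)
  }
  ids <- chain_ids(n_chain)
  types <- unique(res3)
  geom <- sidechain_geometry()
  layout <- lapply(ids, function(ch) {
    bb_rows <- lapply(BACKBONE_ATOMS, function(at)
      vapply(seq_len(nres), function(r) row_of(ch, r, at), integer(1)))
    names(bb_rows) <- BACKBONE_ATOMS
    sc <- lapply(types, function(tp) {
      res_idx <- which(res3 == tp)
      g <- geom[geom$res_name == tp, , drop = FALSE]
      at_rows <- lapply(g$atom, function(at)
        vapply(res_idx, function(r) row_of(ch, r, at), integer(1)))
      names(at_rows) <- g$atom
      list(res_idx = res_idx, rows = at_rows)
    })
    names(sc) <- types
    list(bb = bb_rows, sc = sc)
  })
  names(layout) <- ids
  chi_default <- lapply(types, function(tp) {
    rots <- ROTAMERS[[tp]][[1]]
    matrix(rots, nrow = 1)
  })
  names(chi_default) <- types
  n_atoms <- nrow(template)
  function(x) {
    xyz <- matrix(NA_real_, n_atoms, 3)
    for (ci in seq_len(n_chain)) {
      ch <- ids[ci]
      bb <- crick_chain_coords(nres, x[["radius"]], psign * x[["pitch"]],
                               x[["interface_angle"]], shr[ci],
                               base$z_shift, base$orientation, t_ref,
                               fold = fold)
      for (at in BACKBONE_ATOMS) xyz[layout[[ch]]$bb[[at]], ] <- bb[[at]]
      for (tp in types) {
        lay <- layout[[ch]]$sc[[tp]]
        if (length(lay$rows) == 0) next
        k <- length(lay$res_idx)
        bbm <- list(N = bb$N[lay$res_idx, , drop = FALSE],
                    CA = bb$CA[lay$res_idx, , drop = FALSE],
                    C = bb$C[lay$res_idx, , drop = FALSE])
        chis <- chi_default[[tp]][rep(1, k), , drop = FALSE]
        if (ncol(chis) == 0) chis <- matrix(0, k, 1)
        placed <- place_type_sidechain(tp, bbm, chis)
        for (at in names(placed)) xyz[lay$rows[[at]], ] <- placed[[at]]
      }
    }
    pair_energy_terms(xyz, chain_v, radius_v, hydro_v, charge_v,
                      constants)$total
  }
}

#' Optimize structural parameters of a basic-mode assembly
#'
#' Runs Metropolis Monte Carlo over (radius, pitch magnitude, interface
#' angle), rebuilding and re-scoring the full model at every step
#' (build -> place_sidechains -> interaction_energy). The objective places
#' side chains at the primary rotamer without clash cycling, keeping it a
#' deterministic smooth function of the parameters; the soft-core
#' potential is finite in clashes. Only basic-mode specifications can be
#' optimized, and requests are capped at `config$max_residues` residues
#' across all chains unless `allow_large`.
#'
#' @param spec A basic-mode [assembly_spec()].
#' @param config An [optimizer_config()].
#' @param allow_large Lift the residue cap (for local, off-web use).
#' @return A `coilr_optimization` object: `best_spec`, `best_parameters`,
#'   `best_energy`, `initial_energy`, `trace`, `seed`, `evaluations`. Has
#'   tidy()/glance() and autoplot() methods.
#' @export
#' @examples
#' \donttest{
#' p <- helix_params(radius = 7, pitch = -160, interface_angle = 10,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' spec <- assembly_spec(oligomer_state = 2, helices = p)
#' res <- optimize_parameters(spec, optimizer_config(steps = 50, seed = 1))
#' res$best_energy <= res$initial_energy
#' }
optimize_parameters <- function(spec, config = optimizer_config(),
                                allow_large = FALSE) {
  spec <- validate_spec(spec)
  if (spec$mode != "basic") {
    abort_validation(paste(
      "optimization is restricted to basic-mode specifications;",
      "rebuild the request in basic mode"))
  }
  total_res <- sum(vapply(spec$helices, function(h) nchar(h$sequence),
                          integer(1)))
  if (total_res == 0) {
    abort_validation("optimization needs sequences on the helices")
  }
  if (total_res > config$max_residues && !allow_large) {
    abort_validation(sprintf(
      "request totals %d residues, above the cap of %d (set allow_large = TRUE to override)",
      total_res, config$max_residues))
  }
  base <- spec$helices[[1]]
  x0 <- c(radius = base$radius, pitch = abs(base$pitch),
          interface_angle = base$interface_angle)
  res <- metropolis_run(basic_mode_objective(spec), x0,
                        step_sizes = config$step_sizes,
                        bounds = config$bounds,
                        steps = config$steps,
                        temperature = config$temperature,
                        cooling = config$cooling,
                        seed = config$seed,
                        reset_every = config$reset_every %||% Inf)
  psign <- sign(base$pitch)
  best <- base
  best$radius <- res$best_par[["radius"]]
  best$pitch <- psign * res$best_par[["pitch"]]
  best$interface_angle <- res$best_par[["interface_angle"]]
  structure(list(
    best_spec = assembly_spec("basic", spec$fold, spec$oligomer_state,
                              list(best)),
    best_parameters = tibble::tibble(
      radius = best$radius, pitch = best$pitch,
      interface_angle = best$interface_angle),
    best_energy = res$best_energy,
    initial_energy = res$initial_energy,
    trace = res$trace,
    seed = config$seed,
    evaluations = res$evaluations), class = "coilr_optimization")
}

#' @export
print.coilr_optimization <- function(x, ...) {
  cat(sprintf(
    "# Metropolis MC optimization: %d evaluations, energy %.3f -> %.3f (a.u.)\n",
    x$evaluations, x$initial_energy, x$best_energy))
  print(x$best_parameters)
  invisible(x)
}

#' @export
tidy.coilr_optimization <- function(x, ...) x$trace

#' @export
glance.coilr_optimization <- function(x, ...) {
  tibble::tibble(best_energy = x$best_energy,
                 initial_energy = x$initial_energy,
                 acceptance_rate = mean(x$trace$accepted),
                 evaluations = x$evaluations,
                 seed = x$seed)
}

#' Scan oligomeric states for a sequence
#'
#' Runs seeded restarts of [optimize_parameters()] at each oligomeric
#' state and compares the best interaction energy normalized per helix;
#' the predicted state is the argmin of the per-helix energy (the
#' normalization makes bundles of different size comparable).
#'
#' @param sequence One-letter sequence of one helix.
#' @param register Heptad register (default repeating "abcdefg").
#' @param n_range Integer vector of oligomeric states to scan (e.g.
#'   `2:6`).
#' @param config An [optimizer_config()]; restart `j` at state `n` uses
#'   seed `config$seed + 97 * n + j`.
#' @param restarts Seeded restarts per state (best kept).
#' @param pitch Starting pitch (A, signed).
#' @return A `coilr_scan` tibble: `n`, `best_energy`, `energy_per_helix`,
#'   `radius`, `pitch`, `interface_angle`, `predicted` (logical). The
#'   predicted state is also in the `predicted_state` attribute.
#' @export
scan_oligomer_states <- function(sequence, register = "",
                                 n_range = 2:6,
                                 config = optimizer_config(steps = 150),
                                 restarts = 3, pitch = -200) {
  if (length(n_range) == 0) {
    abort_domain("`n_range` must contain at least one oligomeric state")
  }
  rows <- lapply(n_range, function(n) {
    r_init <- 5 / sin(pi / n)   # ~10 A neighbour-helix separation
    h <- helix_params(radius = r_init, pitch = pitch, interface_angle = 26,
                      sequence = sequence, register = register)
    spec <- assembly_spec("basic", "coiled_coil", n, list(h))
    best <- NULL
    for (j in seq_len(restarts)) {
      cfg <- config
      cfg$seed <- config$seed + 97L * n + j
      res <- optimize_parameters(spec, cfg, allow_large = TRUE)
      if (is.null(best) || res$best_energy < best$best_energy) best <- res
    }
    tibble::tibble(n = n, best_energy = best$best_energy,
                   energy_per_helix = best$best_energy / n,
                   radius = best$best_parameters$radius,
                   pitch = best$best_parameters$pitch,
                   interface_angle = best$best_parameters$interface_angle)
  })
  out <- dplyr::bind_rows(rows)
  out$predicted <- out$energy_per_helix == min(out$energy_per_helix)
  class(out) <- c("coilr_scan", class(out))
  attr(out, "predicted_state") <- out$n[which.min(out$energy_per_helix)]
  out
}
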