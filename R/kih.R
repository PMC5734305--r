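# SOCKET-style knobs-into-holes packing detection and register assignment.
#
# A residue is a knob into a partner chain when at least four side-chain
# centers on that chain lie within the packing cutoff of its own side-chain
# center; the four nearest such residues form the hole. A knob is
# complementary when the partner chain in turn places a knob whose hole
# contains it.

#' Side-chain centers of a model
#'
#' The centroid of each residue's side-chain heavy atoms (including CB);
#' for glycine, the CA position.
#'
#' @param model An all-atom model tibble.
#' @return A tibble with one row per residue: `chain`, `res_num`,
#'   `res_name`, `x`, `y`, `z`.
#' @export
sidechain_centers <- function(model) {
  model <- as_model(model)
  sc <- model[!(model$atom %in% BACKBONE_ATOMS) | model$res_name == "GLY", ]
  sc <- sc[sc$res_name != "GLY" | sc$atom == "CA", ]
  # residues with no side-chain atoms at all (and not Gly) are an error
  all_res <- dplyr::distinct(model, .data$chain, .data$res_num, .data$res_name)
  have <- dplyr::distinct(sc, .data$chain, .data$res_num)
  missing <- dplyr::anti_join(all_res, have, by = c("chain", "res_num"))
  if (nrow(missing) > 0) {
    abort_validation(sprintf(
      "residue(s) without side-chain atoms (run place_sidechains() first): %s",
      paste(utils::head(paste0(missing$chain, missing$res_num), 5),
            collapse = ", ")))
  }
  dplyr::summarise(dplyr::group_by(sc, .data$chain, .data$res_num,
                                   .data$res_name),
                   x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                   .groups = "drop")
}

# local helix-axis direction per residue from the CA trace (central
# difference of CA positions, normalized; ends use one-sided differences)
local_axes <- function(model) {
  ca <- model[model$atom == "CA", ]
  ca <- ca[order(ca$chain, ca$res_num), ]
  out <- dplyr::group_modify(dplyr::group_by(ca, .data$chain), function(d, g) {
    m <- as.matrix(d[, c("x", "y", "z")])
    n <- nrow(m)
    lo <- pmax(seq_len(n) - 2L, 1L)
    hi <- pmin(seq_len(n) + 2L, n)
    ax <- normalize_rows(m[hi, , drop = FALSE] - m[lo, , drop = FALSE])
    d$ax <- ax[, 1]; d$ay <- ax[, 2]; d$az <- ax[, 3]
    d
  })
  dplyr::ungroup(out)
}

#' Detect knobs-into-holes packing
#'
#' @param model An all-atom model tibble with at least two chains.
#' @param cutoff Packing cutoff in Angstrom between side-chain centers
#'   (default 7.0, the classical SOCKET value).
#' @return A `coilr_kih` tibble with one row per knob: `knob_chain`,
#'   `knob_res`, `knob_name`, `hole_chain`, `hole_res` (list column of the
#'   four hole residue numbers), `complementarity` (`"isolated"` or
#'   `"complementary"`), `orientation` (`"parallel"`/`"antiparallel"` from
#'   the local helix-axis dot product) and `cutoff`. Sorted by knob chain
#'   and residue. The first and last residue of each chain are not knob
#'   candidates (insufficient hole context).
#' @export
#' @examples
#' p <- helix_params(radius = 4.9, pitch = -180, interface_angle = 26,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' m <- build_assembly(assembly_spec(oligomer_state = 2, helices = p))$model
#' kih <- find_kih(place_sidechains(m))
#' nrow(kih) > 0
find_kih <- function(model, cutoff = 7.0) {
  model <- as_model(model)
  if (dplyr::n_distinct(model$chain) < 2) {
    abort_analysis("knobs-into-holes analysis needs at least 2 chains")
  }
  if (model_is_backbone_only(model)) {
    abort_analysis("backbone-only model: run place_sidechains() first")
  }
  centers <- sidechain_centers(model)
  axes <- local_axes(model)
  centers <- dplyr::left_join(
    centers, axes[, c("chain", "res_num", "ax", "ay", "az")],
    by = c("chain", "res_num"))
  cxyz <- as.matrix(centers[, c("x", "y", "z")])
  nres <- nrow(centers)
  dmat <- as.matrix(stats::dist(cxyz))
  ends <- dplyr::group_by(centers, .data$chain)
  ends <- dplyr::mutate(ends, is_end = .data$res_num == min(.data$res_num) |
                          .data$res_num == max(.data$res_num))
  is_end <- dplyr::ungroup(ends)$is_end
  rows <- list()
  for (k in seq_len(nres)) {
    if (is_end[k]) next
    for (ch in setdiff(unique(centers$chain), centers$chain[k])) {
      idx <- which(centers$chain == ch)
      d <- dmat[k, idx]
      within <- which(d <= cutoff)
      if (length(within) >= 4) {
        hole_idx <- idx[within[order(d[within])[1:4]]]
        dot <- sum(c(centers$ax[k], centers$ay[k], centers$az[k]) *
                     colMeans(as.matrix(centers[hole_idx, c("ax", "ay", "az")])))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          knob_chain = centers$chain[k],
          knob_res = centers$res_num[k],
          knob_name = centers$res_name[k],
          hole_chain = ch,
          hole_res = list(sort(centers$res_num[hole_idx])),
          orientation = if (dot >= 0) "parallel" else "antiparallel",
          cutoff = cutoff)
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    knob_chain = character(), knob_res = integer(), knob_name = character(),
    hole_chain = character(), hole_res = list(), orientation = character(),
    cutoff = numeric())
  # complementarity: partner chain hosts a knob whose hole contains this one
  comp <- logical(nrow(out))
  if (nrow(out) > 0) {
    for (r in seq_len(nrow(out))) {
      back <- out[out$knob_chain == out$hole_chain[r] &
                    out$hole_chain == out$knob_chain[r], ]
      comp[r] <- any(vapply(back$hole_res, function(h)
        out$knob_res[r] %in% h, logical(1)))
    }
  }
  out$complementarity <- ifelse(comp, "complementary", "isolated")
  out <- out[order(out$knob_chain, out$knob_res), ]
  out <- out[, c("knob_chain", "knob_res", "knob_name", "hole_chain",
                 "hole_res", "complementarity", "orientation", "cutoff")]
  class(out) <- c("coilr_kih", class(out))
  attr(out, "centers") <- centers
  out
}

#' Assign heptad register from knobs-into-holes contacts
#'
#' Labels each knob `a` or `d` from its Crick angle in the fitted
#' super-helical frame (a sits within half a phase step of the core-facing
#' direction on the positive side, d on the negative side:
#' a in \[0, 51.4), d in \[-51.4, 0) degrees), then fills the remaining
#' positions of each chain by heptad periodicity. The confidence is the
#' fraction of labeled knobs consistent with the winning phase.
#'
#' @param contacts A `coilr_kih` table from [find_kih()].
#' @param model The same all-atom model.
#' @return A tibble with one row per chain: `chain`, `register` (string
#'   over a-g, or `NA` when the chain has fewer than 2 complementary
#'   knobs), `confidence`, `n_knobs`. Per-knob labels are attached as the
#'   `knob_labels` attribute.
#' @export
assign_register <- function(contacts, model) {
  model <- as_model(model)
  chains <- sort(unique(model$chain))
  crick <- tryCatch({
    fit <- measure_parameters(model)
    attr(fit, "crick_angles")
  }, error = function(e) NULL)
  half_step <- fold_constants("coiled_coil")$twist / 2   # 51.43 deg
  labels <- list()
  if (!is.null(crick) && nrow(contacts) > 0) {
    for (r in seq_len(nrow(contacts))) {
      kc <- contacts$knob_chain[r]; kr <- contacts$knob_res[r]
      ang <- crick$crick_angle[crick$chain == kc & crick$res_num == kr]
      if (length(ang) != 1) next    # chain not fitted (e.g. uncoiled)
      lab <- if (ang >= 0 && ang < half_step) "a"
      else if (ang >= -half_step && ang < 0) "d"
      else NA_character_
      labels[[length(labels) + 1L]] <- tibble::tibble(
        chain = kc, res_num = kr, label = lab, angle = ang,
        complementarity = contacts$complementarity[r])
    }
  }
  knob_labels <- if (length(labels) > 0) dplyr::bind_rows(labels) else
    tibble::tibble(chain = character(), res_num = integer(),
                   label = character(), angle = numeric(),
                   complementarity = character())
  rows <- lapply(chains, function(ch) {
    kl <- knob_labels[knob_labels$chain == ch & !is.na(knob_labels$label), ]
    ncomp <- sum(kl$complementarity == "complementary")
    if (nrow(kl) < 2 || ncomp < 2) {
      return(tibble::tibble(chain = ch, register = NA_character_,
                            confidence = NA_real_, n_knobs = nrow(kl)))
    }
    # each knob votes for the heptad phase that would put 'a' where the
    # geometry says: an a-knob at residue i backs phase (i-1) mod 7, a
    # d-knob backs (i-4) mod 7
    votes <- ifelse(kl$label == "a", (kl$res_num - 1L) %% 7L,
                    (kl$res_num - 4L) %% 7L)
    tab <- table(votes)
    phase <- as.integer(names(tab)[which.max(tab)])
    conf <- max(tab) / nrow(kl)
    nres <- max(model$res_num[model$chain == ch])
    reg <- paste(letters[((seq_len(nres) - 1L - phase) %% 7L) + 1L],
                 collapse = "")
    tibble::tibble(chain = ch, register = reg, confidence = conf,
                   n_knobs = nrow(kl))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "knob_labels") <- knob_labels
  out
}
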