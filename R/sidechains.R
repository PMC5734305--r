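# Side-chain placement: promote a backbone model to all-atom.
#
# The internal placer puts each residue's side chain at its single
# most-populated backbone-independent rotamer using ideal internal
# coordinates (shipped in extdata/sidechain_geometry.tsv), then greedily
# resolves steric clashes by cycling clashing residues to alternative
# rotamers. It exists so the full pipeline (build -> pack -> score) runs
# hermetically; an external side-chain packer can be hooked in instead.

sidechain_geometry <- function() {
  if (is.null(.coilr_cache$sc_geom)) {
    path <- system.file("extdata", "sidechain_geometry.tsv", package = "coilr")
    .coilr_cache$sc_geom <- utils::read.delim(path, comment.char = "#",
                                              stringsAsFactors = FALSE)
  }
  .coilr_cache$sc_geom
}

# Backbone-independent rotamer chi values (degrees). First entry is the
# most-populated rotamer; the rest are fallbacks for clash resolution.
ROTAMERS <- list(
  ARG = list(c(-65, 180, 180, 180), c(180, 180, 180, 180), c(-65, -80, 180, 180)),
  ASN = list(c(-65, -20), c(180, 0), c(65, -20)),
  ASP = list(c(-70, -15), c(180, 0), c(65, -15)),
  CYS = list(-65, 180, 65),
  GLN = list(c(-65, 180, 0), c(180, 65, 0), c(180, 180, 0)),
  GLU = list(c(-65, 180, -10), c(180, 180, 0), c(-65, -80, 0)),
  HIS = list(c(-65, -70), c(180, 60), c(65, -70)),
  ILE = list(c(-65, 170), c(-65, -60), c(180, 165)),
  LEU = list(c(-65, 175), c(180, 65), c(-85, 65)),
  LYS = list(c(-65, 180, 180, 180), c(180, 180, 180, 180), c(-65, -80, 180, 180)),
  MET = list(c(-65, 180, 75), c(180, 180, 180), c(-65, -80, -70)),
  PHE = list(c(-65, -85), c(180, 80), c(65, -85)),
  SER = list(65, -65, 180),
  THR = list(65, -60, 180),
  TRP = list(c(-65, 95), c(180, -105), c(65, 95)),
  TYR = list(c(-65, -85), c(180, 80), c(65, -85)),
  VAL = list(175, -60, 65),
  ALA = list(numeric(0)),
  GLY = list(numeric(0)),
  PRO = list(numeric(0)),
  HYP = list(numeric(0))
)

# Place side-chain atoms for a set of residues of one type, vectorized over
# residues. `bb` is a named list of k x 3 matrices (N, CA, C); `chis` a
# k x n_chi matrix of torsion values. Returns a named list of k x 3
# matrices, one per side-chain atom, in placement order.
place_type_sidechain <- function(res_name, bb, chis) {
  rows <- sidechain_geometry()
  rows <- rows[rows$res_name == res_name, , drop = FALSE]
  if (nrow(rows) == 0) return(list())
  pos <- bb
  out <- list()
  for (j in seq_len(nrow(rows))) {
    r <- rows[j, ]
    tors <- if (r$tors_kind == "chi") {
      chis[, r$chi_idx] + r$tors_value
    } else {
      rep(r$tors_value, nrow(bb$CA))
    }
    p <- nerf_place(pos[[r$ref1]], pos[[r$ref2]], pos[[r$ref3]],
                    r$bond, r$angle, tors)
    pos[[r$atom]] <- p
    out[[r$atom]] <- p
  }
  out
}

residue_keys <- function(model) paste(model$chain, model$res_num, sep = "\r")

# inter-residue heavy-atom clash pairs below `cutoff`, ignoring directly
# bonded backbone neighbours (C_i - N_{i+1})
clash_pairs <- function(model, cutoff) {
  xyz <- model_xyz(model)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    i <- idx[, 1]; j <- idx[, 2]
    same_res <- model$chain[i] == model$chain[j] &
      model$res_num[i] == model$res_num[j]
    peptide <- model$chain[i] == model$chain[j] &
      ((model$atom[i] == "C" & model$atom[j] == "N" &
          model$res_num[j] == model$res_num[i] + 1L) |
         (model$atom[j] == "C" & model$atom[i] == "N" &
            model$res_num[i] == model$res_num[j] + 1L))
    idx <- idx[!same_res & !peptide, , drop = FALSE]
  }
  tibble::tibble(i = idx[, 1], j = idx[, 2], dist = d[idx])
}

#' Place side chains on a backbone model
#'
#' Promotes a backbone-only model to all heavy atoms. The
#' `"ideal_rotamer"` strategy places every residue at its most-populated
#' backbone-independent rotamer by ideal internal geometry, then runs up to
#' `max_passes` greedy passes cycling clashing residues (inter-residue
#' heavy-atom pairs closer than `clash_cutoff`) through alternative
#' rotamers. The `"external_packer"` strategy round-trips the model through
#' a SCWRL4-compatible command-line packer (`packer -i in.pdb -o out.pdb`).
#' Calling this on a model that already has side-chain atoms is an error
#' (no silent re-packing).
#'
#' @param model A backbone model tibble.
#' @param strategy `"ideal_rotamer"` or `"external_packer"`.
#' @param clash_cutoff Heavy-atom clash distance, Angstrom.
#' @param max_passes Greedy clash-resolution passes.
#' @param packer Path or name of the external packer binary (defaults to
#'   `getOption("coilr.packer")`).
#' @return An all-atom model tibble; unresolved clash pairs (if any) are
#'   recorded in the `clashes` attribute.
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' m <- build_assembly(assembly_spec(oligomer_state = 2, helices = p))$model
#' aa <- place_sidechains(m)
#' table(aa$atom %in% c("N", "CA", "C", "O"))
place_sidechains <- function(model,
                             strategy = c("ideal_rotamer", "external_packer"),
                             clash_cutoff = 2.0, max_passes = 3,
                             packer = getOption("coilr.packer")) {
  model <- as_model(model)
  strategy <- match.arg(strategy)
  if (!model_is_backbone_only(model)) {
    abort_validation(paste(
      "model already carries side-chain atoms; place_sidechains() refuses",
      "to re-pack (rebuild the backbone first)"))
  }
  by_res <- dplyr::distinct(model, .data$chain, .data$res_num, .data$res_name)
  unknown <- setdiff(unique(by_res$res_name), names(ROTAMERS))
  if (length(unknown) > 0) {
    abort_validation(sprintf("unknown residue type(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  missing_bb <- dplyr::count(model, .data$chain, .data$res_num)
  if (any(missing_bb$n < 4)) {
    abort_validation("every residue needs complete backbone atoms N, CA, C, O")
  }
  if (strategy == "external_packer") {
    return(run_external_packer(model, packer))
  }

  rot_idx <- stats::setNames(rep(1L, nrow(by_res)),
                             paste(by_res$chain, by_res$res_num, sep = "\r"))
  place_all <- function(rot_idx) {
    sc_rows <- list()
    for (rn in unique(by_res$res_name)) {
      sub <- by_res[by_res$res_name == rn, , drop = FALSE]
      keys <- paste(sub$chain, sub$res_num, sep = "\r")
      bb <- lapply(c("N", "CA", "C"), function(at) {
        rows <- model[model$atom == at, ]
        m <- as.matrix(rows[match(keys, residue_keys(rows)), c("x", "y", "z")])
        m
      })
      names(bb) <- c("N", "CA", "C")
      rots <- ROTAMERS[[rn]]
      nchi <- length(rots[[1]])
      chis <- matrix(0, nrow(sub), max(nchi, 1))
      for (k in seq_len(nrow(sub))) {
        ri <- ((rot_idx[keys[k]] - 1L) %% length(rots)) + 1L
        if (nchi > 0) chis[k, seq_len(nchi)] <- rots[[ri]]
      }
      placed <- place_type_sidechain(rn, bb, chis)
      for (at in names(placed)) {
        sc_rows[[paste(rn, at)]] <- tibble::tibble(
          chain = sub$chain, res_num = sub$res_num, res_name = rn,
          atom = at, element = substr(at, 1, 1),
          x = placed[[at]][, 1], y = placed[[at]][, 2], z = placed[[at]][, 3])
      }
    }
    full <- dplyr::bind_rows(c(list(model), sc_rows))
    # stable atom order: backbone first, then side chain in placement order
    ord <- order(match(full$chain, unique(model$chain)), full$res_num,
                 match(full$atom, c(BACKBONE_ATOMS,
                                    unique(sidechain_geometry()$atom))))
    as_model(full[ord, ])
  }

  full <- place_all(rot_idx)
  for (pass in seq_len(max_passes)) {
    cl <- clash_pairs(full, clash_cutoff)
    if (nrow(cl) == 0) break
    keys_i <- residue_keys(full)[cl$i]
    keys_j <- residue_keys(full)[cl$j]
    counts <- sort(table(c(keys_i, keys_j)), decreasing = TRUE)
    moved <- FALSE
    for (key in names(counts)) {
      rn <- by_res$res_name[match(key, paste(by_res$chain, by_res$res_num,
                                             sep = "\r"))]
      if (length(ROTAMERS[[rn]]) > 1 &&
          length(ROTAMERS[[rn]][[1]]) > 0) {
        rot_idx[key] <- rot_idx[key] + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
    full <- place_all(rot_idx)
  }
  leftover <- clash_pairs(full, clash_cutoff)
  attr(full, "clashes") <- leftover
  full
}

run_external_packer <- function(model, packer) {
  if (is.null(packer) || !nzchar(Sys.which(packer))) {
    abort_io(sprintf(
      "external packer %s not found on PATH; set options(coilr.packer=) or use strategy = 'ideal_rotamer'",
      if (is.null(packer)) "(unset)" else sprintf("'%s'", packer)))
  }
  fin <- tempfile(fileext = ".pdb")
  fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_pdb(model, fin)
  status <- suppressWarnings(
    system2(packer, c("-i", fin, "-o", fout), stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout)) {
    abort_io(sprintf("external packer failed (exit %d): %s", code,
                     paste(utils::tail(status, 5), collapse = "; ")))
  }
  read_pdb(fout)
}
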