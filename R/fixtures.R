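# Canonical example specifications: a fixture generator covering the
# standard coiled-coil and collagen topologies. Every fixture builds
# without warnings and is used throughout the test-suite.

fixture_cc_seq <- function(heptads) strrep("IAALKQE", heptads)
fixture_cc_reg <- function(heptads) strrep("abcdefg", heptads)

# homotypic defaults per oligomeric state: the engine's canonical states,
# i.e. the interaction-energy-optimal parameters for the Ile@a/Leu@d
# heptad under the default potential (radius grows with the bundle so
# neighbouring helices pack at contact)
HOMOTYPIC_PARAMS <- list(
  `2` = list(radius = 4.9, pitch = -130, interface_angle = 19),
  `3` = list(radius = 6.4, pitch = -170, interface_angle = 16),
  `4` = list(radius = 6.8, pitch = -213, interface_angle = 15),
  `5` = list(radius = 10.0, pitch = -390, interface_angle = 16),
  `6` = list(radius = 11.9, pitch = -480, interface_angle = 16),
  `7` = list(radius = 13.5, pitch = -500, interface_angle = 18)
)

#' Canonical example assembly specifications
#'
#' A named collection of complete build requests covering the standard
#' topologies: parallel homotypic dimer through heptamer, an antiparallel
#' homodimer, a slipped heptamer, acidic/basic heterodimers (equal-length
#' and length-mismatched), and homotrimeric/heterotrimeric collagens
#' (three symmetric strands with the glycine edge facing the core).
#'
#' @param name Optional fixture name; omit to get the full named list.
#' @return A `coilr_spec` (when `name` is given) or a named list of specs.
#' @export
#' @examples
#' names(example_specs())
#' example_specs("cc-dimer")
example_specs <- function(name = NULL) {
  specs <- list()
  hept <- 4
  state_names <- c(`2` = "dimer", `3` = "trimer", `4` = "tetramer",
                   `5` = "pentamer", `6` = "hexamer", `7` = "heptamer")
  for (n in 2:7) {
    par <- HOMOTYPIC_PARAMS[[as.character(n)]]
    h <- helix_params(radius = par$radius, pitch = par$pitch,
                      interface_angle = par$interface_angle,
                      sequence = fixture_cc_seq(hept),
                      register = fixture_cc_reg(hept))
    specs[[paste0("cc-", state_names[[as.character(n)]])]] <-
      assembly_spec("basic", "coiled_coil", n, list(h))
  }
  # antiparallel homodimer
  ap <- lapply(1:2, function(i) {
    helix_params(radius = 4.9, pitch = -130, interface_angle = 19,
                 super_helical_rotation = default_shr(i, 2),
                 orientation = if (i == 1) "parallel" else "antiparallel",
                 sequence = fixture_cc_seq(hept),
                 register = fixture_cc_reg(hept), helix_index = i)
  })
  specs[["cc-dimer-antiparallel"]] <-
    assembly_spec("advanced", "coiled_coil", 2, ap)
  # slipped heptamer: progressive one-Angstrom axial offsets
  par7 <- HOMOTYPIC_PARAMS[["7"]]
  sl <- lapply(1:7, function(i) {
    helix_params(radius = par7$radius, pitch = par7$pitch,
                 interface_angle = par7$interface_angle,
                 super_helical_rotation = default_shr(i, 7),
                 z_shift = (i - 1) * 1.0,
                 sequence = fixture_cc_seq(hept),
                 register = fixture_cc_reg(hept), helix_index = i)
  })
  specs[["cc-heptamer-slipped"]] <-
    assembly_spec("advanced", "coiled_coil", 7, sl)
  # acidic/basic heterodimers
  acid <- strrep("IAALEQE", hept)
  base <- strrep("IAALKQK", hept)
  hd <- function(seqs, heptads) {
    lapply(seq_along(seqs), function(i) {
      helix_params(radius = 4.9, pitch = -130, interface_angle = 19,
                   super_helical_rotation = default_shr(i, length(seqs)),
                   sequence = seqs[[i]],
                   register = fixture_cc_reg(heptads[[i]]), helix_index = i)
    })
  }
  specs[["cc-heterodimer-a4b4"]] <-
    assembly_spec("advanced", "coiled_coil", 2, hd(list(acid, base), c(4, 4)))
  specs[["cc-heterodimer-a3b4"]] <-
    assembly_spec("advanced", "coiled_coil", 2,
                  hd(list(strrep("IAALEQE", 3), base), c(3, 4)))
  # collagens: three symmetric strands; the -90 deg phase reference points
  # the glycine edge of each strand at the triple-helical core
  col <- function(seqs) {
    lapply(seq_along(seqs), function(i) {
      helix_params(radius = 3.0, pitch = 85, interface_angle = -90,
                   super_helical_rotation = default_shr(i, 3),
                   sequence = seqs[[i]], helix_index = i)
    })
  }
  gpo <- strrep("GPO", 8)
  specs[["collagen-homotrimer"]] <-
    assembly_spec("advanced", "collagen", 3, col(list(gpo, gpo, gpo)))
  specs[["collagen-heterotrimer"]] <-
    assembly_spec("advanced", "collagen", 3,
                  col(list(gpo, strrep("GPP", 8), strrep("GAO", 8))))
  if (!is.null(name)) {
    if (!name %in% names(specs)) {
      abort_validation(sprintf("unknown example '%s'; available: %s", name,
                               paste(names(specs), collapse = ", ")))
    }
    return(specs[[name]])
  }
  specs
}
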