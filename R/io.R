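# Fixed-column PDB v3.3 reading and writing, and the combined analysis
# report used by the command-line interface.

HETATM_RESIDUES <- c("HYP")

#' Write a model as a PDB file
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records (hydroxyproline as
#' HETATM with residue name HYP), a TER record between chains, and END.
#' Occupancy 1.00, B-factor 0.00, residue numbering as stored (1-based per
#' chain for built models).
#'
#' @param model A model tibble.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  model <- as_model(model)
  if (any(model$res_num > 9999)) {
    abort_io("PDB residue numbers overflow the 4-column field (> 9999)")
  }
  if (nrow(model) + dplyr::n_distinct(model$chain) > 99999) {
    abort_io("PDB atom serials overflow the 5-column field (> 99999)")
  }
  lines <- character(0)
  serial <- 0L
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, ]
    rec <- ifelse(sub$res_name %in% HETATM_RESIDUES, "HETATM", "ATOM  ")
    serials <- serial + seq_len(nrow(sub))
    serial <- serial + nrow(sub) + 1L   # TER consumes a serial
    atom_field <- ifelse(nchar(sub$atom) < 4, sprintf(" %-3s", sub$atom),
                         sprintf("%-4s", sub$atom))
    lines <- c(lines, sprintf(
      "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serials, atom_field, sub$res_name, substr(ch, 1, 1), sub$res_num,
      sub$x, sub$y, sub$z, 1.0, 0.0, sub$element))
    last <- nrow(sub)
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serials[last] + 1L, sub$res_name[last],
                              substr(ch, 1, 1), sub$res_num[last]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB file into a model tibble
#'
#' Parses fixed-column ATOM/HETATM records; chains are taken from the
#' chain-id column, with TER-separated segments sharing a chain id kept
#' distinct by suffixing. Malformed records raise an error naming the line
#' number.
#'
#' @param path Source file path.
#' @return A model tibble (see [as_model()]).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(keep)) abort_io(sprintf("no ATOM/HETATM records in %s", path))
  idx <- which(keep)
  txt <- lines[keep]
  short <- nchar(txt) < 54
  if (any(short)) {
    abort_io(sprintf("malformed ATOM/HETATM record at line %d (too short)",
                     idx[which(short)[1]]))
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(txt, from, to)))
    if (anyNA(v)) {
      abort_io(sprintf("malformed %s field at line %d",
                       what, idx[which(is.na(v))[1]]))
    }
    v
  }
  df <- tibble::tibble(
    chain = trimws(substr(txt, 22, 22)),
    res_num = as.integer(num(23, 26, "residue number")),
    res_name = trimws(substr(txt, 18, 20)),
    atom = trimws(substr(txt, 13, 16)),
    element = trimws(substr(txt, 77, 78)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"))
  df$element[df$element == ""] <- substr(df$atom[df$element == ""], 1, 1)
  df <- df[df$element != "H", ]
  as_model(df)
}

#' Combined analysis report for a model
#'
#' Runs the three analysis stages — super-helical parameter fitting,
#' knobs-into-holes detection (with register assignment) and the
#' inter-chain interaction energy — and collects them into one report, the
#' JSON form of which is the CLI's `analyze` output.
#'
#' @param model A model tibble; backbone-only models get side chains
#'   placed first (ideal rotamers).
#' @param kih_cutoff Packing cutoff for [find_kih()], Angstrom.
#' @return A list of class `coilr_report` with elements `schema_version`,
#'   `parameters` (the [measure_parameters()] tibble), `kih` (contact
#'   table), `register` (per-chain assignment), `energy` (breakdown list).
#' @export
analyze_model <- function(model, kih_cutoff = 7.0) {
  model <- as_model(model)
  if (model_is_backbone_only(model)) {
    model <- place_sidechains(model)
  }
  fit <- measure_parameters(model)
  kih <- find_kih(model, cutoff = kih_cutoff)
  reg <- assign_register(kih, model)
  en <- interaction_energy(model)
  structure(list(schema_version = "1.0",
                 parameters = fit, kih = kih, register = reg,
                 energy = en), class = "coilr_report")
}

#' Serialize an analysis report as JSON
#'
#' @param report A `coilr_report` from [analyze_model()].
#' @return A JSON string (schema version 1.0).
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "coilr_report"))
  kih <- tibble::as_tibble(report$kih)
  kih$hole_res <- vapply(kih$hole_res, paste, character(1), collapse = ",")
  jsonlite::toJSON(list(
    schema_version = report$schema_version,
    parameters = tibble::as_tibble(report$parameters),
    kih = kih,
    register = tibble::as_tibble(report$register),
    energy = report$energy[c("steric", "desolvation", "charge", "total",
                             "pairs")]
  ), auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
}

#' @export
print.coilr_report <- function(x, ...) {
  cat(sprintf("# coilr analysis report (schema %s)\n", x$schema_version))
  print(x$parameters)
  cat(sprintf("knobs-into-holes contacts: %d\n", nrow(x$kih)))
  print(x$energy)
  invisible(x)
}
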