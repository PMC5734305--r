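# Assembly specification, validation and full-assembly building.

#' Full build request for a coiled coil or collagen triple helix
#'
#' @param mode `"basic"` (one symmetric parameter set replicated over all
#'   helices with [default_shr()] offsets) or `"advanced"` (independent
#'   parameters per helix).
#' @param fold `"coiled_coil"` or `"collagen"`. Collagen assemblies are
#'   locked to three strands.
#' @param oligomer_state Number of helices, `n >= 2`.
#' @param helices A single [helix_params()] (basic mode) or a list with one
#'   entry per helix (advanced mode).
#' @return A list of class `coilr_spec`. Validate and normalize with
#'   [validate_spec()].
#' @export
#' @examples
#' p <- helix_params(radius = 4.9, pitch = -180,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' assembly_spec(oligomer_state = 2, helices = p)
assembly_spec <- function(mode = c("basic", "advanced"),
                          fold = c("coiled_coil", "collagen"),
                          oligomer_state,
                          helices) {
  mode <- match.arg(mode)
  fold <- match.arg(fold)
  if (inherits(helices, "coilr_helix_params")) helices <- list(helices)
  structure(list(mode = mode, fold = fold,
                 oligomer_state = as.integer(oligomer_state),
                 helices = helices),
            class = "coilr_spec")
}

#' Validate and normalize an assembly specification
#'
#' Enforces the build-mode contracts: oligomer state at least 2 (exactly 3
#' for collagen), `O` (hydroxyproline) only in collagen sequences, register
#' and sequence of equal length, and — in basic mode — replication of helix
#' 1's parameters over all helices with symmetric [default_shr()] offsets.
#' A missing register on a coiled-coil helix with a sequence is
#' auto-assigned as a repeating "abcdefg" (with a warning recorded in the
#' build report).
#'
#' @param spec An [assembly_spec()].
#' @return The normalized spec, with one `helix_params` per chain and a
#'   `warnings` attribute listing any normalizations applied.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "coilr_spec")) {
    abort_validation("`spec` must be created with assembly_spec()")
  }
  n <- spec$oligomer_state
  if (is.na(n) || n < 2) {
    abort_validation(sprintf("oligomer state must be >= 2, got %s", n))
  }
  if (spec$fold == "collagen" && n != 3) {
    abort_validation(sprintf(
      "collagen assemblies are locked to an oligomeric state of 3, got %d", n))
  }
  warnings <- character()
  helices <- spec$helices
  if (!all(vapply(helices, inherits, logical(1), "coilr_helix_params"))) {
    abort_validation("every element of `helices` must be a helix_params() object")
  }
  if (spec$mode == "basic") {
    if (length(helices) != 1 && length(helices) != n) {
      abort_validation(sprintf(
        "basic mode takes one helix parameter set (or %d identical ones), got %d",
        n, length(helices)))
    }
    base <- helices[[1]]
    if (base$orientation != "parallel") {
      abort_validation("basic mode builds parallel assemblies only")
    }
    helices <- lapply(seq_len(n), function(i) {
      h <- base
      h$super_helical_rotation <- norm_angle(default_shr(i, n))
      h$helix_index <- i
      h
    })
  } else {
    if (length(helices) != n) {
      abort_validation(sprintf(
        "advanced mode needs %d helix parameter sets, got %d", n, length(helices)))
    }
    helices <- lapply(seq_len(n), function(i) {
      h <- helices[[i]]
      h$helix_index <- i
      h
    })
  }
  collagen <- spec$fold == "collagen"
  helices <- lapply(helices, function(h) {
    if (nzchar(h$sequence)) {
      seq_to_res3(h$sequence, collagen = collagen)  # validates characters
    }
    if (!collagen && nzchar(h$sequence) && !nzchar(h$register)) {
      h$register <- substr(strrep("abcdefg", ceiling(nchar(h$sequence) / 7)),
                           1, nchar(h$sequence))
      warnings <<- c(warnings, sprintf(
        "helix %d: register auto-assigned as repeating 'abcdefg'", h$helix_index))
    }
    h
  })
  out <- assembly_spec(spec$mode, spec$fold, n, helices)
  attr(out, "warnings") <- warnings
  out
}

#' Build an assembly from a specification
#'
#' Validates the spec, then builds one chain per helix (chain ids A, B, C,
#' ..., then AA, AB, ... past 26 chains) with that helix's independent
#' parameters, threading residue identities from the sequence.
#'
#' @param spec An [assembly_spec()].
#' @param n_residues Residues per chain when sequences are absent;
#'   otherwise each chain uses its own sequence length.
#' @return A list with `model` (the backbone model tibble) and `report`
#'   (spec echo, per-chain residue counts, warnings, and the
#'   secondary-structure constants used).
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200,
#'                   sequence = strrep("IAALKQE", 4),
#'                   register = strrep("abcdefg", 4))
#' built <- build_assembly(assembly_spec(oligomer_state = 2, helices = p))
#' built$report$residue_counts
build_assembly <- function(spec, n_residues = NULL) {
  spec <- validate_spec(spec)
  n <- spec$oligomer_state
  ids <- chain_ids(n)
  builder <- if (spec$fold == "collagen") build_collagen_strand else build_helix_backbone
  chains <- lapply(seq_len(n), function(i) {
    h <- spec$helices[[i]]
    nres <- if (nzchar(h$sequence)) nchar(h$sequence) else n_residues
    tryCatch(builder(h, nres, chain_id = ids[i]),
             error = function(e) {
               rlang::abort(sprintf("chain %s (helix %d): %s", ids[i], i,
                                    conditionMessage(e)),
                            class = "coilr_build_error", parent = e)
             })
  })
  model <- as_model(dplyr::bind_rows(chains))
  report <- list(
    spec = spec,
    residue_counts = stats::setNames(
      vapply(chains, function(m) max(m$res_num), integer(1)), ids),
    warnings = attr(spec, "warnings") %||% character(),
    constants = fold_constants(spec$fold)
  )
  list(model = model, report = report)
}

# ---- JSON (de)serialization of specs ------------------------------------

SPEC_KEYS <- c("mode", "fold", "oligomer_state", "helices")
HELIX_KEYS <- c("radius", "pitch", "interface_angle", "super_helical_rotation",
                "z_shift", "orientation", "sequence", "register")

coerce_num <- function(x, key, path) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1 || is.na(v)) {
    abort_validation(sprintf("%s: `%s` must be a number, got %s",
                             path, key, deparse(x)))
  }
  v
}

#' Read or write an assembly spec as JSON
#'
#' The JSON document mirrors the build request: `{mode, fold,
#' oligomer_state, helices: [{radius, pitch, interface_angle,
#' super_helical_rotation, z_shift, orientation, sequence, register}]}`.
#' Numeric fields given as strings (e.g. `"5.0"`) are coerced; unknown keys
#' are rejected with the list of accepted keys; missing required keys are
#' reported by name with their path.
#'
#' @param x A file path or a JSON string (for `spec_from_json`); a
#'   `coilr_spec` (for `spec_to_json`).
#' @return `spec_from_json()` returns a `coilr_spec`; `spec_to_json()` a
#'   JSON string.
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200, sequence = "IAALKQE")
#' json <- spec_to_json(assembly_spec(oligomer_state = 2, helices = p))
#' identical(spec_to_json(spec_from_json(json)), json)
spec_from_json <- function(x) {
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyDataFrame = FALSE, simplifyVector = TRUE),
    error = function(e) abort_validation(
      sprintf("malformed JSON document: %s", conditionMessage(e))))
  unknown <- setdiff(names(doc), SPEC_KEYS)
  if (length(unknown) > 0) {
    abort_validation(sprintf("unknown key(s) %s; accepted keys: %s",
                             paste(unknown, collapse = ", "),
                             paste(SPEC_KEYS, collapse = ", ")))
  }
  for (key in c("mode", "oligomer_state", "helices")) {
    if (is.null(doc[[key]])) {
      abort_validation(sprintf("missing required key `%s`", key))
    }
  }
  fold <- doc$fold %||% "coiled_coil"
  helices <- lapply(seq_along(doc$helices), function(i) {
    h <- doc$helices[[i]]
    path <- sprintf("helices[%d]", i)
    unknown <- setdiff(names(h), HELIX_KEYS)
    if (length(unknown) > 0) {
      abort_validation(sprintf("%s: unknown key(s) %s; accepted keys: %s",
                               path, paste(unknown, collapse = ", "),
                               paste(HELIX_KEYS, collapse = ", ")))
    }
    for (key in c("radius", "pitch")) {
      if (is.null(h[[key]])) {
        abort_validation(sprintf("%s: missing required key `%s`", path, key))
      }
    }
    helix_params(
      radius = coerce_num(h$radius, "radius", path),
      pitch = coerce_num(h$pitch, "pitch", path),
      interface_angle = coerce_num(h$interface_angle %||% 26,
                                   "interface_angle", path),
      super_helical_rotation = coerce_num(h$super_helical_rotation %||% 0,
                                          "super_helical_rotation", path),
      z_shift = coerce_num(h$z_shift %||% 0, "z_shift", path),
      orientation = h$orientation %||% "parallel",
      sequence = h$sequence %||% "",
      register = h$register %||% "",
      helix_index = i)
  })
  assembly_spec(doc$mode, fold, coerce_num(doc$oligomer_state,
                                           "oligomer_state", "document"),
                helices)
}

#' @rdname spec_from_json
#' @param spec A `coilr_spec`.
#' @export
spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "coilr_spec"))
  doc <- list(
    mode = spec$mode,
    fold = spec$fold,
    oligomer_state = spec$oligomer_state,
    helices = lapply(spec$helices, function(h) h[HELIX_KEYS])
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @export
print.coilr_spec <- function(x, ...) {
  cat(sprintf("# coilr assembly spec: %s %s, n = %d, %d helix parameter set(s)\n",
              x$mode, x$fold, x$oligomer_state, length(x$helices)))
  invisible(x)
}
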