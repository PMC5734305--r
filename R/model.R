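#' Atom-record structure models
#'
#' A structure model in coilr is a tibble of atom records with one row per
#' atom and columns `chain`, `res_num`, `res_name`, `atom`, `element`, `x`,
#' `y`, `z` (coordinates in Angstrom, right-handed frame, super-helical axis
#' along +z for freshly built models). The class `coilr_model` marks a tibble
#' that has passed this shape check; all analysis functions accept any data
#' frame with these columns.
#'
#' @param df A data frame of atom records.
#' @return `as_model()` returns the input as a validated `coilr_model`
#'   tibble; `is_model()` returns a logical scalar.
#' @export
#' @examples
#' p <- helix_params(radius = 5, pitch = -200, sequence = "IAALKQE")
#' m <- build_helix_backbone(p, 7)
#' is_model(m)
as_model <- function(df) {
  required <- c("chain", "res_num", "res_name", "atom", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_validation(sprintf("atom table is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (!"element" %in% names(df)) {
    df$element <- substr(df$atom, 1, 1)
  }
  df$res_num <- as.integer(df$res_num)
  class(df) <- unique(c("coilr_model", class(df)))
  df
}

#' @rdname as_model
#' @export
is_model <- function(df) {
  inherits(df, "coilr_model")
}

model_xyz <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

set_model_xyz <- function(model, xyz) {
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

#' Apply a rigid-body transform to a model
#'
#' Rotates and translates every atom. Used to re-frame models and, in tests,
#' to assert rigid-motion invariance of analysis results.
#'
#' @param model A model tibble (see [as_model()]).
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric translation (Angstrom).
#' @return The transformed model tibble.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model <- as_model(model)
  set_model_xyz(model, rigid_transform(model_xyz(model), rotation, translation))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

model_is_backbone_only <- function(model) {
  all(model$atom %in% BACKBONE_ATOMS)
}

chain_ids <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  # two-character ids beyond 26 chains: AA, AB, ...
  extra <- n - 26
  two <- paste0(rep(LETTERS, each = 26), LETTERS)
  c(LETTERS, two[seq_len(extra)])
}

#' @export
print.coilr_model <- function(x, ...) {
  nres <- dplyr::n_distinct(paste(x$chain, x$res_num))
  cat(sprintf("# coilr model: %d chain(s), %d residues, %d atoms\n",
              dplyr::n_distinct(x$chain), nres, nrow(x)))
  NextMethod()
}
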