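#' @keywords internal
#' @noRd
`%||%` <- rlang::`%||%`

# panel columns that are identifiers, not measured variables
.panel_id_cols <- c("subject_id", "group", "day", "beep")

#' @noRd
panel_variables <- function(panel) {
  setdiff(names(panel), .panel_id_cols)
}

#' @noRd
check_variables <- function(requested, available, where = "panel") {
  missing <- setdiff(requested, available)
  if (length(missing) > 0) {
    abort(sprintf(
      "Variable(s) %s not found in %s. Available: %s.",
      paste0("'", missing, "'", collapse = ", "), where,
      paste(available, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' @noRd
spectral_radius <- function(m) {
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}
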