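#' Steady-state fitting targets
#'
#' Literature-derived average activities the fitted sham model must hold at
#' rest: LC 2.3 Hz, prefrontal NE 0.4 pg, mPFC 2.05 Hz, NTS 1.85 Hz,
#' accumbal NE 0.4 pg, NAcc 1.55 Hz. Shipped as a packaged JSON fixture and
#' overridable with a user file of the same shape.
#'
#' @param path optional path to a JSON file mapping the six state names to
#'   positive values; default the packaged fixture.
#' @return Named numeric vector of length 6 in state order
#'   `[LC, NE_mPFC, mPFC, NTS, NE_NAcc, NAcc]`.
#' @export
steady_state_targets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "steady_state_targets.json",
                        package = "necsim", mustWork = TRUE)
  }
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(STATE_NAMES, names(v))
  if (length(missing)) {
    stop("targets file is missing: ", paste(missing, collapse = ", "))
  }
  tg <- vapply(v[STATE_NAMES], as.numeric, numeric(1))
  if (any(!is.finite(tg)) || any(tg <= 0)) {
    stop("all six steady-state targets must be finite and strictly positive")
  }
  tg
}
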