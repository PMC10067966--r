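#' Serialize fitted encoding models as JSON
#'
#' Writes the per-neuron coefficients (tuning weights with their bin edges,
#' filter coefficients, baselines and hyperparameters) to a JSON file, e.g.
#' for recovery tests or archiving alongside a trial table.
#'
#' @param fits A `gam_fit` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gam_json <- function(fits, path) {
  if (inherits(fits, "gam_fit")) fits <- list(fits)
  out <- lapply(fits, function(f) {
    list(neuron = f$neuron,
         baseline = f$b,
         hyperparams = unclass(f$hp),
         coupled = f$coupled,
         tuning = lapply(f$tuning, function(tt)
           list(weights = tt$weights, edges = tt$edges)),
         event = lapply(f$event, `[[`, "coef"),
         kernel = lapply(f$kernel, `[[`, "coef"),
         history = if (is.null(f$history)) NULL else f$history$coef,
         coupling = lapply(f$coupling, function(cp)
           list(from = cp$from, coef = cp$coef)))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
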