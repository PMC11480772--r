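## Umbrella window sets ---------------------------------------------------

#' Build an umbrella window set
#'
#' A window set couples one bias definition per window with the reaction
#' coordinate samples collected under that bias, at a shared temperature.
#'
#' @param biases list of [bias_potential()], one per window; centers must be
#'   strictly monotone.
#' @param samples list of numeric sample vectors, one per window.
#' @param temperature simulation temperature in K (shared by all windows).
#' @param coordinate_id a label for the reaction coordinate (e.g.
#'   `"com_separation"`).
#' @param seed optional integer seed recorded as provenance.
#' @return An object of class `bindfe_window_set`.
#' @export
umbrella_window_set <- function(biases, samples, temperature = 300,
                                coordinate_id = "coordinate", seed = NULL) {
  .assert(length(biases) == length(samples) && length(biases) >= 1L,
          "bindfe_input_error", "need one sample series per bias")
  centers <- vapply(biases, function(b) b$center, numeric(1))
  if (length(centers) > 1L) {
    d <- diff(centers)
    .assert(all(d > 0) || all(d < 0), "bindfe_input_error",
            "window centers must be strictly monotone")
  }
  for (s in samples)
    .assert(length(s) >= 1L && all(is.finite(s)), "bindfe_input_error",
            "each window needs >= 1 finite sample")
  structure(list(biases = biases, samples = samples,
                 temperature = temperature, coordinate_id = coordinate_id,
                 seed = seed),
            class = "bindfe_window_set")
}

#' @export
print.bindfe_window_set <- function(x, ...) {
  cat(sprintf("<bindfe_window_set: %d windows on '%s', T = %g K>\n",
              length(x$biases), x$coordinate_id, x$temperature))
  invisible(x)
}

#' Window centers of a window set
#' @param windows a [umbrella_window_set()].
#' @return Numeric vector of bias centers.
#' @export
window_centers <- function(windows)
  vapply(windows$biases, function(b) b$center, numeric(1))
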