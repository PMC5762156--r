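# Inverse current-source-density estimation across the laminar probe.
#
# The step method assumes the CSD is constant within a slab of thickness h
# (the electrode spacing) centered on each contact, over a disc of radius R.
# The potential such a slab produces at contact depth z_j has the closed
# form used below, giving a forward matrix F with V = F %*% C; the CSD
# estimate is F^{-1} V per time sample. The traditional alternative is the
# (negated, scaled) second spatial difference with Vaknin end-channel
# duplication. Both outputs are sign-inverted so current *sinks* are
# positive, matching the plotting convention in which warm colors are sinks.

#' Forward matrix of the step (delta-source / slab) CSD model
#'
#' `F[j, i]` is the potential at contact `j` produced by a unit
#' current-source density occupying the slab of thickness `h` centered on
#' contact `i`, over a disc of radius `disc_radius`:
#' `F[j,i] = 1/(2*sigma) * integral over the slab of
#' (sqrt(R^2 + (z_j - z')^2) - |z_j - z'|) dz'`, evaluated in closed form.
#'
#' @param channel_depths Contact depths in micrometres, uniformly spaced.
#' @param conductivity Extracellular conductivity in S/m (default 0.3).
#' @param disc_radius Disc radius in micrometres (default 500).
#'
#' @return An n x n matrix mapping CSD (A/m^3) to potential (V).
#' @export
csd_forward_matrix <- function(channel_depths, conductivity = 0.3,
                               disc_radius = 500) {
  assert_scalar_number(conductivity, "conductivity", lower = 0, strict_lower = TRUE)
  assert_scalar_number(disc_radius, "disc_radius", lower = 0, strict_lower = TRUE)
  z <- channel_depths * 1e-6
  d <- diff(z)
  if (length(z) < 3L) abort("At least 3 channels are required.")
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9) {
    abort("`channel_depths` must be strictly increasing and uniformly spaced.")
  }
  h <- d[1]
  R <- disc_radius * 1e-6
  # antiderivative of sqrt(R^2 + u^2) - |u|
  G <- function(u) {
    u / 2 * sqrt(R^2 + u^2) + R^2 / 2 * asinh(u / R) - u * abs(u) / 2
  }
  n <- length(z)
  F_mat <- matrix(0, n, n)
  for (j in seq_len(n)) {
    a <- z - h / 2 - z[j]
    b <- z + h / 2 - z[j]
    F_mat[j, ] <- (G(b) - G(a)) / (2 * conductivity)
  }
  F_mat
}

#' Current-source-density map from an evoked average
#'
#' Estimates the laminar CSD of the averaged evoked response, sample by
#' sample, either by inverting the step-method forward matrix (units A/m^3)
#' or by the negated second spatial difference with Vaknin end-channel
#' duplication (arbitrary units). The output is sign-inverted so sinks are
#' positive.
#'
#' @param avg An `evoked_average` with >= 3 uniformly spaced channels.
#' @param method `"step"` (inverse forward model) or `"second_difference"`.
#' @param conductivity Extracellular conductivity in S/m.
#' @param disc_radius Step-method disc radius in micrometres.
#'
#' @return A `csd_map`: list with `csd` (channels x window-samples,
#'   sink-positive), `time_ms`, `channel_depths`, `method`.
#' @export
compute_csd <- function(avg, method = c("step", "second_difference"),
                        conductivity = 0.3, disc_radius = 500) {
  stopifnot(inherits(avg, "evoked_average"))
  method <- match.arg(method)
  v_volts <- avg$mean * 1e-3
  n <- nrow(v_volts)
  if (n < 3L) abort("At least 3 channels are required.")
  csd <- if (method == "step") {
    F_mat <- csd_forward_matrix(avg$channel_depths, conductivity, disc_radius)
    est <- tryCatch(solve(F_mat, v_volts),
                    error = function(e) abort(paste0(
                      "Step-method forward matrix is singular: ", conditionMessage(e))))
    -est  # invert so sinks (negative CSD) plot positive
  } else {
    h <- diff(avg$channel_depths)[1] * 1e-6
    padded <- rbind(v_volts[1, ], v_volts, v_volts[n, ])  # Vaknin duplication
    d2 <- padded[3:(n + 2), ] - 2 * padded[2:(n + 1), ] + padded[1:n, ]
    # standard CSD is -sigma * d2V/dz^2; inverted convention flips the sign
    conductivity * d2 / h^2
  }
  structure(
    list(csd = csd, time_ms = avg$time_ms, channel_depths = avg$channel_depths,
         method = method),
    class = "csd_map"
  )
}
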