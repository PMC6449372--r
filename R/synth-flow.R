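#' Build a steady channel flow field with a log-law vertical profile
#'
#' Horizontal speed follows the law of the wall,
#' `u(h) = (ustar / kappa) * log(h / z0)` for height above bed
#' `h in [z0, depth]`, clipped at >= 0 and evaluated at `h = z0` for any
#' `h < z0` (documented clamp). Horizontal dispersion is
#' `scaling * baseDh`; vertical dispersion is constant.
#'
#' @param config named list from [flowFieldConfig()].
#' @return a [FlowField-class].
#' @export
generateFlowField <- function(config = flowFieldConfig()) {
  assertThat(config$z0 < config$waterDepth, "z0 must be < waterDepth")
  assertThat(config$ustar >= 0, "ustar must be >= 0")
  assertThat(config$Dv >= 0 && config$baseDh >= 0, "dispersion must be >= 0")
  new("FlowField", depth = config$waterDepth, ustar = config$ustar,
      z0 = config$z0, kappa = config$kappa,
      Dh = config$scaling * config$baseDh, Dv = config$Dv,
      scaling = config$scaling)
}

#' Log-law speed at a height above the bed
#'
#' @param flow a [FlowField-class].
#' @param h height above the bed, m; values below `z0` are evaluated at `z0`.
#' @return speed, m/s (>= 0).
#' @export
logLawSpeed <- function(flow, h) {
  h <- pmax(h, flow@z0)
  pmax((flow@ustar / flow@kappa) * log(h / flow@z0), 0)
}

#' Speed at a depth below the surface
#'
#' Convenience wrapper converting depth-below-surface `z` to height above
#' bed `h = depth - z` before evaluating the log law.
#'
#' @param flow a [FlowField-class].
#' @param z depth below surface, m.
#' @return speed, m/s.
#' @export
speedAtDepth <- function(flow, z) logLawSpeed(flow, flow@depth - z)

#' Depth-averaged log-law speed
#'
#' Analytic mean of the log law over `[z0, depth]`:
#' `(ustar/kappa) * (log(depth/z0) - 1 + z0/depth) / (1 - z0/depth)`.
#'
#' @param flow a [FlowField-class].
#' @return depth-averaged speed, m/s.
#' @export
depthAveragedSpeed <- function(flow) {
  D <- flow@depth; z0 <- flow@z0
  (flow@ustar / flow@kappa) * (log(D / z0) - 1 + z0 / D) / (1 - z0 / D)
}
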