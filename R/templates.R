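# Parametric single-cycle pulse templates.
#
# Each pressure/volume pulse is a sum of two Gaussians on normalized phase
# u in [0, 1] (main systolic wave + dicrotic wave), corrected by the chord
# between its endpoint values so the cycle starts and ends exactly at zero,
# then scaled to unit peak. The correction makes the diastolic foot an exact
# V-shaped minimum at u = 0/1, so the template's fiducial points (foot, peak,
# maximum upslope, intersecting tangent) have well-defined phases that are
# computed once to high precision and reused as analytic ground truth: a
# cycle warped linearly onto a beat of duration T has its fiducials at
# exactly onset + u * T.

gauss_u <- function(u, mu, sdev) exp(-((u - mu)^2) / (2 * sdev^2))
dgauss_u <- function(u, mu, sdev) -((u - mu) / sdev^2) * gauss_u(u, mu, sdev)

template_params <- list(
  abp = list(mu = c(0.32, 0.62), sdev = c(0.09, 0.14), amp = c(1, 0.32)),
  ppg = list(mu = c(0.34, 0.65), sdev = c(0.11, 0.16), amp = c(1, 0.45))
)

template_raw <- function(u, p) {
  p$amp[1] * gauss_u(u, p$mu[1], p$sdev[1]) +
    p$amp[2] * gauss_u(u, p$mu[2], p$sdev[2])
}

template_raw_deriv <- function(u, p) {
  p$amp[1] * dgauss_u(u, p$mu[1], p$sdev[1]) +
    p$amp[2] * dgauss_u(u, p$mu[2], p$sdev[2])
}

.template_cache <- new.env(parent = emptyenv())

# Unit-amplitude cycle shape and its exact phase-domain fiducials.
# Returned fields:
#   shape(u), deriv(u)    normalized shape and its derivative (peak value 1)
#   u_peak                phase of the systolic peak
#   u_maxderiv            phase of maximum upslope on the rising limb
#   u_it                  intersecting-tangent onset phase (tangent at the
#                         maximum upslope intersected with the horizontal
#                         tangent through the zero-valued foot)
#   mean_level            time-average of the shape over one cycle
template_info <- function(channel = c("abp", "ppg")) {
  channel <- match.arg(channel)
  if (!is.null(.template_cache[[channel]])) return(.template_cache[[channel]])
  p <- template_params[[channel]]
  r0 <- template_raw(0, p)
  r1 <- template_raw(1, p)
  chord_slope <- r1 - r0
  base <- function(u) template_raw(u, p) - ((1 - u) * r0 + u * r1)
  base_deriv <- function(u) template_raw_deriv(u, p) - chord_slope

  u_peak <- stats::optimize(base, c(0.05, 0.6), maximum = TRUE,
                            tol = 1e-12)$maximum
  smax <- base(u_peak)
  shape <- function(u) base(u) / smax
  deriv <- function(u) base_deriv(u) / smax

  u_md <- stats::optimize(deriv, c(1e-4, u_peak), maximum = TRUE,
                          tol = 1e-12)$maximum
  u_it <- u_md - shape(u_md) / deriv(u_md)
  grid <- seq(0, 1, length.out = 20001L)
  mean_level <- mean(shape(grid))

  info <- list(shape = shape, deriv = deriv, u_peak = u_peak,
               u_maxderiv = u_md, u_it = u_it, mean_level = mean_level)
  .template_cache[[channel]] <- info
  info
}

# Narrow Gaussian QRS complex plus a low, broad T wave.
ecg_beat_shape <- function(dt) {
  exp(-dt^2 / (2 * 0.012^2)) + 0.2 * exp(-(dt - 0.25)^2 / (2 * 0.05^2))
}
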