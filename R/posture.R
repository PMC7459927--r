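as_waist_profile <- function(profile) {
  if (inherits(profile, "waist_model")) return(profile$profile)
  if (!inherits(profile, "waist_profile"))
    stop("`profile` must be a waist_profile (see standard_profile()) ",
         "or a waist_model")
  profile
}

# Slope and intercept of cos(alpha) = slope * h/H - intercept.
#
# "paper_rounded" rounds both coefficients to two decimals (3.70 and 0.63
# for the standard profile); only these rounded coefficients reproduce the
# model's published forces, because near the upright end of the range the
# sine amplifies even a third-decimal change in the cosine. "derived" keeps
# the exact fractions 1/k2 and (a - b)/k2.
cosine_coefficients <- function(profile, mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  slope <- 1 / profile$k2
  intercept <- (profile$a - profile$b) / profile$k2
  if (mode == "paper_rounded") {
    slope <- round(slope, 2)
    intercept <- round(intercept, 2)
  }
  c(slope = slope, intercept = intercept)
}

#' Trunk inclination versus object height
#'
#' In the stoop posture the trunk rotates about L5-S1, so the height h of
#' the object's centre of gravity above ground fixes the trunk inclination
#' angle alpha (measured from the horizontal, 0 < alpha <= 90 degrees)
#' through cos(alpha) = (h/H + b - a)/k2. For the standard profile this is
#' cos(alpha) = 3.70 h/H - 0.63.
#'
#' @param h Object-centre height(s) above ground, cm; must be >= 0.
#' @param profile A [waist_profile][standard_profile()] (or [waist_model()]).
#' @param mode \code{"paper_rounded"} (default) evaluates the cosine with its
#'   coefficients rounded to two decimals, the form behind all published
#'   numbers of the model; \code{"derived"} uses the exact fractions.
#' @return A data frame (one row per element of \code{h}) with columns
#'   \code{object_height_h}, \code{cos_alpha}, \code{sin_alpha},
#'   \code{alpha_deg} and \code{in_range}. Heights outside the valid range
#'   are returned flagged (\code{in_range = FALSE}, angle columns \code{NA}),
#'   not raised as errors; a negative height is an error.
#' @seealso [valid_height_range()], [erector_force()]
#' @export
#' @examples
#' trunk_cosine(c(40, 55, 70))
trunk_cosine <- function(h, profile = standard_profile(),
                         mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(h) || any(is.na(h)))
    stop("`h` must be numeric with no missing values")
  if (any(h < 0))
    stop("object height `h` must be non-negative (cm above ground)")
  cf <- cosine_coefficients(profile, mode)
  cos_alpha <- cf[["slope"]] * h / profile$stature_H - cf[["intercept"]]
  # the interval is closed at h_min; absorb the floating rounding of
  # h_min itself (no clamping of genuinely out-of-range heights)
  cos_alpha[cos_alpha < 0 & cos_alpha >= -1e-9] <- 0
  in_range <- cos_alpha >= 0 & cos_alpha < 1
  sin_alpha <- ifelse(in_range, sqrt(pmax(0, 1 - cos_alpha^2)), NA_real_)
  alpha_deg <- ifelse(in_range, acos(pmin(1, pmax(-1, cos_alpha))) * 180 / pi,
                      NA_real_)
  data.frame(object_height_h = h, cos_alpha = cos_alpha,
             sin_alpha = sin_alpha, alpha_deg = alpha_deg,
             in_range = in_range)
}

#' Valid lifting-height range of the posture model
#'
#' The trunk-inclination constraint 0 <= cos(alpha) < 1 restricts the
#' object height to a half-open interval [h_min, h_max): at h_min the trunk
#' is horizontal-armed fully bent (alpha = 90 deg, cos = 0) and at h_max the
#' trunk would be upright (alpha = 0), which the model excludes. For the
#' standard 168 cm profile the range is 28.6 cm <= h < 74.0 cm.
#'
#' @inheritParams trunk_cosine
#' @return Named numeric vector \code{c(h_min, h_max)} in cm; closed at
#'   \code{h_min}, open at \code{h_max}.
#' @export
#' @examples
#' round(valid_height_range(standard_profile()), 1) # 28.6, 74.0
valid_height_range <- function(profile = standard_profile(),
                               mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  cf <- cosine_coefficients(profile, mode)
  c(h_min = cf[["intercept"]] / cf[["slope"]] * profile$stature_H,
    h_max = (1 + cf[["intercept"]]) / cf[["slope"]] * profile$stature_H)
}

#' Erector spinae force coefficients
#'
#' The torque balance about L5-S1 collapses to
#' F = (c1 M + c2 G) sin(alpha), with c1 = (j1 k1 + j2 k2 + j3 k3) divided
#' by the erector spinae moment-arm fraction and c2 = k2 divided by the
#' same arm. With the standard constants these round to the published
#' (3.42, 9.06).
#'
#' @inheritParams trunk_cosine
#' @param mode \code{"paper_rounded"} returns the two-decimal published
#'   coefficients; \code{"derived"} the unrounded fractions.
#' @return Named numeric vector \code{c(c1, c2)} (dimensionless).
#' @export
#' @examples
#' force_coefficients(standard_profile())            # 3.42 9.06
#' force_coefficients(standard_profile(), "derived") # 3.4209... 9.0604...
force_coefficients <- function(profile = standard_profile(),
                               mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  c1 <- with(profile, (j1 * k1 + j2 * k2 + j3 * k3) / erector_arm_frac)
  c2 <- profile$k2 / profile$erector_arm_frac
  if (mode == "paper_rounded") {
    c1 <- round(c1, 2)
    c2 <- round(c2, 2)
  }
  c(c1 = c1, c2 = c2)
}

stop_out_of_range <- function(h, profile, mode) {
  rng <- valid_height_range(profile, mode)
  stop(sprintf(
    "object height h = %g cm is outside the model's valid range [%.1f, %.1f) cm",
    h, rng[["h_min"]], rng[["h_max"]]), call. = FALSE)
}

#' Erector spinae pulling force during a stooped lift
#'
#' Closed form of the static sagittal-plane torque balance about L5-S1:
#' F = (c1 M + c2 G) sin(alpha), where M is the worker's weight force, G the
#' object's weight force and alpha the trunk inclination implied by the
#' object height. For the standard worker F = (1976.76 + 9.06 G) sin(alpha).
#'
#' @param G Object weight force(s), N (mass * 9.8); must be >= 0.
#' @param h Object-centre height(s) above ground, cm; must lie inside
#'   [valid_height_range()].
#' @inheritParams trunk_cosine
#' @param include_abdominal If \code{TRUE}, subtract the intra-abdominal
#'   pressure relief term F4 L4 / (erector arm) = 0.0228 M (about 13 N for
#'   the standard worker). The published closed form drops this term, so the
#'   default is \code{FALSE}.
#' @return A data frame with columns \code{erector_force_F},
#'   \code{object_weight_G}, \code{c1}, \code{c2} and the posture columns of
#'   [trunk_cosine()]. \code{G} and \code{h} are recycled to a common length.
#' @seealso [torque_balance_oracle()] for the explicit lever-by-lever
#'   moment sum.
#' @export
#' @examples
#' erector_force(G = 20 * 9.8, h = 50)
erector_force <- function(G, h, profile = standard_profile(),
                          mode = c("paper_rounded", "derived"),
                          include_abdominal = FALSE) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(G) || any(is.na(G)) || any(G < 0))
    stop("object weight `G` must be non-negative (N)")
  n <- max(length(G), length(h))
  G <- rep_len(G, n)
  h <- rep_len(h, n)
  post <- trunk_cosine(h, profile, mode)
  if (any(!post$in_range))
    stop_out_of_range(h[!post$in_range][1], profile, mode)
  cf <- force_coefficients(profile, mode)
  F <- (cf[["c1"]] * profile$weight_force_M + cf[["c2"]] * G) * post$sin_alpha
  if (include_abdominal) {
    F <- F - with(profile,
                  abdominal_force_frac * abdominal_arm_frac /
                    erector_arm_frac * weight_force_M)
  }
  cbind(data.frame(erector_force_F = F, object_weight_G = G,
                   c1 = cf[["c1"]], c2 = cf[["c2"]]),
        post)
}

#' Lever-by-lever torque-balance oracle
#'
#' Recomputes the erector spinae force by explicitly building each moment
#' about L5-S1 -- head+neck weight j1 M at lever k1 H sin(alpha), both arms
#' j2 M at k2 H sin(alpha), upper trunk j3 M at k3 H sin(alpha), the object
#' G at k2 H sin(alpha), optionally less the abdominal relief F4 L4 -- then
#' dividing the net moment by the erector spinae arm. It never calls
#' [erector_force()]; it exists as an independent derivation path against
#' which the closed form is tested, and always uses unrounded constants.
#'
#' @inheritParams erector_force
#' @return Numeric vector of forces, N.
#' @export
torque_balance_oracle <- function(G, h, profile = standard_profile(),
                                  include_abdominal = FALSE) {
  profile <- as_waist_profile(profile)
  if (!is.numeric(G) || any(is.na(G)) || any(G < 0))
    stop("object weight `G` must be non-negative (N)")
  n <- max(length(G), length(h))
  G <- rep_len(G, n)
  h <- rep_len(h, n)
  post <- trunk_cosine(h, profile, mode = "derived")
  if (any(!post$in_range))
    stop_out_of_range(h[!post$in_range][1], profile, mode = "derived")
  H <- profile$stature_H
  M <- profile$weight_force_M
  s <- post$sin_alpha
  moment <- (profile$j1 * M) * (profile$k1 * H * s) +
    (profile$j2 * M) * (profile$k2 * H * s) +
    (profile$j3 * M) * (profile$k3 * H * s) +
    G * (profile$k2 * H * s)
  if (include_abdominal) {
    moment <- moment - (profile$abdominal_force_frac * M) *
      (profile$abdominal_arm_frac * H)
  }
  moment / (profile$erector_arm_frac * H)
}
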