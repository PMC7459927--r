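#' Erector spinae force at the recommended weight limit
#'
#' F(RWL): the erector spinae pulling force when the lifted weight equals
#' the China-adapted recommended weight limit for the same height. This is
#' the denominator of the waist comfort score.
#'
#' @inheritParams rwl_chinese
#' @return Force in N.
#' @export
#' @examples
#' force_at_rwl(70) # about 2082 N
force_at_rwl <- function(h, profile = standard_profile(),
                         mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  G <- rwl_chinese(h, profile, mode)$rwl_kg * GRAVITY
  erector_force(G, h, profile, mode)$erector_force_F
}

classify_load <- function(LI, tol) {
  if (LI > 3) "severely_dangerous"
  else if (LI > 1 + tol) "dangerous"
  else if (LI >= 1 - tol) "limit"
  else "acceptable"
}

#' Waist comfort assessment of a lifting task
#'
#' Scores a lift by the waist comfort model C = 1 - F/F(RWL): the erector
#' spinae force the task demands, relative to the force it would demand at
#' the recommended weight limit for the same height. C = 1 would be total
#' rest (never attained, since holding the posture alone loads the muscle),
#' C = 0 marks the limit load, and C < 0 a dangerous one. The lifting index
#' LI = mass/RWL carries the load-risk category: \code{acceptable}
#' (LI < 1), \code{limit} (LI = 1), \code{dangerous} (LI > 1) and
#' \code{severely_dangerous} (LI > 3).
#'
#' @param object_mass_kg Mass of the lifted object, kg; must be >= 0.
#' @inheritParams rwl_chinese
#' @param tol Relative half-width of the LI band labelled \code{limit}. The
#'   C = 0 class is a measure-zero boundary, so the default is a tight
#'   1e-9; batch assessment of rounded inputs uses a looser band.
#' @return An object of class \code{comfort_assessment}: a list with
#'   \code{erector_force_F}, \code{erector_force_at_rwl}, \code{rwl_kg},
#'   \code{discomfort_muC}, \code{comfort_C}, \code{lifting_index_LI} and
#'   \code{category}.
#' @export
#' @examples
#' assess(20, h = 55)
assess <- function(object_mass_kg, h, profile = standard_profile(),
                   tol = 1e-9, mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(object_mass_kg) || length(object_mass_kg) != 1L ||
      is.na(object_mass_kg) || object_mass_kg < 0)
    stop("`object_mass_kg` must be a single non-negative mass (kg)")
  rwl <- rwl_chinese(h, profile, mode)
  F <- erector_force(object_mass_kg * GRAVITY, h, profile, mode)$erector_force_F
  F_rwl <- erector_force(rwl$rwl_kg * GRAVITY, h, profile, mode)$erector_force_F
  muC <- F / F_rwl
  # mass ratio, not force ratio: identical since g is one constant, but
  # avoids a kg -> N -> kg round trip
  LI <- object_mass_kg / rwl$rwl_kg
  structure(list(object_mass_kg = object_mass_kg, object_height_h = h,
                 rwl_kg = rwl$rwl_kg,
                 erector_force_F = F, erector_force_at_rwl = F_rwl,
                 discomfort_muC = muC, comfort_C = 1 - muC,
                 lifting_index_LI = LI,
                 category = classify_load(LI, tol)),
            class = "comfort_assessment")
}

#' Force cost of one unit of lifting index
#'
#' The erector spinae force is linear in the lifted weight, so at a fixed
#' height the slope of F with respect to the lifting index is exactly
#' c2 * RWL * g * sin(alpha). Over mid-range lifting heights this is about
#' 1300 N per unit LI for the standard worker.
#'
#' @inheritParams rwl_chinese
#' @return Force per unit lifting index, N.
#' @export
#' @examples
#' force_per_li(50) # about 1326 N
force_per_li <- function(h, profile = standard_profile(),
                         mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  rwl <- rwl_chinese(h, profile, mode)
  cf <- force_coefficients(profile, mode)
  s <- trunk_cosine(h, profile, mode)$sin_alpha
  cf[["c2"]] * rwl$rwl_kg * GRAVITY * s
}

#' @export
print.comfort_assessment <- function(x, ...) {
  cat(sprintf("Lift assessment: %.2f kg at h = %.1f cm\n",
              x$object_mass_kg, x$object_height_h))
  cat(sprintf("  RWL            %.2f kg\n", x$rwl_kg))
  cat(sprintf("  F / F(RWL)     %.2f / %.2f N\n",
              x$erector_force_F, x$erector_force_at_rwl))
  cat(sprintf("  comfort C      %.4f\n", x$comfort_C))
  cat(sprintf("  lifting index  %.3f  [%s]\n",
              x$lifting_index_LI, x$category))
  invisible(x)
}
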