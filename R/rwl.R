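fm_table <- function() {
  path <- system.file("extdata", "frequency_multiplier.csv",
                      package = "waistload", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("numeric", "character", "numeric", "numeric"))
}

#' NIOSH frequency multiplier (FM) lookup
#'
#' Exact lookup in the tabulated frequency-multiplier table, keyed by lift
#' frequency, shift-duration class and whether the vertical origin V is
#' below or at/above the 75 cm reference. The table is discrete; untabulated
#' frequencies are an error rather than being interpolated, unless
#' \code{conservative = TRUE}, which rounds an untabulated frequency up to
#' the next tabulated (more penalising) rate.
#'
#' @param frequency Lifts per minute; tabulated rates are 0.2, 0.5, 1, 2, 3
#'   and 4.
#' @param duration_class Shift duration: \code{"1h"}, \code{"2h"} or
#'   \code{"8h"} (meaning up to 1, 2 or 8 hours).
#' @param V Vertical origin of the lift, cm; must be >= 0.
#' @param conservative Map an untabulated frequency to the next-higher
#'   tabulated rate instead of erroring.
#' @return The frequency multiplier, a dimensionless value in (0, 1].
#' @export
#' @examples
#' frequency_multiplier(0.2, "1h", V = 40) # 1.00
#' frequency_multiplier(4, "8h", V = 80)   # 0.45
frequency_multiplier <- function(frequency, duration_class = c("1h", "2h", "8h"),
                                 V = 75, conservative = FALSE) {
  duration_class <- match.arg(duration_class)
  if (!is.numeric(frequency) || length(frequency) != 1L || is.na(frequency))
    stop("`frequency` must be a single number (lifts/minute)")
  if (!is.numeric(V) || V < 0)
    stop("`V` must be a non-negative height (cm)")
  tab <- fm_table()
  rates <- sort(unique(tab$frequency))
  if (frequency < min(rates))
    stop("`frequency` must be at least ", min(rates), " lifts/minute")
  row <- which(tab$frequency == frequency & tab$duration_class == duration_class)
  if (!length(row)) {
    if (conservative && frequency <= max(rates)) {
      frequency <- rates[which(rates >= frequency)[1]]
      row <- which(tab$frequency == frequency &
                     tab$duration_class == duration_class)
    } else {
      stop("untabulated lift frequency ", frequency,
           "; tabulated rates are ", paste(rates, collapse = ", "),
           " lifts/minute (set conservative = TRUE to round up)")
    }
  }
  if (V < 75) tab$fm_v_lt_75[row] else tab$fm_v_ge_75[row]
}

#' NIOSH lifting-task descriptors
#'
#' Bundles the task variables of the revised NIOSH lifting equation, with
#' the load constant and vertical-multiplier reference kept as explicit
#' fields so both the original (23 kg, 75 cm) and the China-adapted
#' (20 kg, 72 cm) settings are expressible.
#'
#' @param horizontal_dist Horizontal distance from the palms to the
#'   ankle-midpoint, cm (the equation's H; renamed to avoid collision with
#'   stature).
#' @param vertical_origin_V Height of the hands at the origin of the lift,
#'   cm.
#' @param travel_D Vertical travel distance of the lift, cm; must be > 0
#'   (the distance multiplier diverges at 0). No lower clamp at 25 cm is
#'   applied: the China-adapted closed form evaluates travel distances down
#'   to 2 cm, where the distance multiplier exceeds 1.
#' @param frequency Lifts per minute (tabulated rates only; see
#'   [frequency_multiplier()]).
#' @param duration_class \code{"1h"}, \code{"2h"} or \code{"8h"}.
#' @param asymmetry_A Asymmetry angle out of the sagittal plane, degrees.
#' @param coupling_CM Coupling multiplier: 1.00 (good), 0.95 (fair) or
#'   0.90 (poor).
#' @param load_constant Load constant, kg (23 for original NIOSH, 20 for
#'   the Chinese adaptation).
#' @param vm_reference Vertical-multiplier reference height, cm (75
#'   original, 72 Chinese).
#' @return An object of class \code{lift_conditions}.
#' @seealso [rwl_niosh()], [rwl_chinese()]
#' @export
lift_conditions <- function(horizontal_dist = 25, vertical_origin_V = 75,
                            travel_D = 25, frequency = 0.2,
                            duration_class = c("1h", "2h", "8h"),
                            asymmetry_A = 0, coupling_CM = 1.00,
                            load_constant = 23, vm_reference = 75) {
  duration_class <- match.arg(duration_class)
  if (horizontal_dist <= 0) stop("`horizontal_dist` must be positive (cm)")
  if (travel_D < 0) stop("`travel_D` must be non-negative (cm)")
  if (frequency < 0.2) stop("`frequency` must be at least 0.2 lifts/minute")
  if (!coupling_CM %in% c(1.00, 0.95, 0.90))
    stop("`coupling_CM` must be one of 1.00, 0.95, 0.90")
  if (asymmetry_A < 0) stop("`asymmetry_A` must be non-negative (degrees)")
  if (vertical_origin_V < 0) stop("`vertical_origin_V` must be >= 0 (cm)")
  if (load_constant <= 0) stop("`load_constant` must be positive (kg)")
  structure(list(horizontal_dist = horizontal_dist,
                 vertical_origin_V = vertical_origin_V,
                 travel_D = travel_D, frequency = frequency,
                 duration_class = duration_class,
                 asymmetry_A = asymmetry_A, coupling_CM = coupling_CM,
                 load_constant = load_constant, vm_reference = vm_reference),
            class = "lift_conditions")
}

#' Recommended weight limit (revised NIOSH lifting equation)
#'
#' RWL = LC * HM * VM * DM * FM * AM * CM with HM = 25/horizontal_dist,
#' VM = 1 - 0.003 |V - reference|, DM = 0.82 + 4.5/D, FM from the
#' frequency table, AM = 1 - 0.0032 A, and the coupling multiplier CM. No
#' multiplier caps or distance clamps are applied (the China-adapted form
#' relies on DM > 1 at short travel), which deviates from the official
#' NIOSH applications manual.
#'
#' @param conditions A [lift_conditions()] object.
#' @return An object of class \code{rwl_result}: a list with \code{rwl_kg},
#'   the named \code{multipliers} vector (HM, VM, DM, FM, AM, CM) and the
#'   \code{conditions}.
#' @export
#' @examples
#' rwl_niosh(lift_conditions()) # all multipliers 1 -> 23 kg
rwl_niosh <- function(conditions) {
  if (!inherits(conditions, "lift_conditions"))
    stop("`conditions` must be a lift_conditions object")
  if (conditions$travel_D == 0)
    stop("travel distance D = 0: the distance multiplier 0.82 + 4.5/D diverges")
  hm <- 25 / conditions$horizontal_dist
  vm <- 1 - 0.003 * abs(conditions$vertical_origin_V - conditions$vm_reference)
  if (vm <= 0)
    stop("vertical multiplier is non-positive: V = ",
         conditions$vertical_origin_V, " cm is too far from the ",
         conditions$vm_reference, " cm reference")
  dm <- 0.82 + 4.5 / conditions$travel_D
  fm <- frequency_multiplier(conditions$frequency, conditions$duration_class,
                             V = conditions$vertical_origin_V)
  am <- 1 - 0.0032 * conditions$asymmetry_A
  if (am <= 0) stop("asymmetry multiplier is non-positive")
  cm <- conditions$coupling_CM
  mult <- c(HM = hm, VM = vm, DM = dm, FM = fm, AM = am, CM = cm)
  structure(list(rwl_kg = conditions$load_constant * prod(mult),
                 multipliers = mult, conditions = conditions),
            class = "rwl_result")
}

#' China-adapted recommended weight limit as a function of lifting height
#'
#' Specialises the NIOSH equation to the Chinese standard lifting task:
#' load constant 20 kg (the 23 kg constant reduced by 15 percent per
#' GB/T 31002x), vertical reference 72 cm, horizontal distance 25 cm
#' (HM = 1), sagittal lifting (AM = 1), single lifts at 0.2/min for under
#' an hour (FM = 1), poor coupling (CM = 0.90), and vertical travel
#' D = 74 - h up to the 50th-percentile functional hand height of 74 cm:
#' RWL(h) = 20 (1 - 0.003 |h - 72|) (0.82 + 4.5/(74 - h)) 0.90.
#' Lifts delivering at or above 74 cm are outside the model's scope.
#'
#' @param h Height of the object's centre of gravity above ground, cm; must
#'   lie in [h_min, 74) where h_min is the posture model's lower bound.
#' @inheritParams trunk_cosine
#' @return An object of class \code{rwl_result} (see [rwl_niosh()]).
#' @export
#' @examples
#' rwl_chinese(70) # 34.80 kg
rwl_chinese <- function(h, profile = standard_profile(),
                        mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(h) || length(h) != 1L || is.na(h))
    stop("`h` must be a single height (cm)")
  h_min <- valid_height_range(profile, mode)[["h_min"]]
  if (h >= 74)
    stop("h = ", h, " cm: lifts delivering at or above the 74 cm functional ",
         "hand height are outside the model's domain")
  if (h < h_min)
    stop(sprintf("h = %g cm is below the posture model's lower bound %.1f cm",
                 h, h_min))
  rwl_niosh(lift_conditions(
    horizontal_dist = 25, vertical_origin_V = h, travel_D = 74 - h,
    frequency = 0.2, duration_class = "1h", asymmetry_A = 0,
    coupling_CM = 0.90, load_constant = 20, vm_reference = 72
  ))
}

#' @export
print.rwl_result <- function(x, ...) {
  cat(sprintf("Recommended weight limit: %.2f kg\n", x$rwl_kg))
  cat("  multipliers: ",
      paste(sprintf("%s=%.3f", names(x$multipliers), x$multipliers),
            collapse = "  "), "\n", sep = "")
  cat(sprintf("  load constant %.0f kg, V = %.0f cm, D = %.1f cm\n",
              x$conditions$load_constant, x$conditions$vertical_origin_V,
              x$conditions$travel_D))
  invisible(x)
}
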