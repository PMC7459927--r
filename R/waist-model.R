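#' Static waist-loading model for a worker
#'
#' Constructs the full static sagittal-plane lifting model for one worker:
#' the anthropometric profile, the trunk-posture geometry, the erector
#' spinae force law F = (c1 M + c2 G) sin(alpha), the China-adapted
#' recommended weight limit, the waist comfort score and the L5-S1 stress
#' decomposition. The returned object is the package's central interface;
#' use [predict.waist_model()] to evaluate tasks, [plot.waist_model()] for
#' the height-sweep curves and [summary.waist_model()] for the model's
#' headline quantities.
#'
#' @param stature_cm Worker stature, cm (default: the 50th-percentile
#'   Chinese male, 168 cm).
#' @param body_mass_kg Worker body mass, kg (default 59).
#' @inheritParams trunk_cosine
#' @param include_abdominal Include the intra-abdominal pressure relief
#'   term in the erector force (see [erector_force()]).
#' @param criterion_N L5-S1 force criterion, N.
#' @param constants Passed to [standard_profile()].
#' @return An object of class \code{waist_model}.
#' @export
#' @examples
#' m <- waist_model()
#' predict(m, data.frame(height_cm = 55, mass_kg = 15))
waist_model <- function(stature_cm = 168, body_mass_kg = 59,
                        mode = c("paper_rounded", "derived"),
                        include_abdominal = FALSE,
                        criterion_N = NIOSH_COMPRESSION_CRITERION,
                        constants = c("published", "derived")) {
  mode <- match.arg(mode)
  constants <- match.arg(constants)
  profile <- if (stature_cm == 168 && body_mass_kg == 59)
    standard_profile(constants)
  else custom_profile(stature_cm, body_mass_kg, constants)
  structure(list(profile = profile, mode = mode,
                 include_abdominal = include_abdominal,
                 criterion_N = criterion_N,
                 coefficients = force_coefficients(profile, mode),
                 cosine = cosine_coefficients(profile, mode),
                 height_range = valid_height_range(profile, mode),
                 call = match.call()),
            class = "waist_model")
}

#' @export
print.waist_model <- function(x, ...) {
  cat("Static waist-loading model (stoop lift, sagittal plane)\n")
  cat(sprintf("  worker: H = %.1f cm, M = %.1f N (%.1f kg)\n",
              x$profile$stature_H, x$profile$weight_force_M,
              x$profile$weight_force_M / GRAVITY))
  cat(sprintf("  force law: F = (%.2f M + %.2f G) sin(alpha), mode \"%s\"\n",
              x$coefficients[["c1"]], x$coefficients[["c2"]], x$mode))
  cat(sprintf("  valid lifting heights: [%.1f, %.1f) cm\n",
              x$height_range[["h_min"]], x$height_range[["h_max"]]))
  invisible(x)
}

#' Model coefficients
#'
#' @param object A [waist_model()].
#' @param ... Unused.
#' @return Named vector with the force coefficients c1, c2, the cosine
#'   slope and intercept, and the valid height bounds.
#' @export
coef.waist_model <- function(object, ...) {
  c(object$coefficients,
    cos_slope = unname(object$cosine[["slope"]]),
    cos_intercept = unname(object$cosine[["intercept"]]),
    h_min = unname(object$height_range[["h_min"]]),
    h_max = unname(object$height_range[["h_max"]]))
}

#' Evaluate the model on lifting tasks
#'
#' @param object A [waist_model()].
#' @param newdata Data frame with columns \code{height_cm} and
#'   \code{mass_kg} (one lifting task per row). Defaults to the limit load
#'   (mass = RWL) on the integer height grid 34..72.
#' @param tol LI half-width of the \code{limit} risk class.
#' @param ... Unused.
#' @return A data frame with one row per task: \code{rwl_kg}, \code{F_N},
#'   \code{F_at_rwl_N}, \code{comfort_C}, \code{LI}, \code{sigma_N},
#'   \code{tau_N}, \code{resultant_N}, \code{below_criterion},
#'   \code{category} and \code{in_domain}. Out-of-domain tasks are flagged,
#'   not errored.
#' @export
predict.waist_model <- function(object, newdata = NULL, tol = 1e-9, ...) {
  p <- object$profile
  if (is.null(newdata)) {
    h <- 34:72
    newdata <- data.frame(
      height_cm = h,
      mass_kg = vapply(h, function(hh)
        rwl_chinese(hh, p, object$mode)$rwl_kg, numeric(1)))
  }
  stopifnot(is.data.frame(newdata),
            all(c("height_cm", "mass_kg") %in% names(newdata)))
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    h <- newdata$height_cm[i]
    mass <- newdata$mass_kg[i]
    base <- data.frame(height_cm = h, mass_kg = mass, rwl_kg = NA_real_,
                       F_N = NA_real_, F_at_rwl_N = NA_real_,
                       comfort_C = NA_real_, LI = NA_real_,
                       sigma_N = NA_real_, tau_N = NA_real_,
                       resultant_N = NA_real_, below_criterion = NA,
                       category = NA_character_, in_domain = FALSE,
                       stringsAsFactors = FALSE)
    tryCatch({
      a <- assess(mass, h, p, tol = tol, mode = object$mode)
      st <- stress_decomposition(mass * GRAVITY, h, p, object$mode,
                                 object$criterion_N)
      base$rwl_kg <- a$rwl_kg
      base$F_N <- a$erector_force_F
      base$F_at_rwl_N <- a$erector_force_at_rwl
      base$comfort_C <- a$comfort_C
      base$LI <- a$lifting_index_LI
      base$sigma_N <- st$normal_sigma
      base$tau_N <- st$shear_tau
      base$resultant_N <- st$resultant_N
      base$below_criterion <- st$below_criterion
      base$category <- a$category
      base$in_domain <- TRUE
      base
    }, error = function(e) base)
  })
  do.call(rbind, rows)
}

#' Summarise the model over its working height range
#'
#' Computes the limit-load sweep on the integer grid 34..72 cm and reports
#' the model's headline quantities: the F(RWL) extremes, the RWL at the
#' height of least L5-S1 load, and the compression-criterion check.
#'
#' @param object A [waist_model()].
#' @param h_grid Heights for the sweep, cm.
#' @param ... Unused.
#' @return An object of class \code{summary.waist_model}.
#' @export
summary.waist_model <- function(object, h_grid = 34:72, ...) {
  val <- validate_at_rwl(object$profile, h_grid, object$criterion_N,
                         object$mode)
  rows <- val$rows
  i_fmax <- which.max(rows$F_N)
  i_fmin <- which.min(rows$F_N)
  structure(list(model = object, validation = val,
                 F_max = rows$F_N[i_fmax], h_at_F_max = rows$h_cm[i_fmax],
                 F_min = rows$F_N[i_fmin], h_at_F_min = rows$h_cm[i_fmin],
                 rwl_at_min_N = rows$rwl_kg[rows$h_cm == val$h_at_min]),
            class = "summary.waist_model")
}

#' @export
print.summary.waist_model <- function(x, ...) {
  print(x$model)
  v <- x$validation
  cat(sprintf("Limit load (G = RWL) over h = %g..%g cm:\n",
              min(v$rows$h_cm), max(v$rows$h_cm)))
  cat(sprintf("  F(RWL): max %.2f N at h = %g cm, min %.2f N at h = %g cm\n",
              x$F_max, x$h_at_F_max, x$F_min, x$h_at_F_min))
  cat(sprintf("  L5-S1 resultant: min %.2f N at h = %g cm (RWL %.2f kg)\n",
              v$min_N, v$h_at_min, x$rwl_at_min_N))
  cat(sprintf("  criterion %.0f N: %s\n", v$criterion,
              if (v$all_below_criterion) "met at every height"
              else "exceeded"))
  invisible(x)
}

#' Plot the model's height-sweep curves
#'
#' Four panels against lifting height at the limit load: the RWL, the
#' erector spinae force F(RWL), the L5-S1 stress components with the
#' compression criterion, and (if \code{fixed_mass_kg} is given) the
#' comfort score for that object mass.
#'
#' @param x A [waist_model()].
#' @param h_grid Heights, cm.
#' @param fixed_mass_kg Optional object mass for the comfort panel.
#' @param ... Passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.waist_model <- function(x, h_grid = 34:72, fixed_mass_kg = NULL, ...) {
  sw <- sweep_heights(x$profile, min(h_grid), max(h_grid),
                      if (length(h_grid) > 1) diff(h_grid[1:2]) else 1,
                      fixed_mass_kg, x$mode, x$criterion_N)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(sw$h_cm, sw$rwl_kg, type = "l", xlab = "h (cm)",
                 ylab = "RWL (kg)", main = "Recommended weight limit", ...)
  graphics::plot(sw$h_cm, sw$F_at_rwl_N, type = "l", xlab = "h (cm)",
                 ylab = "F(RWL) (N)", main = "Erector spinae force at RWL",
                 ...)
  graphics::plot(sw$h_cm, sw$resultant_N, type = "l", xlab = "h (cm)",
                 ylab = "force (N)",
                 ylim = range(sw$tau_N, sw$resultant_N, x$criterion_N),
                 main = "L5-S1 load at RWL", ...)
  graphics::lines(sw$h_cm, sw$sigma_N, lty = 2)
  graphics::lines(sw$h_cm, sw$tau_N, lty = 3)
  graphics::abline(h = x$criterion_N, col = "red")
  graphics::legend("right", legend = c("resultant N", "sigma", "tau",
                                       "criterion"),
                   lty = c(1, 2, 3, 1), col = c(1, 1, 1, 2), bty = "n",
                   cex = 0.8)
  if (!is.null(fixed_mass_kg)) {
    graphics::plot(sw$h_cm, sw$comfort_C_at_mass, type = "l",
                   xlab = "h (cm)", ylab = "comfort C",
                   main = sprintf("Comfort at %.1f kg", fixed_mass_kg), ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::plot(sw$h_cm, sw$rwl_kg * GRAVITY, type = "l",
                   xlab = "h (cm)", ylab = "G at RWL (N)",
                   main = "Limit load weight force", ...)
  }
  invisible(x)
}

#' Simulate worker-task records from the model's population
#'
#' Draws synthetic worker-task records (see [generate_fixture_tasks()]);
#' provided as the \code{simulate} method so the model object supports the
#' usual generate-then-refit workflow in tests.
#'
#' @param object A [waist_model()] (the population ranges are fixed; the
#'   object selects the method).
#' @param nsim Number of records.
#' @param seed Integer seed (required for reproducibility; defaults to 1).
#' @param ... Unused.
#' @return A data frame of task records.
#' @export
simulate.waist_model <- function(object, nsim = 10, seed = 1L, ...) {
  generate_fixture_tasks(seed = seed, n = nsim)
}

#' Residual loads against the recommended weight limit
#'
#' For a set of tasks, the signed mass margin mass - RWL(h) in kg: positive
#' residuals are loads above the limit.
#'
#' @param object A [waist_model()].
#' @param newdata Data frame with \code{height_cm} and \code{mass_kg};
#'   defaults to the limit-load grid (all-zero residuals).
#' @param ... Unused.
#' @return Numeric vector of mass margins, kg (NA out of domain).
#' @export
residuals.waist_model <- function(object, newdata = NULL, ...) {
  pr <- predict(object, newdata)
  pr$mass_kg - pr$rwl_kg
}
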