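# NIOSH maximum acceptable L5-S1 compression, N. Named here once; every
# function that uses it takes it as an overridable argument.
NIOSH_COMPRESSION_CRITERION <- 3400

#' L5-S1 load decomposition into compression and shear
#'
#' Resolves the static load on the L5-S1 disc into the component along the
#' disc axis (normal, sigma) and across it (shear, tau):
#' sigma = F + (w M + G) cos(alpha), tau = (w M + G) sin(alpha), with
#' resultant N = sqrt(sigma^2 + tau^2), where F is the erector spinae force
#' and w = 0.47 the weight fraction of the body above L5-S1. The resultant
#' is compared against the NIOSH compression criterion (3400 N by default).
#'
#' @inheritParams erector_force
#' @param criterion Maximum acceptable L5-S1 force, N.
#' @return A data frame with columns \code{normal_sigma}, \code{shear_tau},
#'   \code{resultant_N}, \code{below_criterion}, \code{criterion} and the
#'   posture columns of [trunk_cosine()].
#' @export
#' @examples
#' stress_decomposition(G = 34.80 * 9.8, h = 70)
stress_decomposition <- function(G, h, profile = standard_profile(),
                                 mode = c("paper_rounded", "derived"),
                                 criterion = NIOSH_COMPRESSION_CRITERION) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  # F from the published closed form (abdominal relief off) for consistency
  # with the validated numbers
  fr <- erector_force(G, h, profile, mode, include_abdominal = FALSE)
  w <- profile$upper_body_weight_frac
  above <- w * profile$weight_force_M + fr$object_weight_G
  sigma <- fr$erector_force_F + above * fr$cos_alpha
  tau <- above * fr$sin_alpha
  N <- sqrt(sigma^2 + tau^2)
  cbind(data.frame(normal_sigma = sigma, shear_tau = tau, resultant_N = N,
                   below_criterion = N < criterion, criterion = criterion,
                   object_weight_G = fr$object_weight_G),
        fr[c("object_height_h", "cos_alpha", "sin_alpha", "alpha_deg",
             "in_range")])
}

#' Validate the comfort model against the L5-S1 compression criterion
#'
#' At the limit load (G = RWL, comfort C = 0) the model is considered
#' usable only if the L5-S1 resultant stays below the compression
#' criterion across the working range of heights. Evaluates the stress
#' decomposition at G = RWL(h) over a height grid and reports the grid
#' extremes and an all-below flag.
#'
#' @inheritParams trunk_cosine
#' @param h_grid Heights to evaluate, cm (default the integer grid
#'   34..72).
#' @param criterion Maximum acceptable L5-S1 force, N.
#' @return An object of class \code{stress_validation}: a list with the
#'   per-height data frame \code{rows} (columns \code{h_cm},
#'   \code{rwl_kg}, \code{F_N}, \code{sigma_N}, \code{tau_N}, \code{N_N},
#'   \code{below_criterion}), the grid extremes \code{min_N},
#'   \code{h_at_min}, \code{max_N}, \code{h_at_max}, the \code{criterion}
#'   and \code{all_below_criterion}.
#' @export
#' @examples
#' validate_at_rwl()
validate_at_rwl <- function(profile = standard_profile(), h_grid = 34:72,
                            criterion = NIOSH_COMPRESSION_CRITERION,
                            mode = c("paper_rounded", "derived")) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(h_grid) || length(h_grid) == 0L)
    stop("`h_grid` must be a non-empty numeric vector of heights (cm)")
  rows <- do.call(rbind, lapply(h_grid, function(h) {
    rwl <- rwl_chinese(h, profile, mode)
    G <- rwl$rwl_kg * GRAVITY
    st <- stress_decomposition(G, h, profile, mode, criterion)
    data.frame(h_cm = h, rwl_kg = rwl$rwl_kg,
               F_N = erector_force(G, h, profile, mode)$erector_force_F,
               sigma_N = st$normal_sigma, tau_N = st$shear_tau,
               N_N = st$resultant_N, below_criterion = st$below_criterion)
  }))
  i_min <- which.min(rows$N_N)
  i_max <- which.max(rows$N_N)
  structure(list(rows = rows,
                 min_N = rows$N_N[i_min], h_at_min = rows$h_cm[i_min],
                 max_N = rows$N_N[i_max], h_at_max = rows$h_cm[i_max],
                 criterion = criterion,
                 all_below_criterion = all(rows$below_criterion)),
            class = "stress_validation")
}

#' @export
print.stress_validation <- function(x, ...) {
  cat(sprintf("L5-S1 validation at the limit load (C = 0), %d heights\n",
              nrow(x$rows)))
  cat(sprintf("  resultant N: min %.2f N at h = %g cm, max %.2f N at h = %g cm\n",
              x$min_N, x$h_at_min, x$max_N, x$h_at_max))
  cat(sprintf("  criterion %.0f N: %s\n", x$criterion,
              if (x$all_below_criterion) "all heights below (model usable)"
              else "EXCEEDED at one or more heights"))
  invisible(x)
}
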