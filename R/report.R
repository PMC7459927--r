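#' Height sweep of the lifting model
#'
#' Evaluates the full model over a grid of lifting heights at the limit
#' load: at each height the China-adapted RWL, the erector spinae force
#' F(RWL), and the L5-S1 stress decomposition at G = RWL; optionally also
#' the comfort score and lifting index for a user-fixed object mass. These
#' are the tabular data behind the model's published result curves.
#'
#' @inheritParams trunk_cosine
#' @param h_start,h_stop,step Grid bounds (inclusive) and spacing, cm. The
#'   default integer grid 34..72 mirrors the span of the published result
#'   figures; any grid inside the model domain is accepted.
#' @param fixed_mass_kg If given, add columns \code{comfort_C_at_mass} and
#'   \code{LI_at_mass} for an object of this mass lifted at each height.
#' @param criterion Maximum acceptable L5-S1 force, N.
#' @return A data frame with one row per height: \code{h_cm},
#'   \code{rwl_kg}, \code{F_at_rwl_N}, \code{sigma_N}, \code{tau_N},
#'   \code{resultant_N}, and the optional comfort columns.
#' @export
#' @examples
#' head(sweep_heights())
sweep_heights <- function(profile = standard_profile(), h_start = 34,
                          h_stop = 72, step = 1, fixed_mass_kg = NULL,
                          mode = c("paper_rounded", "derived"),
                          criterion = NIOSH_COMPRESSION_CRITERION) {
  profile <- as_waist_profile(profile)
  mode <- match.arg(mode)
  if (!is.numeric(step) || step <= 0) stop("`step` must be positive (cm)")
  if (h_stop < h_start) stop("empty grid: `h_stop` is below `h_start`")
  grid <- seq(h_start, h_stop, by = step)
  val <- validate_at_rwl(profile, grid, criterion, mode)
  out <- val$rows
  names(out)[names(out) == "F_N"] <- "F_at_rwl_N"
  names(out)[names(out) == "N_N"] <- "resultant_N"
  out$below_criterion <- NULL
  if (!is.null(fixed_mass_kg)) {
    cl <- vapply(grid, function(h) {
      a <- assess(fixed_mass_kg, h, profile, mode = mode)
      c(a$comfort_C, a$lifting_index_LI)
    }, numeric(2))
    out$comfort_C_at_mass <- cl[1, ]
    out$LI_at_mass <- cl[2, ]
  }
  out
}

#' Batch assessment of worker-task records
#'
#' Assesses a table of lifting tasks, one worker-task per row. Each row
#' gets its own anthropometric profile from the worker's stature and body
#' mass; heights outside the worker's model domain are flagged
#' (\code{in_domain = FALSE}, numeric results \code{NA}) and processing
#' continues, so one bad row never aborts a batch.
#'
#' @param records A data frame with columns \code{worker_id},
#'   \code{stature_cm}, \code{body_mass_kg}, \code{object_mass_kg},
#'   \code{object_height_cm}, and optionally \code{frequency} (default
#'   0.2 lifts/min) and \code{duration_class} (default \code{"1h"}).
#'   Non-default frequency/duration enter through the frequency
#'   multiplier of the China-adapted RWL.
#' @param tol LI half-width of the \code{limit} class. Batch inputs are
#'   typically entered at two decimals, so the default 1e-3 lets a mass
#'   recorded as its RWL classify as \code{limit} rather than falling a
#'   rounding error to either side.
#' @inheritParams sweep_heights
#' @return A data frame with one row per record: the identifying input
#'   columns plus \code{rwl_kg}, \code{F_N}, \code{F_at_rwl_N},
#'   \code{comfort_C}, \code{LI}, \code{sigma_N}, \code{tau_N},
#'   \code{resultant_N}, \code{below_criterion}, \code{category},
#'   \code{in_domain} and \code{note}.
#' @seealso [read_task_csv()], [generate_fixture_tasks()]
#' @export
assess_batch <- function(records, tol = 1e-3,
                         mode = c("paper_rounded", "derived"),
                         criterion = NIOSH_COMPRESSION_CRITERION) {
  mode <- match.arg(mode)
  records <- validate_task_records(records)
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    base <- data.frame(worker_id = r$worker_id, stature_cm = r$stature_cm,
                       body_mass_kg = r$body_mass_kg,
                       object_mass_kg = r$object_mass_kg,
                       object_height_cm = r$object_height_cm,
                       rwl_kg = NA_real_, F_N = NA_real_,
                       F_at_rwl_N = NA_real_, comfort_C = NA_real_,
                       LI = NA_real_, sigma_N = NA_real_, tau_N = NA_real_,
                       resultant_N = NA_real_, below_criterion = NA,
                       category = NA_character_, in_domain = FALSE,
                       note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      p <- custom_profile(r$stature_cm, r$body_mass_kg)
      h <- r$object_height_cm
      rwl <- rwl_chinese_at(h, p, mode, r$frequency, r$duration_class)
      fm_ratio <- rwl$multipliers[["FM"]]
      G <- r$object_mass_kg * GRAVITY
      F <- erector_force(G, h, p, mode)$erector_force_F
      F_rwl <- erector_force(rwl$rwl_kg * GRAVITY, h, p, mode)$erector_force_F
      st <- stress_decomposition(G, h, p, mode, criterion)
      LI <- r$object_mass_kg / rwl$rwl_kg
      base$rwl_kg <- rwl$rwl_kg
      base$F_N <- F
      base$F_at_rwl_N <- F_rwl
      base$comfort_C <- 1 - F / F_rwl
      base$LI <- LI
      base$sigma_N <- st$normal_sigma
      base$tau_N <- st$shear_tau
      base$resultant_N <- st$resultant_N
      base$below_criterion <- st$below_criterion
      base$category <- classify_load(LI, tol)
      base$in_domain <- TRUE
      base
    }, error = function(e) {
      base$note <- conditionMessage(e)
      base
    })
    res
  })
  do.call(rbind, out)
}

# China-adapted RWL at height h with a non-default frequency/duration
# entering through the FM lookup.
rwl_chinese_at <- function(h, profile, mode, frequency, duration_class) {
  h_min <- valid_height_range(profile, mode)[["h_min"]]
  if (h >= 74)
    stop("h = ", h, " cm is at or above the 74 cm functional hand height")
  if (h < h_min)
    stop(sprintf("h = %g cm is below the posture model's lower bound %.1f cm",
                 h, h_min))
  rwl_niosh(lift_conditions(
    horizontal_dist = 25, vertical_origin_V = h, travel_D = 74 - h,
    frequency = frequency, duration_class = duration_class,
    asymmetry_A = 0, coupling_CM = 0.90, load_constant = 20,
    vm_reference = 72
  ))
}

validate_task_records <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  needed <- c("worker_id", "stature_cm", "body_mass_kg", "object_mass_kg",
              "object_height_cm")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("task records are missing column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(records$frequency)) records$frequency <- 0.2
  if (is.null(records$duration_class)) records$duration_class <- "1h"
  num <- c("stature_cm", "body_mass_kg", "object_mass_kg",
           "object_height_cm", "frequency")
  for (col in num) {
    bad <- which(!is.numeric(records[[col]]) | is.na(records[[col]]) |
                   records[[col]] < 0)
    if (length(bad))
      stop(sprintf("column `%s` has a missing or negative value at row %d",
                   col, bad[1]))
  }
  records
}

#' Read worker-task records from CSV
#'
#' @param path CSV file with the [assess_batch()] input columns.
#' @return A validated data frame of task records.
#' @export
read_task_csv <- function(path) {
  records <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  validate_task_records(records)
}

#' Generate deterministic synthetic worker-task records
#'
#' Draws reproducible pseudo-random worker-task records for testing and
#' demonstration: statures uniform on [155, 190] cm, body masses uniform on
#' [50, 95] kg, object heights spread across each worker's own valid
#' lifting range (below the 74 cm hand-height cap), and object masses
#' uniform on [0, 2] times the RWL at that height, so the generated lifting
#' indices straddle the LI = 1 limit. The caller's RNG state is left
#' untouched.
#'
#' @param seed Integer seed; the same seed always yields identical records.
#' @param n Number of records, > 0.
#' @return A data frame of task records accepted by [assess_batch()].
#' @export
#' @examples
#' generate_fixture_tasks(seed = 1, n = 5)
generate_fixture_tasks <- function(seed, n) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  stature <- runif(n, 155, 190)
  body_mass <- runif(n, 50, 95)
  rows <- lapply(seq_len(n), function(i) {
    p <- custom_profile(stature[i], body_mass[i])
    h_min <- valid_height_range(p)[["h_min"]]
    h_max <- min(74, valid_height_range(p)[["h_max"]])
    # keep a margin off both domain edges so heights survive the 0.1 cm
    # rounding below for any stature in range
    h <- h_min + (0.02 + 0.96 * runif(1)) * (h_max - h_min)
    rwl <- rwl_chinese(h, p)$rwl_kg
    data.frame(worker_id = sprintf("W%04d", i),
               stature_cm = round(stature[i], 1),
               body_mass_kg = round(body_mass[i], 1),
               object_mass_kg = round(runif(1, 0, 2) * rwl, 2),
               object_height_cm = round(h, 1),
               frequency = 0.2, duration_class = "1h",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write and re-read model output tables
#'
#' Thin CSV writers/readers that preserve full double precision, so a
#' written sweep or batch report re-reads to the values it was computed
#' with.
#'
#' @param x A data frame (sweep rows, batch report, validation rows).
#' @param path Output CSV path.
#' @return \code{write_report_csv} returns \code{path} invisibly;
#'   \code{read_report_csv} the data frame.
#' @export
write_report_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
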