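# Acceleration of gravity for every kg <-> N conversion in the package
# (m/s^2). The published weight-force constants (578 N for a 59 kg worker)
# are built on 9.8, never 9.81.
GRAVITY <- 9.8

#' Body-segment inertial parameter table for Chinese adult males
#'
#' Returns the bundled body-segment inertial parameters (GB/T 17245-2004,
#' adult males, 18-60 years): for each somatic segment the distance from its
#' stated measurement start point to the segment centroid, the centroid's
#' position as a percentage of segment length, and the segment mass as a
#' percentage of whole-body mass.
#'
#' @return A data frame with one row per segment and columns
#'   \code{segment}, \code{centroid_position_mm}, \code{relative_position_pct},
#'   \code{relative_mass_pct} and \code{bilateral} (\code{TRUE} for segments
#'   present on both sides of the body, whose relative mass therefore counts
#'   twice in whole-body sums). The \code{Whole} row carries the whole-body
#'   centroid and has no relative mass.
#' @seealso [standard_profile()], [iliac_spine_height()], [reference_stature()]
#' @export
#' @examples
#' segment_table()
segment_table <- function() {
  path <- system.file("extdata", "segment_inertia.csv",
                      package = "waistload", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(
    nrow(tab) == 10L,
    all(tab$centroid_position_mm > 0),
    all(tab$relative_position_pct > 0 & tab$relative_position_pct < 100),
    all(is.na(tab$relative_mass_pct) |
          (tab$relative_mass_pct > 0 & tab$relative_mass_pct <= 100))
  )
  tab
}

#' Reference stature from the whole-body centroid
#'
#' The whole-body centroid position (measured from the head vertex) divided
#' by its relative position along the body reconstructs the stature of the
#' reference male: 734.2 mm / 0.438 = 1676 mm, matching the 50th-percentile
#' Chinese adult male (GB10000-88).
#'
#' @param whole_centroid_position Whole-body centroid position in mm.
#' @param whole_relative_position Centroid's relative position as a fraction
#'   in (0, 1).
#' @return Stature in mm (unrounded).
#' @export
#' @examples
#' round(reference_stature(734.2, 0.438)) # 1676
reference_stature <- function(whole_centroid_position = 734.2,
                              whole_relative_position = 0.438) {
  if (!is.numeric(whole_centroid_position) || whole_centroid_position <= 0)
    stop("`whole_centroid_position` must be a positive length (mm)")
  if (!is.numeric(whole_relative_position) ||
      whole_relative_position <= 0 || whole_relative_position >= 1)
    stop("`whole_relative_position` must be a fraction strictly between 0 and 1")
  whole_centroid_position / whole_relative_position
}

#' Standing height of the anterior superior iliac spine
#'
#' Stacks the thigh, lower leg and foot: each segment's length is
#' reconstructed from its distal-referenced centroid position,
#' length = centroid_position / (1 - relative_position), and the three
#' lengths are summed. The anterior superior iliac spine height is used as
#' a proxy for the standing height of L5-S1 (the two are approximately
#' level; this is an approximation of the source anthropometry, not an
#' anatomical identity).
#'
#' @param segments A segment table as returned by [segment_table()].
#' @return Height in mm (unrounded; 908.8 mm for the bundled table, rounding
#'   to the published 909 mm).
#' @export
iliac_spine_height <- function(segments = segment_table()) {
  needed <- c("Thigh", "Lower leg", "Foot")
  idx <- match(needed, segments$segment)
  if (anyNA(idx))
    stop("segment table is missing row(s): ",
         paste(needed[is.na(idx)], collapse = ", "))
  rows <- segments[idx, ]
  sum(rows$centroid_position_mm / (1 - rows$relative_position_pct / 100))
}

new_waist_profile <- function(stature_H, weight_force_M, a, b, k1, k2, k3,
                              j1, j2, j3, erector_arm_frac,
                              abdominal_arm_frac, abdominal_force_frac,
                              upper_body_weight_frac, constants) {
  p <- list(
    stature_H = stature_H, weight_force_M = weight_force_M,
    a = a, b = b, k1 = k1, k2 = k2, k3 = k3,
    j1 = j1, j2 = j2, j3 = j3,
    erector_arm_frac = erector_arm_frac,
    abdominal_arm_frac = abdominal_arm_frac,
    abdominal_force_frac = abdominal_force_frac,
    upper_body_weight_frac = upper_body_weight_frac,
    constants = constants
  )
  fr <- unlist(p[c("a", "b", "k1", "k2", "k3", "j1", "j2", "j3",
                   "erector_arm_frac", "abdominal_arm_frac",
                   "abdominal_force_frac", "upper_body_weight_frac")])
  stopifnot(
    stature_H > 0, weight_force_M > 0,
    all(fr > 0 & fr < 1),
    a > b  # otherwise cos(alpha) never crosses 0 at a positive height
  )
  structure(p, class = "waist_profile")
}

#' Anthropometric profile of the standard Chinese male worker
#'
#' The 50th-percentile Chinese adult male (18-60 years): stature H = 168 cm,
#' body mass 59 kg (weight force M = 578 N), and the dimensionless model
#' constants derived from the bundled segment table and GB10000-88 body
#' dimensions:
#' \describe{
#'   \item{a = 0.54}{L5-S1 standing height over stature (H1/H).}
#'   \item{b = 0.37}{arm length over stature (H2/H).}
#'   \item{k1, k2, k3 = 0.39, 0.27, 0.15}{distances from L5-S1 to the head
#'     centroid, the acromion, and the upper-trunk centroid, as fractions of
#'     stature.}
#'   \item{j1, j2, j3 = 0.0862, 0.0864, 0.30}{weights of head+neck, both
#'     arms, and the trunk above L5-S1, as fractions of body weight.}
#'   \item{erector_arm_frac = 0.0298}{erector spinae moment arm (about 5 cm)
#'     over stature.}
#'   \item{abdominal_arm_frac = 0.068, abdominal_force_frac = 0.01}{moment
#'     arm and magnitude of the intra-abdominal pressure force, as fractions
#'     of stature and body weight.}
#'   \item{upper_body_weight_frac = 0.47}{weight of the whole body above
#'     L5-S1 over body weight, used in the spinal stress decomposition.}
#' }
#'
#' @param constants \code{"published"} (default) uses the rounded constants
#'   above, which are the ones that reproduce the model's published results;
#'   \code{"derived"} recomputes them unrounded from the segment table and
#'   the raw GB dimensions (shoulder height 1367 mm, functional hand height
#'   741 mm, iliac spine height 908.8 mm) for sensitivity checks.
#' @return An object of class \code{waist_profile}.
#' @seealso [custom_profile()], [waist_model()]
#' @export
#' @examples
#' standard_profile()
standard_profile <- function(constants = c("published", "derived")) {
  constants <- match.arg(constants)
  if (constants == "published") {
    return(new_waist_profile(
      stature_H = 168, weight_force_M = 578,
      a = 0.54, b = 0.37, k1 = 0.39, k2 = 0.27, k3 = 0.15,
      j1 = 0.0862, j2 = 0.0864, j3 = 0.30,
      erector_arm_frac = 0.0298,
      abdominal_arm_frac = 0.068, abdominal_force_frac = 0.01,
      upper_body_weight_frac = 0.47,
      constants = constants
    ))
  }
  tab <- segment_table()
  H_mm <- reference_stature(
    tab$centroid_position_mm[tab$segment == "Whole"],
    tab$relative_position_pct[tab$segment == "Whole"] / 100
  )
  iliac <- iliac_spine_height(tab)
  shoulder_mm <- 1367   # acromion standing height, GB10000-88 50th pct male
  hand_mm <- 741        # functional hand height, same source
  neck <- tab[tab$segment == "Neck", ]
  # head+neck segment length from its vertex-referenced centroid
  headneck_len <- neck$centroid_position_mm /
    (neck$relative_position_pct / 100)
  arms_pct <- 2 * sum(tab$relative_mass_pct[
    tab$segment %in% c("Upper arm", "Forearm", "Hand")])
  j1 <- neck$relative_mass_pct / 100
  j2 <- arms_pct / 100
  j3 <- 0.30  # trunk above L5-S1; from cadaver work, not in the table
  new_waist_profile(
    stature_H = H_mm / 10, weight_force_M = 59 * GRAVITY,
    a = iliac / H_mm,
    b = (shoulder_mm - hand_mm) / H_mm,
    k1 = ((H_mm - iliac) - neck$centroid_position_mm) / H_mm,
    k2 = (shoulder_mm - iliac) / H_mm,
    k3 = ((H_mm - headneck_len - iliac) / 2) / H_mm,
    j1 = j1, j2 = j2, j3 = j3,
    erector_arm_frac = 50 / H_mm,
    abdominal_arm_frac = 114.3 / H_mm, abdominal_force_frac = 0.01,
    upper_body_weight_frac = j1 + j2 + j3,
    constants = constants
  )
}

#' Anthropometric profile for a custom worker
#'
#' Scales the standard profile to a worker's own stature and body mass. All
#' dimensionless constants (segment-weight and lever-arm fractions) are kept
#' from the standard male profile; only H and the weight force M change, so
#' the profile is scale-free in its fractions.
#'
#' @param stature_cm Stature in cm, within [100, 230].
#' @param mass_kg Body mass in kg, within [30, 200]; converted to weight
#'   force with g = 9.8 m/s^2. At exactly the standard dimensions (168 cm,
#'   59 kg) the standard profile is returned, whose published weight force
#'   is the rounded 578 N rather than the exact 578.2 N.
#' @inheritParams standard_profile
#' @return An object of class \code{waist_profile}.
#' @export
#' @examples
#' custom_profile(180, 80)
custom_profile <- function(stature_cm, mass_kg,
                           constants = c("published", "derived")) {
  if (!is.numeric(stature_cm) || length(stature_cm) != 1L ||
      is.na(stature_cm) || stature_cm < 100 || stature_cm > 230)
    stop("`stature_cm` must be a single value in [100, 230]")
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L ||
      is.na(mass_kg) || mass_kg < 30 || mass_kg > 200)
    stop("`mass_kg` must be a single value in [30, 200]")
  p <- standard_profile(constants)
  if (stature_cm == 168 && mass_kg == 59) return(p)
  p$stature_H <- stature_cm
  p$weight_force_M <- mass_kg * GRAVITY
  p
}

#' @export
print.waist_profile <- function(x, ...) {
  cat("Anthropometric profile (", x$constants, " constants)\n", sep = "")
  cat(sprintf("  stature H        %.1f cm\n", x$stature_H))
  cat(sprintf("  weight force M   %.1f N (%.1f kg at g = %.1f)\n",
              x$weight_force_M, x$weight_force_M / GRAVITY, GRAVITY))
  cat(sprintf("  a, b             %.4f, %.4f\n", x$a, x$b))
  cat(sprintf("  k1, k2, k3       %.4f, %.4f, %.4f\n", x$k1, x$k2, x$k3))
  cat(sprintf("  j1, j2, j3       %.4f, %.4f, %.4f\n", x$j1, x$j2, x$j3))
  cat(sprintf("  erector arm      %.4f H\n", x$erector_arm_frac))
  cat(sprintf("  abdominal F4, L4 %.4f M, %.4f H\n",
              x$abdominal_force_frac, x$abdominal_arm_frac))
  cat(sprintf("  upper-body wt    %.4f M\n", x$upper_body_weight_frac))
  invisible(x)
}

profile_fields <- c("stature_H", "weight_force_M", "a", "b", "k1", "k2",
                    "k3", "j1", "j2", "j3", "erector_arm_frac",
                    "abdominal_arm_frac", "abdominal_force_frac",
                    "upper_body_weight_frac", "constants")

#' Read or write an anthropometric profile
#'
#' Profiles serialize to flat JSON or YAML keyed by field name, so worker
#' profiles can be stored beside task data and passed to the command-line
#' front end.
#'
#' @param profile A \code{waist_profile}.
#' @param path File path; the format is taken from the extension
#'   (\code{.json}, \code{.yml}/\code{.yaml}) unless \code{format} is given.
#' @param format \code{"json"} or \code{"yaml"}.
#' @return \code{write_profile} returns \code{path} invisibly;
#'   \code{read_profile} returns a \code{waist_profile}.
#' @export
write_profile <- function(profile, path, format = c("auto", "json", "yaml")) {
  stopifnot(inherits(profile, "waist_profile"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  x <- unclass(profile)[profile_fields]
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  x <- if (format == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  missing <- setdiff(setdiff(profile_fields, "constants"), names(x))
  if (length(missing))
    stop("profile file is missing field(s): ", paste(missing, collapse = ", "))
  x$constants <- if (is.null(x$constants)) "published" else x$constants
  do.call(new_waist_profile, x[profile_fields])
}
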