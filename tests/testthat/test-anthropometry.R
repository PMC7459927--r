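test_that("bundled segment table carries the printed inertial parameters", {
  tab <- segment_table()
  expect_equal(nrow(tab), 10L)
  neck <- tab[tab$segment == "Neck", ]
  expect_equal(neck$centroid_position_mm, 117.8)
  expect_equal(neck$relative_position_pct, 46.9)
  expect_equal(neck$relative_mass_pct, 8.62)
  whole <- tab[tab$segment == "Whole", ]
  expect_equal(whole$centroid_position_mm, 734.2)
  expect_equal(whole$relative_position_pct, 43.8)
  # bilateral segments count twice in the whole-body mass budget
  seg <- tab[tab$segment != "Whole", ]
  total <- sum(seg$relative_mass_pct * ifelse(seg$bilateral, 2, 1))
  expect_equal(total, 100, tolerance = 0.001)
  # the arm and head-neck rows reconstruct the j weight fractions
  arms <- 2 * sum(seg$relative_mass_pct[
    seg$segment %in% c("Upper arm", "Forearm", "Hand")])
  expect_equal(arms / 100, std$j2)
  expect_equal(neck$relative_mass_pct / 100, std$j1)
})

test_that("reference stature reconstructs from the whole-body centroid", {
  expect_equal(round(reference_stature(734.2, 0.438)), 1676)
  expect_equal(reference_stature(500, 0.5), 1000)
  expect_error(reference_stature(734.2, 1.0), "fraction")
  expect_error(reference_stature(734.2, 0), "fraction")
  expect_error(reference_stature(-1, 0.438), "positive")
})

test_that("iliac spine height stacks leg segment lengths", {
  tab <- segment_table()
  expect_equal(round(iliac_spine_height(tab)), 909)
  # per-segment reconstructed lengths
  term <- function(seg) {
    r <- tab[tab$segment == seg, ]
    r$centroid_position_mm / (1 - r$relative_position_pct / 100)
  }
  expect_equal(term("Thigh"), 465.3, tolerance = 0.05)
  expect_equal(term("Lower leg"), 369.2, tolerance = 0.05)
  expect_equal(term("Foot"), 74.3, tolerance = 0.05)
  # a single segment with centroid at half its length is twice the centroid
  one <- data.frame(segment = c("Thigh", "Lower leg", "Foot"),
                    centroid_position_mm = c(100, 1e-9, 1e-9),
                    relative_position_pct = c(50, 50, 50))
  expect_equal(iliac_spine_height(one), 200, tolerance = 1e-6)
  expect_error(iliac_spine_height(tab[tab$segment != "Foot", ]), "Foot")
})

test_that("standard profile carries the published constants", {
  expect_s3_class(std, "waist_profile")
  expect_equal(std$stature_H, 168)
  # published value: 59 kg * 9.8 printed as 578 N (integer-rounded)
  expect_equal(std$weight_force_M, 578)
  expect_equal(round(59 * 9.8), std$weight_force_M)
  expect_equal(std$a, 0.54)
  expect_equal(std$b, 0.37)
  expect_equal(std$k1, 0.39)
  expect_equal(std$k2, 0.27)
  expect_equal(std$k3, 0.15)
  expect_equal(std$j1, 0.0862)
  expect_equal(std$j2, 0.0864)
  expect_equal(std$j3, 0.30)
  expect_equal(std$erector_arm_frac, 0.0298)
  expect_equal(std$abdominal_arm_frac, 0.068)
  expect_equal(std$abdominal_force_frac, 0.01)
  expect_equal(std$upper_body_weight_frac, 0.47)
  # j fractions sum to 0.4726; the 0.47 upper-body fraction is that sum
  # at two decimals
  expect_equal(std$j1 + std$j2 + std$j3, 0.4726)
  expect_lt(abs(std$upper_body_weight_frac - (std$j1 + std$j2 + std$j3)),
            0.006)
})

test_that("standard profile round-trips through the derivation chain", {
  # stature from the whole-body centroid, in cm
  expect_equal(round(reference_stature(734.2, 0.438) / 10), std$stature_H)
  # L5-S1 height proxy: a * H recovers the iliac spine height in cm
  expect_equal(round(iliac_spine_height() / 10), round(std$a * std$stature_H))
})

test_that("derived-constants profile stays close to the published one", {
  d <- standard_profile("derived")
  for (f in c("a", "b", "k1", "k2", "k3"))
    expect_equal(d[[f]], std[[f]], tolerance = 0.03)
  expect_equal(d$erector_arm_frac, std$erector_arm_frac, tolerance = 0.01)
  expect_equal(d$upper_body_weight_frac, 0.4726)
  expect_equal(d$stature_H, 167.6, tolerance = 0.1)
})

test_that("custom profiles rescale without touching the fractions", {
  # the standard dimensions return the standard profile, including its
  # published (rounded) weight force of 578 N
  expect_equal(unclass(custom_profile(168, 59)), unclass(std))
  expect_equal(custom_profile(168, 59)$weight_force_M, 578)
  big <- custom_profile(180, 80)
  expect_equal(big$weight_force_M, 784)
  expect_equal(big$stature_H, 180)
  for (f in c("a", "b", "k1", "k2", "k3", "j1", "j2", "j3",
              "erector_arm_frac", "upper_body_weight_frac"))
    expect_identical(big[[f]], std[[f]])
  expect_error(custom_profile(90, 59), "stature")
  expect_error(custom_profile(168, 250), "mass")
  expect_error(custom_profile(NA, 59), "stature")
})

test_that("profiles round-trip through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_profile(custom_profile(181, 77), path)
    back <- read_profile(path)
    expect_s3_class(back, "waist_profile")
    expect_equal(unclass(back), unclass(custom_profile(181, 77)))
  }
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(stature_H = 168), bad, auto_unbox = TRUE)
  expect_error(read_profile(bad), "missing field")
})
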