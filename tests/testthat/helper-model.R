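std <- standard_profile()
g <- 9.8

# weight force (N) of the China-adapted RWL at height h, standard worker
rwl_force <- function(h, profile = std) rwl_chinese(h, profile)$rwl_kg * g

# absolute-tolerance assertion (testthat's `tolerance` is relative)
expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
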