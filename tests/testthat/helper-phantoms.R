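# Shared, lazily built phantom fixtures. Everything is generated in code at
# test time; expensive 12-line phantoms are cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# flat-membrane scan: constant-depth BM trace, noiseless
flat_trace <- function(step_um = 15) {
  tr <- physical_trace(seq(-4500, 4500, by = step_um),
                       rep(0, length(seq(-4500, 4500, by = step_um))))
  attr(tr, "angle_deg") <- 0
  tr
}

flat_render <- function() {
  fixture("flat_render", function() render_bscan(flat_trace(), calibration(7, 15)))
}

# 12-line staphyloma phantom with speckle, fixed seed (shared by the
# segmentation-recovery and repeatability checks)
staph_eye_101 <- function() {
  fixture("staph_eye_101", function()
    phantom_eye(surface_model("staphyloma"), n_angles = 12,
                speckle_sigma = 0.25, seed = 101, eye_id = "staph101"))
}

staph_eye_202 <- function() {
  fixture("staph_eye_202", function()
    phantom_eye(surface_model("staphyloma"), n_angles = 12,
                speckle_sigma = 0.25, seed = 202, eye_id = "staph202"))
}

run_101 <- function() {
  fixture("run_101", function() run_eye(staph_eye_101()$set))
}

run_202 <- function() {
  fixture("run_202", function() run_eye(staph_eye_202()$set))
}

# noiseless analytic curvature profiles of the default staphyloma surface
staph_profiles <- function() {
  fixture("staph_profiles", function() {
    trs <- sample_radial_traces(surface_model("staphyloma"), 12, 4500, 1)
    list(profiles = lapply(trs, curvature_profile),
         angles = vapply(trs, attr, numeric(1), "angle_deg"))
  })
}

sphere_profiles <- function() {
  fixture("sphere_profiles", function() {
    trs <- sample_radial_traces(surface_model("sphere"), 12, 4500, 1)
    list(profiles = lapply(trs, curvature_profile),
         angles = vapply(trs, attr, numeric(1), "angle_deg"))
  })
}

# smooth random membrane trace for property checks (gentle physiological slopes)
random_smooth_trace <- function(n = 2001, step = 1) {
  bumps <- stats::rnorm(5, 0, 200)
  ctrs <- stats::runif(5, -800, 800)
  sig <- stats::runif(5, 150, 500)
  s <- seq(-(n - 1) / 2, (n - 1) / 2, by = step)
  d <- rowSums(vapply(1:5, function(i) bumps[i] * exp(-(s - ctrs[i])^2 / (2 * sig[i]^2)),
                      numeric(length(s))))
  physical_trace(s, d)
}
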