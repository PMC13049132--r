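# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small phantom/influence for unit and gradient tests: coarse 4 mm grid
# (58k voxels, ~5k high-dose model voxels, ~200 beamlets), same anatomy.
small_config <- function(seed = 3)
  phantom_config(dims = c(44L, 44L, 30L), spacing = c(4, 4, 4),
                 gtv_center = c(26, 4, 2), gtv_radius = 16, ptv_margin = 4,
                 jitter = 1, seed = seed)

small_phantom <- function() fixture("small_phantom", function() {
  make_phantom(small_config())
})

small_influence <- function() fixture("small_influence", function() {
  build_influence(small_phantom(),
                  beams = default_beams(spot_spacing = 12, layer_spacing = 12))
})

small_problem <- function() fixture("small_problem", function() {
  plan_problem(small_phantom(), small_influence())
})

# A fluence giving clinically-scaled doses on the small phantom.
small_fluence <- function() fixture("small_fluence", function() {
  initial_fluence(small_problem())
})

# Default (study-condition) phantom at seed 1, for solver-level tests.
default_phantom <- function() fixture("default_phantom", function() {
  make_phantom(phantom_config(seed = 1))
})

default_influence <- function() fixture("default_influence", function() {
  build_influence(default_phantom())
})

default_problem <- function(freeze_active = TRUE) {
  key <- paste0("default_problem_", freeze_active)
  fixture(key, function() {
    plan_problem(default_phantom(), default_influence(),
                 freeze_active = freeze_active)
  })
}

baseline_result <- function() fixture("baseline_result", function() {
  solve_plan(default_problem())
})

with_polo_objective <- function(problem, function_id, weight) {
  problem$objectives <- c(problem$objectives,
                          list(objective_spec("PoloRegion", function_id, weight)))
  problem
}

all_polo_ids <- c("polo_ntcp", "polo_lse", "polo_hellinger_p",
                  "polo_hellinger_ptilde")

# Brute-force Euclidean distance: min over mask voxel centers.
brute_distance <- function(grid, mask) {
  xy <- voxel_coordinates(grid)
  src <- xy[as.vector(mask), , drop = FALSE]
  out <- apply(xy, 1, function(p)
    sqrt(min(colSums((t(src) - p)^2))))
  array(out, dim = grid$dims)
}

ptv_d95 <- function(result) {
  pr <- result$problem
  d_at_volume(pr$rbe * result$state$d[pr$struct_idx$PTV], 0.95)
}
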