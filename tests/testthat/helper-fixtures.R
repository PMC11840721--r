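# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small noise-free phantom at 30% burden, shared by CT/PET tests
fixture_phantom <- function() {
  memo("phantom_030", build_thorax_ct(burden = 0.3, seed = 101,
                                      noise = "none"))
}

# a uniform PET frame: every voxel carries `measured` kBq/mL
uniform_pet <- function(measured, shape = c(8, 8, 8), spacing = c(1, 1, 1),
                        frame_start = 15, frame_duration = 2) {
  volume_grid(array(measured, dim = shape), spacing = spacing,
              modality = "PET", frame_start = frame_start,
              frame_duration = frame_duration)
}

full_mask <- function(grid, label = "all") {
  roi_mask(array(TRUE, dim = dim(grid$values)), spacing = grid$spacing,
           origin = grid$origin, label = label)
}

# brute-force list of all orderings of a vector (oracle-side utility)
combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# two-group single-timepoint design for quick simulation tests
two_group_design <- function(n = 3, day = 21, burden_blm = 0.35, ...) {
  traj <- matrix(c(0, burden_blm), nrow = 2,
                 dimnames = list(c("NaCl", "BLM"), paste0("D", day)))
  study_design(groups = c("NaCl" = n, "BLM" = n), timepoints = day,
               trajectories = traj, ...)
}
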