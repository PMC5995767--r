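# Shared fixtures, built once per test run (lazily) and in code only.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_env)) assign(name, build(), envir = .fx_env)
  get(name, envir = .fx_env)
}

fx_sched <- function() fx("sched", default_frame_schedule)

# noise-free 4-participant cohort
fx_spec0 <- function() {
  fx("spec0", function() {
    cohort_spec(n_participants = 4, seed = 42, noise_blood = 0,
                noise_dynamic = 0)
  })
}

fx_metas0 <- function() fx("metas0", function() make_cohort(fx_spec0()))

fx_blood0 <- function() {
  fx("blood0", function() simulate_blood(fx_metas0()[[1]], fx_spec0(), 1L))
}

# ground-truth input function restricted to the 90-min scan grid
fx_truth_if <- function() {
  fx("truth_if", function() {
    tr <- fx_blood0()$true_if
    keep <- tr$time <= scan_end(fx_sched())
    input_function(tr$time[keep], tr$value[keep], id = tr$id,
                   provenance = "true")
  })
}

fx_roi <- function() fx("roi", function() make_roi_phantom(c(6, 6, 6)))

fx_params <- function() fx("params", roi_params_list)

# noise-free dynamic phantom for participant 1
fx_dyn0 <- function() {
  fx("dyn0", function() {
    simulate_dynamic(fx_metas0()[[1]], fx_roi(), fx_params(), fx_truth_if(),
                     fx_sched(), fx_blood0()$wholeblood, noise_scale = 0)
  })
}

# participant 1's reconstructed ppIF from the noise-free blood tables
fx_ppif0 <- function() {
  fx("ppif0", function() {
    bl <- fx_blood0()
    build_ppif(bl$continuous, bl$discrete, scan_end(fx_sched()), id = "P01")
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("max rel err %.3g within %.3g",
                              max(abs(actual / expected - 1)), tol))
}
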