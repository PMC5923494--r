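# Lazily computed, memoised scenario runs shared by the end-to-end tests.
# Study conditions: side-40 lattice, 20 replicates, 10 days sampled every
# 24 h (multifocus additionally at the 17-h media change), default generator
# parameters.

.scenario_cache <- new.env(parent = emptyenv())

scenario_cached <- function(name, expr) {
  if (!exists(name, envir = .scenario_cache))
    assign(name, force(expr), envir = .scenario_cache)
  get(name, envir = .scenario_cache)
}

acc_single_focus <- function() scenario_cached("single_focus",
  run_single_focus(side = 40, n_reps = 20, base_seed = 1, n_restarts = 8,
                   models = c("CC", "aCC", "aCC-dI")))

acc_multifocus <- function() scenario_cached("multifocus",
  run_multifocus(side = 40, n_reps = 20, base_seed = 1, n_restarts = 8,
                 models = c("CC", "aCC", "aCC-dI")))

acc_mixed_slow <- function() scenario_cached("mixed_slow",
  run_mixed_transmission("slow", side = 30, n_reps = 10, base_seed = 1,
                         n_restarts = 6, profile_beta_f = TRUE))

acc_mixed_fast <- function() scenario_cached("mixed_fast",
  run_mixed_transmission("fast", side = 30, n_reps = 10, base_seed = 1,
                         n_restarts = 6))
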