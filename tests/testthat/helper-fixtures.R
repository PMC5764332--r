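# Heavy shared fixtures, computed lazily once per test run.
.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# nominal 55-artery simulation at the production grid
nominal_sim <- function() {
  with_cache("nominal_sim", simulate_tree(default_tree()))
}

# same at half the grid spacing (grid-convergence checks)
nominal_sim_half <- function() {
  with_cache("nominal_sim_half",
             simulate_tree(default_tree(), config = solver_config(dx_cm = 0.125)))
}

# nominal simulation at the coarse desk grid
desk_sim <- function() {
  with_cache("desk_sim",
             simulate_tree(default_tree(),
                           config = solver_config(dx_cm = 1, periodicity_tol = 3e-3)))
}

# five noiseless synthetic subjects (3 male, 2 female) and their desk-budget
# fits: shared between the parameter-recovery property and the fit-quality
# acceptance check (which uses the first three). The last two subjects use a
# smaller swarm budget so the whole suite stays within routine runtimes;
# recovery must still hold at that harder setting.
recovery_fits <- function() {
  with_cache("recovery_fits", {
    tree <- default_tree()
    plan <- data.frame(sex = c("M", "F", "M", "F", "M"),
                       seed = c(201L, 202L, 203L, 204L, 205L))
    lapply(seq_len(nrow(plan)), function(i) {
      subj <- sample_subject(plan$sex[i], seed = plan$seed[i])
      syn <- synthesize_recording(subj, tree, noise = cohort_noise(0, 0))
      cfg <- if (i <= 3) fit_config("desk") else
        fit_config("desk", n_iter = 6, refine_top = 1, refine_maxiter = 10)
      fit <- estimate_parameters(syn$record, tree, config = cfg, seed = 300 + i)
      list(subject = subj, fit = fit)
    })
  })
}
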