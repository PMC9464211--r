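# Shared, lazily computed simulation fixtures. Sessions are deterministic, so
# each scenario is simulated once per test run and reused across test files.

.scn_cache <- new.env(parent = emptyenv())

default_patient <- function() {
  if (is.null(.scn_cache$patient)) .scn_cache$patient <- virtual_patient()
  .scn_cache$patient
}

default_init <- function() {
  if (is.null(.scn_cache$init))
    .scn_cache$init <- solve_initial_steady_state(default_patient())
  .scn_cache$init
}

# one of the scenario_battery names, or the extras used only by tests
get_scenario <- function(name) {
  if (!is.null(.scn_cache[[name]])) return(.scn_cache[[name]])
  tr <- switch(name,
    flatline300 = run_session(
      default_patient(),
      session_protocol(duration_min = 300, uf_total_mL = 0, priming = "none"),
      init = default_init()),
    recovery = run_session(
      default_patient(),
      session_protocol(duration_min = 120, uf_total_mL = 0,
                       priming = "infused", dialyzer = FALSE),
      init = default_init()),
    scenario_battery(default_patient(), scenarios = name,
                     init = default_init())[[1]]
  )
  assign(name, tr, envir = .scn_cache)
  tr
}

kr_end <- function(traj) {
  k <- kr_curve(traj)
  k$Kr[nrow(k)]
}
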