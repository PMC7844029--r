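# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# 10-min virtual-track session (the workhorse for model tests)
fx_vr_session <- function() {
  if (is.null(.fx$vr))
    .fx$vr <- simulate_vr_behavior(behavior_spec("vr_track", 600, seed = 401))
  .fx$vr
}

# matching candidate design
fx_vr_design <- function() {
  if (is.null(.fx$vr_design))
    .fx$vr_design <- assemble_design(fx_vr_session(),
                                     default_variable_configs(fx_vr_session()))
  .fx$vr_design
}

# 10-min open-field session
fx_of_session <- function() {
  if (is.null(.fx$of))
    .fx$of <- simulate_open_field_behavior(
      behavior_spec("open_field", 600, seed = 402))
  .fx$of
}

# a curve object straight from values (for classifier tests)
make_curve <- function(variable, x, y) {
  lnspike:::new_tuning_curve(variable, x, y, kind = "model")
}

# Legendre polynomials: orthogonal fixtures that genuinely require their
# own degree
legendre <- list(
  function(x) x,
  function(x) (3 * x^2 - 1) / 2,
  function(x) (5 * x^3 - 3 * x) / 2,
  function(x) (35 * x^4 - 30 * x^2 + 3) / 8,
  function(x) (63 * x^5 - 70 * x^3 + 15 * x) / 8
)
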