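# shared fixtures: the packaged model is read once per test run
.model_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.model_cache$m)) .model_cache$m <- default_model()
  .model_cache$m
}

# a state with both knees deep inside the ligament dead zone (so the only
# forces during a contact-free drop are gravity), used by the passive
# energy audits; velocities kept small enough that the knees stay inside
# the dead zone over the audit window
tumble_state <- function() {
  model_state(q = c(0, 2, 0.3, 0.4, 1.0, -0.1, -0.3, 1.0, 0.1),
              qd = c(0.5, 0, 0.6, -0.6, 0.2, 0.3, 0.6, -0.2, 0.2))
}
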