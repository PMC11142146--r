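# Shared fixtures: the basic parameter set and a state constructor for
# evaluating the vector field at chosen points.

basic_params <- function(...) trt_parameters(...)

# Named state vector with selected components overridden. The first
# argument is dot-prefixed so that short component names like "p"
# cannot partially match it.
state_at <- function(.params, ...) {
  y <- trt_initial_state(.params)
  over <- list(...)
  for (nm in names(over)) y[nm] <- over[[nm]]
  y
}

# Survival fraction at the trial horizon.
final_survival <- function(trial) {
  trial$curves$surviving[nrow(trial$curves)]
}
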