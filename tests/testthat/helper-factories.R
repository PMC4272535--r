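# Shared factories for engine and checker tests.

simple_exp <- function(Avals, times = seq_along(Avals) - 1L) {
  experiment(lapply(seq_along(Avals), function(i)
    timepoint(value = times[i],
              numericStateVariables = list(
                numeric_state_variable("A", Avals[i])))))
}

state_with <- function(t, regions = list(), clusters = list(), vars = NULL) {
  list(time = t, regions = regions, clusters = clusters, vars = vars)
}

entity_with <- function(...) {
  e <- random_entity()
  over <- list(...)
  for (nm in names(over)) e[[nm]] <- over[[nm]]
  e
}

# one Bernoulli observation per trace: {A} > 1 is true/false by construction;
# the two trace objects are shared so providers are cheap to build
.obs_true_trace <- NULL
.obs_false_trace <- NULL
obs_exp <- function(x) {
  if (is.null(.obs_true_trace)) {
    .obs_true_trace <<- as_trace(simple_exp(5))
    .obs_false_trace <<- as_trace(simple_exp(0))
  }
  if (x) .obs_true_trace else .obs_false_trace
}

obs_provider <- function(xs) trace_provider_memory(lapply(xs, obs_exp))

stmt <- function(txt = "P >= 0.9 [ {A} > 1 ]") parse_pblstl(txt)[[1]]
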