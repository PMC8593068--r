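# Builders for small in-memory response-record fixtures.

mk_records <- function(trial = 1L, condition = "control",
                       arm = "black_female", estimate, recommendation,
                       round = 1L, position = NA_integer_, completed = 1L,
                       ids = NULL) {
  n <- max(length(estimate), length(recommendation))
  if (is.null(ids))
    ids <- sprintf("t%02d_%s_%s_%02d", trial,
                   substr(condition, 1, 3), substr(arm, 1, 2), seq_len(n))
  data.frame(trial_id = as.integer(trial), condition = condition, arm = arm,
             clinician_id = ids, round = as.integer(round),
             estimate = as.numeric(estimate),
             recommendation = as.character(recommendation),
             network_position = as.integer(position),
             completed = as.integer(completed), stringsAsFactors = FALSE)
}

# A round-1 network cell laid out on the nodes of `topo`, in node order.
mk_network_round1 <- function(topo, estimate, recommendation,
                              trial = 1L, arm = "black_female",
                              completed = 1L) {
  mk_records(trial = trial, condition = "network", arm = arm,
             estimate = estimate, recommendation = recommendation,
             position = seq_len(topo$n), completed = completed)
}

# Small reference-shaped generator configs for tests.
small_cfg <- function(...) {
  generator_config(n_trials = 2L, n_network = 10L, n_control = 5L, ...)
}
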