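# Small circuit builders used across tests.

self_loop_model <- function(w, theta = 0.5, k = 20, tau = 1) {
  circuit_model(W = matrix(w, 1, 1), names = "N1", tau = tau, theta = theta,
                k = k)
}

mutual_excitation_model <- function(w, theta = 0.5, k = 20) {
  W <- matrix(c(0, w, w, 0), 2, 2)
  circuit_model(W = W, names = c("A", "B"), theta = theta, k = k)
}

random_circuit <- function(n, seed, w_max = 3, gap_p = 0.3) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, -w_max, w_max), n, n)
  G <- matrix(0, n, n)
  up <- which(upper.tri(G))
  on <- up[stats::runif(length(up)) < gap_p]
  G[on] <- stats::runif(length(on), 0, 1)
  G <- G + t(G)
  circuit_model(W = W, G = G)
}

# The fixture's fixed points are reused by several files; solve once.
.fixture_cache <- new.env(parent = emptyenv())

cached_command_fps <- function() {
  if (is.null(.fixture_cache$fps)) {
    model <- command_circuit_fixture()
    .fixture_cache$model <- model
    .fixture_cache$fps <- command_state_labels(find_fixed_points(model))
  }
  list(model = .fixture_cache$model, fps = .fixture_cache$fps)
}

command_screen_conditions <- function() {
  list(
    ablation_spec(label = "normal"),
    ablation_spec(remove_neurons = c("AVAL", "AVAR"), label = "AVA ablation"),
    ablation_spec(remove_neurons = c("AVBL", "AVBR"), label = "AVB ablation"),
    ablation_spec(remove_neurons = c("AVDL", "AVDR"), label = "AVD ablation"),
    ablation_spec(remove_neurons = c("AVEL", "AVER"), label = "AVE ablation"),
    ablation_spec(remove_neurons = c("PVCL", "PVCR"), label = "PVC ablation"),
    ablation_spec(remove_gap_all = TRUE, label = "gap removed"),
    ablation_spec(remove_gap_pairs = list(c("AVAL", "PVCL"),
                                          c("AVAR", "PVCR")),
                  label = "gap AVA to PVC removed")
  )
}

cached_command_screen <- function() {
  if (is.null(.fixture_cache$screen)) {
    .fixture_cache$screen <- ablation_screen(command_circuit_fixture(),
                                             command_screen_conditions(),
                                             n_starts = 300)
  }
  .fixture_cache$screen
}

stable_by_label <- function(fps) {
  states <- stable_points(fps)$points
  lab <- attr(fps, "state_labels")
  if (is.null(lab)) lab <- paste0("S", seq_along(states))
  names(states) <- lab
  states
}
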