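#' Initialize association-fiber weights
#'
#' Draws the raw pyramidal-to-pyramidal synaptic weights uniformly on
#' `[0, w_init_max]` (default 0.04, roughly a tenth of the typical
#' post-training maximum) on the active synapses of the adjacency;
#' off-adjacency entries are exactly zero and stay zero forever.
#'
#' @param adjacency logical/0-1 matrix (presynaptic rows x postsynaptic
#'   columns) of the association-fiber pathway.
#' @param seed integer seed; initialization is deterministic given it.
#' @param w_init_max upper bound of the uniform draw.
#' @return A numeric weight matrix of the same dimension.
#' @export
init_weights <- function(adjacency, seed, w_init_max = 0.04) {
  adjacency <- as.matrix(adjacency)
  w <- matrix(0, nrow(adjacency), ncol(adjacency))
  active <- which(adjacency != 0)
  w[active] <- with_seed(seed, stats::runif(length(active), 0, w_init_max))
  w
}

#' Postsynaptic depolarization trace
#'
#' Alpha-function time course of the postsynaptic depolarization after a
#' spike: `(t/tau_post) * exp(1 - t/tau_post)`; zero at `t = 0`, unit peak
#' exactly at `t = tau_post` (2 ms by default).  Negative times (no spike
#' yet) give 0.
#'
#' @param t_since_post_spike time since the postsynaptic spike (ms),
#'   vectorized.
#' @param tau_post characteristic depolarization time (ms).
#' @return Trace values in \[0, 1\].
#' @export
post_trace <- function(t_since_post_spike, tau_post = 2) {
  t <- pmax(t_since_post_spike, 0)
  out <- (t / tau_post) * exp(1 - t / tau_post)
  out[t_since_post_spike < 0] <- 0
  out
}

#' NMDA glutamate-binding trace
#'
#' Time course of glutamate binding on NMDA receptors after the
#' presynaptic spike reaches the recurrent synapse.  The default
#' `"rise_fall"` form is `exp(-t/tau_f) * (1 - exp(-t/tau_r))`, rescaled
#' to unit peak, which is zero at `t = 0`, peaks at
#' `t* = tau_r * log((tau_f + tau_r)/tau_r)` and decays with the NMDA fall
#' constant.  `form = "printed"` evaluates the literal product
#' `exp(-t/tau_f) * exp(1 - t/tau_r)`, which is monotone-decreasing and is
#' retained only for comparison (it contradicts a rise time).
#'
#' @param t_since_pre_arrival time since presynaptic arrival (ms),
#'   vectorized; negative values give 0.
#' @param tau_f NMDA fall constant (ms, default 7).
#' @param tau_r NMDA rise constant (ms, default 1).
#' @param form `"rise_fall"` (default) or `"printed"`.
#' @return Trace values (unit peak for `"rise_fall"`).
#' @export
glu_trace <- function(t_since_pre_arrival, tau_f = 7, tau_r = 1,
                      form = c("rise_fall", "printed")) {
  form <- match.arg(form)
  t <- pmax(t_since_pre_arrival, 0)
  if (form == "printed") {
    out <- exp(-t / tau_f) * exp(1 - t / tau_r)
  } else {
    t_peak <- tau_r * log((tau_f + tau_r) / tau_r)
    peak <- exp(-t_peak / tau_f) * (1 - exp(-t_peak / tau_r))
    out <- exp(-t / tau_f) * (1 - exp(-t / tau_r)) / peak
  }
  out[t_since_pre_arrival < 0] <- 0
  out
}

#' One Euler step of the Hebbian coincidence rule
#'
#' Bounded, increase-only weight update on the association fibers: for each
#' active synapse (presynaptic i, postsynaptic j),
#' `w <- w + dt * (1 - w) * glu_trace_i * post_trace_j / tau_pp`.
#' Weights are driven toward 1 with characteristic time `tau_pp` (800 ms)
#' under sustained coincidence; they never decrease and never exceed 1.
#'
#' @param w raw weight matrix (pre x post).
#' @param adjacency 0/1 matrix of active synapses.
#' @param glu_traces per-presynaptic-neuron glutamate traces (length nrow).
#' @param post_traces per-postsynaptic-neuron depolarization traces
#'   (length ncol).
#' @param dt integration step (ms).
#' @param tau_pp weight time constant (ms, default 800).
#' @return Updated weight matrix.
#' @export
hebbian_step <- function(w, adjacency, glu_traces, post_traces, dt,
                         tau_pp = 800) {
  stopifnot(length(glu_traces) == nrow(w), length(post_traces) == ncol(w))
  dw <- (dt / tau_pp) * (1 - w) * outer(glu_traces, post_traces)
  w + dw * (adjacency != 0)
}

#' Globally normalize association-fiber weights
#'
#' Rescales the raw weights so that the sum over all active synapses equals
#' 1: `w_normalized = w / sum(w[active])`.  The raw weights are what
#' learning updates; the normalized copy is what enters the conductance
#' computation.  Normalization concentrates synaptic efficacy on the
#' synapses that grew fastest during training.
#'
#' @param w raw weight matrix.
#' @param adjacency 0/1 matrix of active synapses.
#' @return The normalized weight matrix (sums to 1 over active synapses).
#' @export
normalize_weights <- function(w, adjacency = w != 0) {
  s <- sum(w[adjacency != 0])
  if (!is.finite(s) || s <= 0) {
    stop("cannot normalize: total active weight is ", s)
  }
  wn <- w / s
  wn[adjacency == 0] <- 0
  wn
}

#' Persist trained association-fiber weights as text
#'
#' Writes the raw weight matrix as CSV plus a JSON sidecar recording seed,
#' training metadata and the active-synapse count, so recall runs can
#' reload trained networks reproducibly.
#'
#' @param w raw weight matrix.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param meta named list of metadata (seed, odor seed, NE levels,
#'   sessions, ...).
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, meta = list()) {
  utils::write.table(w, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta$n_active <- sum(w != 0)
  meta$dim <- dim(w)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reload persisted weights
#'
#' @param path CSV path written by [write_weights()].
#' @return List with the weight `matrix` and the sidecar `meta`.
#' @export
read_weights <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(w) <- NULL
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list()
  list(matrix = w, meta = meta)
}
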