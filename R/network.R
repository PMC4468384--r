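# sample a 0/1 adjacency (pre x post) with a fixed fan-in per postsynaptic
# neuron
sample_fan_in <- function(n_pre, n_post, frac) {
  if (frac <= 0 || frac > 1) stop("connectivity fraction must be in (0, 1]")
  k <- max(1L, round(frac * n_pre))
  adj <- matrix(0, n_pre, n_post)
  for (j in seq_len(n_post)) adj[sample.int(n_pre, k), j] <- 1
  adj
}

# fixed fan-out per presynaptic neuron, optionally excluding self-loops
sample_fan_out <- function(n_pre, n_post, frac, no_self = FALSE) {
  if (frac <= 0 || frac > 1) stop("connectivity fraction must be in (0, 1]")
  k <- max(1L, round(frac * n_post))
  adj <- matrix(0, n_pre, n_post)
  for (i in seq_len(n_pre)) {
    cand <- if (no_self) setdiff(seq_len(n_post), i) else seq_len(n_post)
    adj[i, sample(cand, k)] <- 1
  }
  adj
}

#' Build the olfactory bulb + piriform cortex network
#'
#' Instantiates all populations and synaptic pathways of the reduced
#' circuit: per glomerulus, OSN i drives PG i and mitral cell i's apical
#' dendrite, PG i inhibits only that apical dendrite; each mitral cell
#' contacts a random 40% of granule cells with strictly reciprocal
#' dendrodendritic synapses (the granule-to-mitral adjacency is the
#' transpose of mitral-to-granule); each pyramidal cell receives from 20%
#' of mitral cells and 30% of feedforward interneurons, each feedforward
#' interneuron from 40% of mitral cells; pyramidal cells send association
#' fibers to 20% of other pyramidal cells (no self-connections) and
#' interconnect with feedback interneurons at the configured fractions.
#' Fixed pathways have unit weights; association-fiber weights are drawn by
#' [init_weights()] and globally normalized.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; construction is fully deterministic given it.
#' @return An object of class `obpc_network`.
#' @examples
#' net <- build_network(network_config(), seed = 1)
#' colSums(net$adjacency$mi_pyr)[1:5] # fan-in 20 per pyramidal cell
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  n <- cfg$n_per_type
  cc <- cfg$connectivity
  adj <- with_seed(seed, {
    mi_gr <- sample_fan_out(n, n, cc$mi_gr_frac)
    list(
      mi_gr = mi_gr,
      gr_mi = t(mi_gr), # reciprocal dendrodendritic pairs
      mi_pyr = sample_fan_in(n, n, cc$mi_pyr_frac),
      mi_ff = sample_fan_in(n, n, cc$mi_ff_frac),
      ff_pyr = sample_fan_in(n, n, cc$ff_pyr_frac),
      pyr_pyr = sample_fan_out(n, n, cc$pyr_pyr_frac, no_self = TRUE),
      pyr_fb = sample_fan_in(n, n, cc$pyr_fb_frac),
      fb_pyr = sample_fan_in(n, n, cc$fb_pyr_frac)
    )
  })
  w_raw <- init_weights(adj$pyr_pyr, seed = derive_seed(seed, 104729),
                        w_init_max = cfg$plasticity$w_init_max)
  structure(list(cfg = cfg, seed = as.integer(seed), adjacency = adj,
                 w_raw = w_raw,
                 w_norm = normalize_weights(w_raw, adj$pyr_pyr),
                 trained = NULL),
            class = "obpc_network")
}

#' @export
print.obpc_network <- function(x, ...) {
  cat("<obpc_network> n per type =", x$cfg$n_per_type,
      " seed =", x$seed, "\n")
  cat("  association fibers:", sum(x$adjacency$pyr_pyr), "synapses,",
      if (is.null(x$trained)) "naive" else
        paste0("trained (", x$trained$sessions, " sessions)"), "\n")
  invisible(x)
}

# assemble the (possibly NE-modulated) parameter payload for the engine
engine_inputs <- function(network, ne) {
  cfg <- network$cfg
  mod <- modulate(cfg, ne)
  pops <- lapply(cfg$populations, unclass)
  pops$mi$theta_max <- mod$mi_theta_max
  pops$gr$theta_min <- mod$gr_theta_min
  pops$fb$theta_min <- mod$fb_theta_min
  pops$pyr$a_ahc <- mod$pyr_a_ahc
  paths <- lapply(cfg$pathways, unclass)
  paths$pyr_fb$g_max <- mod$pyr_fb_gmax
  paths$pyr_pyr$g_max <- mod$pyr_pyr_gmax
  mats <- list(grmi = t(network$adjacency$gr_mi),
               migr = t(network$adjacency$mi_gr),
               miff = t(network$adjacency$mi_ff),
               mipyr = t(network$adjacency$mi_pyr),
               ffpyr = t(network$adjacency$ff_pyr),
               fbpyr = t(network$adjacency$fb_pyr),
               pyrfb = t(network$adjacency$pyr_fb),
               pp = t(network$w_norm))
  list(pops = pops, paths = paths, mats = mats)
}

#' Run one network simulation
#'
#' Advances the whole circuit with the Euler scheme (default 0.5 ms step)
#' for `duration_ms`, with or without an odor, under a given
#' norepinephrine state.  Firing rates are averaged over the analysis
#' window starting after `settle_ms` (activity stabilizes within
#' 100-200 ms); graded populations report their mean transfer output over
#' the same window.  All randomness (spike draws) comes from the supplied
#' seed, so identical calls are bit-identical.
#'
#' @param network an [build_network()] object.
#' @param odor an [generate_odor()] stimulus, or `NULL` for spontaneous
#'   activity.
#' @param ne an [ne_state()].
#' @param duration_ms simulated time (ms); must be a multiple of `dt`.
#' @param seed integer seed for the spike draws.
#' @param settle_ms settling time excluded from the analysis window.
#' @param record_raster keep the full spike raster (time, neuron) per
#'   population?
#' @param learn apply the Hebbian rule to the association fibers during
#'   this run?  (Used by [train_network()]; recall runs keep it off.)
#' @return An object of class `obpc_sim` with per-population `rates`
#'   (Hz for spiking populations, mean output in \[0,1\] for graded ones),
#'   spike `counts`, the analysis `window_ms`, optional `raster`, and the
#'   updated raw weights if `learn = TRUE`.
#' @export
run_simulation <- function(network, odor = NULL, ne = ne_state(),
                           duration_ms = 1200, seed = 1, settle_ms = 200,
                           record_raster = FALSE, learn = FALSE) {
  stopifnot(inherits(network, "obpc_network"))
  cfg <- network$cfg
  dt <- cfg$dt
  if (abs(duration_ms / dt - round(duration_ms / dt)) > 1e-9) {
    stop("duration_ms must be a multiple of dt = ", dt)
  }
  n_steps <- as.integer(round(duration_ms / dt))
  win_start <- as.integer(round(settle_ms / dt))
  if (win_start >= n_steps) stop("settle_ms leaves an empty analysis window")
  inp <- engine_inputs(network, ne)
  plast <- c(cfg$plasticity,
             list(w_raw = network$w_raw, adjacency = network$adjacency$pyr_pyr))
  res <- with_seed(seed,
    sim_engine_cpp(inp$pops, inp$paths, inp$mats,
                   osn_drive(odor, cfg), n_steps, dt,
                   win_start, n_steps, learn, plast, record_raster,
                   dt / cfg$dynamics$spike_rate_unit_ms,
                   cfg$dynamics$membrane_noise_sd_mv))
  window_s <- (n_steps - win_start) * dt / 1000
  rates <- lapply(res$counts, function(x) as.numeric(x) / window_s)
  rates$osn <- as.numeric(res$graded_mean$osn)
  rates$pg <- as.numeric(res$graded_mean$pg)
  out <- structure(
    list(rates = rates, counts = lapply(res$counts, as.integer),
         window_ms = c(settle_ms, duration_ms), duration_ms = duration_ms,
         dt = dt, seed = as.integer(seed), ne = ne,
         odor_seed = if (is.null(odor)) NA_integer_ else odor$seed,
         concentration = if (is.null(odor)) 0 else odor$concentration),
    class = "obpc_sim")
  if (record_raster) {
    out$raster <- lapply(res$raster, function(df) {
      data.frame(time_ms = df$step * dt, neuron = df$neuron)
    })
  }
  if (learn) out$w_raw <- res$w_raw
  out
}

#' @export
print.obpc_sim <- function(x, ...) {
  cat("<obpc_sim>", x$duration_ms, "ms, window",
      paste(x$window_ms, collapse = "-"), "ms, odor conc",
      x$concentration, "\n")
  mr <- vapply(x$rates[c("mi", "gr", "ff", "pyr", "fb")], mean, numeric(1))
  cat("  mean rates (Hz): ",
      paste(sprintf("%s=%.1f", names(mr), mr), collapse = "  "), "\n")
  invisible(x)
}

#' Train the cortical network on an odorant
#'
#' Runs consecutive training sessions (default 4 x 5 s) with the odor
#' present and the Hebbian rule active on the association fibers, under
#' the given norepinephrine state.  After each session the raw weights are
#' globally renormalized (sum over active synapses = 1); the normalized
#' copy drives the recurrent conductance in subsequent sessions and during
#' recall.  Raw weights only ever increase.
#'
#' @param network an [build_network()] object.
#' @param odor the training [generate_odor()] stimulus.
#' @param ne the [ne_state()] during training.
#' @param sessions number of training sessions.
#' @param session_ms session length (ms).
#' @param seed integer seed.
#' @return The network with updated `w_raw`, `w_norm` and a `trained`
#'   metadata record.
#' @export
train_network <- function(network, odor, ne = ne_state(), sessions = 4,
                          session_ms = 5000, seed = 1) {
  stopifnot(inherits(network, "obpc_network"), sessions >= 1)
  for (s in seq_len(sessions)) {
    sim <- run_simulation(network, odor = odor, ne = ne,
                          duration_ms = session_ms, settle_ms = 0,
                          seed = derive_seed(seed, 7001, s), learn = TRUE)
    network$w_raw <- sim$w_raw
    network$w_norm <- normalize_weights(network$w_raw,
                                        network$adjacency$pyr_pyr)
  }
  network$trained <- list(odor_seed = odor$seed,
                          concentration = odor$concentration,
                          ne_ob_um = ne$ob_um, ne_pc_um = ne$pc_um,
                          sessions = sessions, session_ms = session_ms,
                          seed = as.integer(seed))
  network
}

#' Export a spike raster as three-column text
#'
#' @param sim an [run_simulation()] result with `record_raster = TRUE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(sim, path) {
  if (is.null(sim$raster)) stop("simulation was run without record_raster")
  rows <- do.call(rbind, lapply(names(sim$raster), function(p) {
    r <- sim$raster[[p]]
    if (nrow(r) == 0) return(NULL)
    data.frame(time_ms = r$time_ms, population = p, neuron_id = r$neuron)
  }))
  if (is.null(rows)) {
    rows <- data.frame(time_ms = numeric(0), population = character(0),
                       neuron_id = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export per-neuron rates as CSV
#'
#' @param sim an [run_simulation()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rates <- function(sim, path) {
  rows <- do.call(rbind, lapply(names(sim$rates), function(p) {
    data.frame(population = p, neuron_id = seq_along(sim$rates[[p]]),
               rate_hz = sim$rates[[p]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
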