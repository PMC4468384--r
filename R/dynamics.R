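#' Single Euler step of the leaky-integrator membrane equation
#'
#' Advances the first-order membrane equation
#' \eqn{\tau \, dv/dt + v = V^{ext}} by one forward-Euler step:
#' `v + (dt/tau) * (v_ext - v)`.
#'
#' @param v membrane voltage vector (mV).
#' @param v_ext total synaptic/external drive (mV), scalar or same length.
#' @param tau membrane time constant (ms).
#' @param dt integration step (ms); must satisfy `0 < dt < tau`.
#' @return Updated voltage vector (mV).
#' @examples
#' euler_membrane_step(0, 1, tau = 5, dt = 0.5) # 0.1
#' @export
euler_membrane_step <- function(v, v_ext, tau, dt) {
  stopifnot(dt > 0, dt < tau)
  if (!all(is.finite(v)) || !all(is.finite(v_ext))) {
    stop("non-finite membrane input: max|v| = ", max(abs(v)),
         ", max|v_ext| = ", max(abs(v_ext)))
  }
  v + (dt / tau) * (v_ext - v)
}

#' Output nonlinearity (graded output / spiking probability)
#'
#' Piecewise power-law transfer function mapping membrane voltage to a value
#' in \[0, 1\]: 0 at or below `theta_min`, 1 at or above `theta_max`, and
#' `((v - theta_min)/(theta_max - theta_min))^beta` in between.  For graded
#' populations this is the cell's output; for spiking populations it is the
#' per-timestep firing probability.
#'
#' @param v voltage (mV), vectorized.
#' @param p a [cell_params()] object (or any list with `beta`, `theta_min`,
#'   `theta_max`).
#' @return Activation values in \[0, 1\].
#' @examples
#' gr <- cell_params(tau = 5, beta = 2, theta_min = -1, theta_max = 6)
#' transfer(c(-1, 2.5, 6), gr)
#' @export
transfer <- function(v, p) {
  x <- (v - p$theta_min) / (p$theta_max - p$theta_min)
  out <- pmin(pmax(x, 0), 1)^p$beta
  out[v >= p$theta_max] <- 1
  out
}

#' Difference-of-exponentials conductance kernel
#'
#' Conductance time course after a presynaptic spike:
#' `g_max * (exp(-t/tau2) - exp(-t/tau1))` with `tau1` the rise and `tau2`
#' the fall constant.  The orientation is chosen so that with
#' `tau1 < tau2` the kernel is non-negative, zero at `t = 0`, rises to a
#' single peak at `t* = log(tau2/tau1) / (1/tau1 - 1/tau2)` and decays
#' back to zero.
#'
#' @param t_since_spike time since the presynaptic spike (ms), >= 0,
#'   vectorized.
#' @param k a [synapse_kernel()] object.
#' @return Conductance values (dimensionless), >= 0.
#' @examples
#' k <- synapse_kernel(1, 70, tau1 = 1, tau2 = 2)
#' conductance_kernel(2 * log(2), k) # the peak, 0.25
#' @export
conductance_kernel <- function(t_since_spike, k) {
  if (any(t_since_spike < 0)) stop("t_since_spike must be >= 0")
  k$g_max * (exp(-t_since_spike / k$tau2) - exp(-t_since_spike / k$tau1))
}

#' Synaptic drive from one connection
#'
#' The voltage drive contributed by one synapse,
#' `w * g * (e_nernst - v_post)`; the caller sums over presynaptic sources.
#'
#' @param w synaptic weight, >= 0.
#' @param g instantaneous conductance, >= 0.
#' @param e_nernst reversal potential of the channel (mV).
#' @param v_post postsynaptic membrane voltage (mV).
#' @return Drive (mV).
#' @export
synaptic_drive <- function(w, g, e_nernst, v_post) {
  stopifnot(all(w >= 0), all(g >= 0))
  w * g * (e_nernst - v_post)
}

#' Neuron state container
#'
#' @param n number of neurons.
#' @param v initial voltages (recycled).
#' @return A `neuron_state` list with voltages `v`, adaptation variable
#'   `v_ahc`, last-spike times `t_last_spike` (`-Inf` = never) and the most
#'   recent output value per neuron.
#' @export
neuron_state <- function(n, v = 0) {
  structure(list(v = rep_len(v, n), v_ahc = numeric(n),
                 t_last_spike = rep(-Inf, n), output = numeric(n)),
            class = "neuron_state")
}

#' Stochastic spike emission with reset and refractoriness
#'
#' For each non-refractory neuron draws a Bernoulli spike with per-timestep
#' probability `transfer(v)`; spiking neurons are reset to `v_hyper` and
#' locked out for the refractory period.  Randomness must be supplied
#' explicitly: `rng` is a function of one argument returning that many
#' uniform(0,1) draws (e.g. `runif` under a caller-controlled seed).
#'
#' @param state a [neuron_state()].
#' @param p a [cell_params()] with `is_spiking = TRUE`.
#' @param t current simulation time (ms).
#' @param rng function `n -> n` uniform draws; required.
#' @return The updated state, with an added logical attribute-free element
#'   `spiked` indicating the emitted spikes.
#' @export
spike_and_reset <- function(state, p, t, rng) {
  if (!p$is_spiking) stop("spike_and_reset called on a graded population")
  if (missing(rng) || !is.function(rng)) {
    stop("an explicit rng function is required (no hidden global randomness)")
  }
  prob <- transfer(state$v, p)
  refractory <- (t - state$t_last_spike) < p$t_refrac
  u <- rng(length(state$v))
  spiked <- !refractory & (u < prob)
  state$v[spiked] <- p$v_hyper
  state$t_last_spike[spiked] <- t
  state$output <- as.numeric(spiked)
  state$spiked <- spiked
  state
}

#' Afterhyperpolarization (adaptation) update
#'
#' The adaptation variable relaxes toward `a_ahc * X` with time constant
#' `tau_ahc`, where `X` is 1 in the timestep after a spike and 0 otherwise:
#' one Euler step of \eqn{\tau^{ahc} \, dv^{ahc}/dt + v^{ahc} = A^{ahc} X}.
#' The adaptation variable is itself the conductance of the
#' afterhyperpolarization current: the returned drive is
#' `v_ahc * (e_ahc - v)`, zero when `v_ahc = 0` and maximal right after a
#' spike.  The amplitude `a_ahc` scales the conductance directly, so the
#' drive vanishes continuously as `a_ahc -> 0` (full NE modulation).
#'
#' @param v_ahc adaptation variable (conductance) vector.
#' @param spiked logical vector: did each neuron spike in the previous step.
#' @param p a [cell_params()] carrying `a_ahc`, `tau_ahc`, `e_ahc`.
#' @param dt integration step (ms).
#' @param v current membrane voltages (mV), for the driving force.
#' @return `list(v_ahc = updated variable, drive = hyperpolarizing mV)`.
#' @export
ahp_step <- function(v_ahc, spiked, p, dt, v = 0) {
  stopifnot(p$a_ahc >= 0)
  x <- as.numeric(spiked)
  v_ahc <- v_ahc + (dt / p$tau_ahc) * (p$a_ahc * x - v_ahc)
  list(v_ahc = v_ahc, drive = v_ahc * (p$e_ahc - v))
}

#' Electrical coupling between mitral compartments
#'
#' The apical-minus-soma voltage difference, fed as an additive drive into
#' the soma compartment's membrane equation.
#'
#' @param v_apical apical-compartment voltages (mV).
#' @param v_soma soma-compartment voltages (mV).
#' @return Coupling drive vector (mV).
#' @export
couple_mitral_compartments <- function(v_apical, v_soma) {
  if (length(v_apical) != length(v_soma)) {
    stop("compartment vectors differ in length: ", length(v_apical),
         " vs ", length(v_soma))
  }
  v_apical - v_soma
}
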