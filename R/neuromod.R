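#' Receptor occupancy as a function of norepinephrine concentration
#'
#' Hyperbolic (Hill coefficient 1) dose-response: `1 / (1 + y_half / c)`,
#' i.e. occupancy 0 at `c = 0`, 0.5 at `c = y_half`, saturating at 1.
#'
#' @param c NE concentration (uM), >= 0, vectorized.
#' @param y_half concentration at half-maximal modulation (uM), > 0.
#' @return Occupancy fraction in \[0, 1\].
#' @examples
#' occupancy(c(0, 10, 90), y_half = 10)
#' @export
occupancy <- function(c, y_half) {
  stopifnot(all(c >= 0), y_half > 0)
  ifelse(c > 0, 1 / (1 + y_half / c), 0)
}

#' Norepinephrine state for the two structures
#'
#' Scalar NE concentration and an on/off switch per locus (olfactory bulb
#' and piriform cortex).  A disabled locus behaves exactly as the
#' unmodulated model regardless of concentration.
#'
#' @param ob_um NE concentration in the olfactory bulb (uM).
#' @param pc_um NE concentration in the piriform cortex (uM).
#' @param enabled_ob,enabled_pc logical switches per locus.
#' @return An object of class `ne_state`.
#' @examples
#' ne_state(ob_um = 1, pc_um = 1)                  # medium NE, both loci
#' ne_state(ob_um = 1e6, pc_um = 0, enabled_pc = FALSE) # bulb only
#' @export
ne_state <- function(ob_um = 0, pc_um = ob_um,
                     enabled_ob = TRUE, enabled_pc = TRUE) {
  stopifnot(ob_um >= 0, pc_um >= 0)
  structure(list(ob_um = ob_um, pc_um = pc_um,
                 enabled_ob = isTRUE(enabled_ob),
                 enabled_pc = isTRUE(enabled_pc)),
            class = "ne_state")
}

# linear blend between the without-NE and with-NE endpoints at a given
# occupancy
blend <- function(entry, occ) entry$off + occ * (entry$on - entry$off)

#' Effective granule-cell firing threshold under NE
#'
#' Combines the opposing alpha1 and alpha2 adrenergic components
#' additively: `theta_min = base + O_a2 * delta_a2 + O_a1 * delta_a1` with
#' the alpha2 curve the higher-affinity one.  Because alpha2 saturates
#' first, the threshold first rises (granule cells quieter, mitral cells
#' disinhibited) and then falls below baseline as alpha1 engages at high
#' NE, producing the characteristic non-monotonic dose-response.
#'
#' @param ne_ob_um NE concentration in the bulb (uM), vectorized.
#' @param cfg a [network_config()] (for the endpoint pairs and half-max
#'   constants).
#' @return Effective `theta_min` (mV).
#' @export
granule_threshold <- function(ne_ob_um, cfg = network_config()) {
  m <- cfg$modulation
  y <- cfg$receptor_y_half
  base <- m$gr_theta_min_a1$off
  d_a1 <- m$gr_theta_min_a1$on - m$gr_theta_min_a1$off
  d_a2 <- m$gr_theta_min_a2$on - m$gr_theta_min_a2$off
  base +
    occupancy(ne_ob_um, y$alpha1_gr) * d_a1 +
    occupancy(ne_ob_um, y$alpha2_gr) * d_a2
}

#' Apply norepinephrine modulation to the model parameters
#'
#' Maps an [ne_state()] through the receptor dose-response curves onto every
#' modulated parameter: each target is set to
#' `off + occupancy * (on - off)`, with bulb targets driven by the OB
#' concentration and cortical targets by the PC concentration.  A disabled
#' locus reproduces the unmodulated (`off`) values exactly.
#'
#' @param cfg a [network_config()].
#' @param ne an [ne_state()].
#' @return A named list of effective parameters:
#'   `mi_theta_max`, `gr_theta_min`, `fb_theta_min`, `pyr_fb_gmax`,
#'   `pyr_pyr_gmax`, `pyr_a_ahc`.
#' @export
modulate <- function(cfg, ne = ne_state()) {
  stopifnot(inherits(cfg, "network_config"), inherits(ne, "ne_state"))
  m <- cfg$modulation
  y <- cfg$receptor_y_half
  occ <- function(entry) {
    conc <- if (entry$locus == "ob") ne$ob_um else ne$pc_um
    on <- if (entry$locus == "ob") ne$enabled_ob else ne$enabled_pc
    if (!on) return(0)
    yh <- y[[entry$curve]]
    if (is.null(yh)) stop("unregistered receptor curve: ", entry$curve)
    occupancy(conc, yh)
  }
  gr_theta_min <- m$gr_theta_min_a1$off +
    occ(m$gr_theta_min_a1) * (m$gr_theta_min_a1$on - m$gr_theta_min_a1$off) +
    occ(m$gr_theta_min_a2) * (m$gr_theta_min_a2$on - m$gr_theta_min_a2$off)
  list(
    mi_theta_max = blend(m$mi_theta_max, occ(m$mi_theta_max)),
    gr_theta_min = gr_theta_min,
    fb_theta_min = blend(m$fb_theta_min, occ(m$fb_theta_min)),
    pyr_fb_gmax  = blend(m$pyr_fb_gmax, occ(m$pyr_fb_gmax)),
    pyr_pyr_gmax = blend(m$pyr_pyr_gmax, occ(m$pyr_pyr_gmax)),
    pyr_a_ahc    = blend(m$pyr_a_ahc, occ(m$pyr_a_ahc))
  )
}
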