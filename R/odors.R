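# -- seeding helpers ---------------------------------------------------------

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed plus one or more integer coordinates
#' (grid indices, repeat number, condition codes...) to a sub-seed in
#' \[1, 2^31 - 2\], so that every simulation in an experiment campaign has
#' its own independent, reproducible stream.
#'
#' @param master master seed (integer).
#' @param ... integer coordinates.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ks <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (k in ks) h <- (h * 69069 + k * 2654435761 + 1013904223) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# -- odorants ----------------------------------------------------------------

#' Generate a synthetic odorant
#'
#' An odorant is a random permutation of a fixed array of receptor-affinity
#' values: the Gaussian density `N(x; mu, sigma)` evaluated at
#' `x = 1..n` (defaults `mu = 50`, `sigma = 10`, `n = 100`).  Every odorant
#' therefore carries the same multiset of affinities and elicits the same
#' average sensory response at a given concentration; odorants differ only
#' in which receptor channels carry the strong affinities.
#'
#' @param seed integer seed; the odor is deterministic given the seed.
#' @param concentration scalar concentration in \[0, 1\] (1 = the OSN
#'   saturation point).
#' @param cfg a [network_config()] supplying `n`, `mu`, `sigma`.
#' @return An object of class `odor_stimulus`: list with `affinities`,
#'   `concentration` and `seed`.
#' @examples
#' o <- generate_odor(seed = 1, concentration = 0.5)
#' sum(o$affinities) # identical for every seed
#' @export
generate_odor <- function(seed, concentration = 1, cfg = network_config()) {
  stopifnot(concentration >= 0, concentration <= 1)
  od <- cfg$odor
  base <- stats::dnorm(seq_len(od$n), mean = od$mu, sd = od$sigma)
  aff <- with_seed(seed, sample(base))
  structure(list(affinities = aff, concentration = concentration,
                 seed = as.integer(seed)),
            class = "odor_stimulus")
}

#' Sensory-neuron drive evoked by an odorant
#'
#' Converts an odorant to the external voltage drive on each OSN:
#' `osn_baseline_mv + concentration * (affinity / max(affinity)) *
#' osn_gain * theta_max_osn`, where the small tonic baseline emulates
#' spontaneous sensory-neuron activity (present also without an odor).
#' Concentration 1 is the saturation point for OSN activation: with the
#' default gain of 4 the best-matched receptor channel saturates at a
#' quarter of maximal concentration, and at maximal concentration every
#' channel within about 1.7 affinity standard deviations of the best match
#' is at saturation (the transfer function caps the output at 1, so
#' super-saturating drive is harmless).  The gain is a calibration
#' constant anchored to the learning protocol (maximum trained
#' association-fiber weight about ten times the initialization cap); see
#' the methods vignette, including why a unit gain would leave low
#' concentrations invisible to the circuit.
#'
#' @param odor an [generate_odor()] stimulus (or `NULL` for no odor).
#' @param cfg a [network_config()].
#' @return Numeric drive vector (mV), one entry per OSN.
#' @export
osn_drive <- function(odor, cfg = network_config()) {
  base <- rep(cfg$odor$osn_baseline_mv, cfg$n_per_type)
  if (is.null(odor)) return(base)
  stopifnot(inherits(odor, "odor_stimulus"))
  if (odor$concentration < 0 || odor$concentration > 1) {
    stop("odor concentration must lie in [0, 1], got ", odor$concentration)
  }
  base + odor$concentration * odor$affinities / max(odor$affinities) *
    cfg$odor$osn_gain * cfg$odor$theta_max_osn
}

# cache for the Monte-Carlo inter-odor distance normalization constant
.obpc_cache <- new.env(parent = emptyenv())

#' Expected sensory-level distance between two independent odorants
#'
#' Monte-Carlo estimate (fixed internal seed, cached) of the mean Euclidean
#' distance between the affinity vectors of two independently drawn
#' odorants.  Used as the normalization constant that puts odor distances
#' on the \[0, 1\] scale where 1 means "as far apart as two unrelated
#' odors".
#'
#' @param cfg a [network_config()].
#' @param n_pairs Monte-Carlo sample size.
#' @return A single positive number.
#' @export
interodor_distance_constant <- function(cfg = network_config(),
                                        n_pairs = 200) {
  key <- paste(cfg$odor$n, cfg$odor$mu, cfg$odor$sigma, n_pairs, sep = "_")
  hit <- .obpc_cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- stats::dnorm(seq_len(cfg$odor$n), cfg$odor$mu, cfg$odor$sigma)
  d <- with_seed(791003, vapply(seq_len(n_pairs), function(i) {
    sqrt(sum((sample(base) - sample(base))^2))
  }, numeric(1)))
  val <- mean(d)
  .obpc_cache[[key]] <- val
  val
}

#' Euclidean distance between two pattern vectors
#'
#' Plain L2 distance, optionally normalized by the expected distance
#' between two independent odorants (see
#' [interodor_distance_constant()]) so that 1 corresponds to unrelated
#' patterns.
#'
#' @param a,b numeric vectors of equal length.
#' @param normalized logical; divide by the inter-odor constant?
#' @param cfg a [network_config()] (only used when `normalized = TRUE`).
#' @return A single non-negative number.
#' @export
euclidean_distance <- function(a, b, normalized = FALSE,
                               cfg = network_config()) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  d <- sqrt(sum((a - b)^2))
  if (normalized) d <- d / interodor_distance_constant(cfg)
  d
}

#' Perturb an odorant to a target distance from the original
#'
#' Produces a noisy version of a learned odorant whose sensory (affinity)
#' representation lies at a requested normalized Euclidean distance from
#' the original, within a +/- 2% tolerance.  Mechanism: re-permute a random
#' subset of affinity positions to obtain a far point, then blend linearly
#' between the original and the far point; because the distance is linear
#' in the blend coefficient, the target is hit essentially exactly.
#' The perturbed affinities remain non-negative and the concentration is
#' preserved.
#'
#' @param odor the original [generate_odor()] stimulus.
#' @param target_distance requested normalized distance in \[0, 1\].
#' @param seed integer seed for the re-permutation.
#' @param cfg a [network_config()].
#' @param tol relative tolerance on the achieved distance (default 0.02).
#' @param max_tries bounded search for a sufficiently distant far point.
#' @return A perturbed `odor_stimulus`.
#' @export
perturb_odor <- function(odor, target_distance, seed,
                         cfg = network_config(), tol = 0.02,
                         max_tries = 100) {
  stopifnot(inherits(odor, "odor_stimulus"))
  if (target_distance < 0 || target_distance > 1) {
    stop("target_distance must lie in [0, 1], got ", target_distance)
  }
  if (target_distance == 0) return(odor)
  norm_const <- interodor_distance_constant(cfg)
  a <- odor$affinities
  n <- length(a)
  far <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      # grow the re-permuted subset until the far point is distant enough
      k <- min(n, ceiling(n * min(1, target_distance + 0.2 * try)))
      idx <- sample(n, k)
      cand <- a
      cand[idx] <- cand[sample(idx)]
      if (euclidean_distance(cand, a, normalized = TRUE, cfg = cfg) >=
            target_distance) {
        found <- cand
        break
      }
    }
    found
  })
  if (is.null(far)) {
    stop("could not reach normalized distance ", target_distance,
         " after ", max_tries, " re-permutations")
  }
  d_far <- euclidean_distance(far, a, normalized = TRUE, cfg = cfg)
  s <- target_distance / d_far
  pert <- a + s * (far - a)
  achieved <- euclidean_distance(pert, a, normalized = TRUE, cfg = cfg)
  if (abs(achieved - target_distance) > tol * target_distance) {
    stop("perturbation missed the target distance: requested ",
         target_distance, ", achieved ", achieved)
  }
  structure(list(affinities = pert, concentration = odor$concentration,
                 seed = as.integer(seed)),
            class = "odor_stimulus")
}

#' @export
print.odor_stimulus <- function(x, ...) {
  cat("<odor_stimulus> n =", length(x$affinities),
      " concentration =", x$concentration, " seed =", x$seed, "\n")
  invisible(x)
}
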