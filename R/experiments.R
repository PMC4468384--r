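# Shared measurement primitive: run a baseline set of spontaneous
# simulations plus one evoked simulation per odor, and score rates and
# detection per population.
detect_odors <- function(network, odors, ne, seed, n_baseline = 5,
                         duration_ms = 1200, settle_ms = 200,
                         populations = c("mi", "pyr")) {
  stopifnot(n_baseline >= 2)
  spont <- lapply(seq_len(n_baseline + 1), function(i) {
    run_simulation(network, odor = NULL, ne = ne,
                   duration_ms = duration_ms, settle_ms = settle_ms,
                   seed = derive_seed(seed, 11, i))
  })
  ref <- spont[[n_baseline + 1]]
  base <- spont[seq_len(n_baseline)]
  per_odor <- lapply(seq_along(odors), function(k) {
    ev <- run_simulation(network, odor = odors[[k]], ne = ne,
                         duration_ms = duration_ms, settle_ms = settle_ms,
                         seed = derive_seed(seed, 13, k))
    stats <- lapply(populations, function(p) {
      rep <- detection_index(lapply(base, `[[`, c("rates", p)),
                             ev$rates[[p]], ref$rates[[p]])
      list(rate_mean = mean(ev$rates[[p]]), detection = rep$index,
           detectable = rep$detectable)
    })
    names(stats) <- populations
    stats
  })
  spont_rates <- lapply(populations, function(p) {
    mean(vapply(base, function(s) mean(s$rates[[p]]), numeric(1)))
  })
  names(spont_rates) <- populations
  list(per_odor = per_odor, spont_rate_mean = spont_rates)
}

#' Detection grid over norepinephrine and odor concentration
#'
#' For every (NE concentration, odor concentration) grid point, builds a
#' fresh network and odorant, runs spontaneous baseline and odor-evoked
#' simulations, and records mean firing rate and the detection index for
#' the mitral (bulbar) and pyramidal (cortical) populations.  The desk
#' default is a 10 x 10 grid with one instantiation per point; the full
#' published campaign (30 x 30) is reachable through the arguments.
#'
#' @param ne_um vector of NE concentrations (uM), length >= 2; default a
#'   log-spaced ladder over 1e-2..1e6 uM.
#' @param odor_conc vector of odor concentrations in \[0, 1\], length >= 2.
#' @param cfg a [network_config()].
#' @param master_seed master seed; all per-point seeds derive from it.
#' @param n_repeats fresh network+odor instantiations per grid point.
#' @param n_baseline spontaneous runs per point for the baseline pairs.
#' @param ne_flags list with `enabled_ob`, `enabled_pc`.
#' @param duration_ms,settle_ms simulation timing.
#' @return A tidy data frame: `ne_um`, `conc`, `rep`, `population`,
#'   `rate_mean`, `spont_rate_mean`, `detection`, `detectable`.
#' @export
detection_grid <- function(ne_um = 10^seq(-2, 6, length.out = 10),
                           odor_conc = seq(0.1, 1, length.out = 10),
                           cfg = network_config(), master_seed = 1,
                           n_repeats = 1, n_baseline = 5,
                           ne_flags = list(enabled_ob = TRUE,
                                           enabled_pc = TRUE),
                           duration_ms = 1200, settle_ms = 200) {
  stopifnot(length(ne_um) >= 2, length(odor_conc) >= 2)
  rows <- list()
  for (i in seq_along(ne_um)) {
    for (j in seq_along(odor_conc)) {
      for (r in seq_len(n_repeats)) {
        seed <- derive_seed(master_seed, i, j, r)
        point <- tryCatch(
          grid_point(cfg, seed, ne_um[i], odor_conc[j], ne_flags,
                     n_baseline, duration_ms, settle_ms),
          error = function(e) {
            stop("grid point (ne = ", ne_um[i], " uM, conc = ",
                 odor_conc[j], ", rep ", r, ") failed: ",
                 conditionMessage(e))
          })
        for (p in names(point$per_odor[[1]])) {
          st <- point$per_odor[[1]][[p]]
          rows[[length(rows) + 1]] <- data.frame(
            ne_um = ne_um[i], conc = odor_conc[j], rep = r, population = p,
            rate_mean = st$rate_mean,
            spont_rate_mean = point$spont_rate_mean[[p]],
            detection = st$detection, detectable = st$detectable)
        }
      }
    }
  }
  do.call(rbind, rows)
}

grid_point <- function(cfg, seed, ne_um, conc, ne_flags, n_baseline,
                       duration_ms, settle_ms) {
  net <- build_network(cfg, seed = derive_seed(seed, 1))
  odor <- generate_odor(derive_seed(seed, 2), concentration = conc,
                        cfg = cfg)
  ne <- ne_state(ob_um = ne_um, pc_um = ne_um,
                 enabled_ob = ne_flags$enabled_ob,
                 enabled_pc = ne_flags$enabled_pc)
  detect_odors(net, list(odor), ne, seed = derive_seed(seed, 3),
               n_baseline = n_baseline, duration_ms = duration_ms,
               settle_ms = settle_ms)
}

#' Locus-knockout comparison of norepinephrine modulation
#'
#' Runs the detection grid under four conditions with paired seeds (every
#' condition sees identical networks, odors and spike-draw streams, so
#' differences are attributable to the NE switches alone): modulation ON
#' in both structures, OFF in both, ON in the bulb only, and ON in the
#' cortex only.  Pyramidal rates and detection per condition are compared
#' against the both-ON control with paired Wilcoxon signed-rank tests,
#' Bonferroni-corrected across the three comparisons.
#'
#' @inheritParams detection_grid
#' @return List with `grid` (the per-condition tidy frame, extra column
#'   `condition`) and `comparisons` (one row per knockout condition:
#'   Wilcoxon statistic, raw and corrected p on Pyr rates, and the mean
#'   absolute detection difference from control).
#' @export
locus_knockout <- function(ne_um = 10^seq(-2, 6, length.out = 6),
                           odor_conc = seq(0.2, 1, length.out = 6),
                           cfg = network_config(), master_seed = 1,
                           n_baseline = 5, duration_ms = 1200,
                           settle_ms = 200) {
  conditions <- list(
    both_on = list(enabled_ob = TRUE, enabled_pc = TRUE),
    both_off = list(enabled_ob = FALSE, enabled_pc = FALSE),
    ob_only = list(enabled_ob = TRUE, enabled_pc = FALSE),
    pc_only = list(enabled_ob = FALSE, enabled_pc = TRUE)
  )
  grids <- lapply(names(conditions), function(cn) {
    g <- detection_grid(ne_um = ne_um, odor_conc = odor_conc, cfg = cfg,
                        master_seed = master_seed, n_repeats = 1,
                        n_baseline = n_baseline,
                        ne_flags = conditions[[cn]],
                        duration_ms = duration_ms, settle_ms = settle_ms)
    g$condition <- cn
    g
  })
  grid <- do.call(rbind, grids)
  ctrl <- grid[grid$condition == "both_on" & grid$population == "pyr", ]
  ord <- order(ctrl$ne_um, ctrl$conc)
  comparisons <- do.call(rbind, lapply(
    c("both_off", "ob_only", "pc_only"), function(cn) {
      g <- grid[grid$condition == cn & grid$population == "pyr", ]
      g <- g[order(g$ne_um, g$conc), ]
      cc <- ctrl[ord, ]
      ht <- compare_conditions(g$rate_mean, cc$rate_mean,
                               test = "wilcoxon", n_comparisons = 3)
      data.frame(condition = cn, statistic = ht$statistic,
                 p_value = ht$p_value, p_corrected = ht$p_corrected,
                 mean_abs_detection_diff =
                   mean(abs(g$detection - cc$detection)),
                 mean_abs_rate_diff = mean(abs(g$rate_mean - cc$rate_mean)))
    }))
  list(grid = grid, comparisons = comparisons)
}

#' Learn/recall protocol
#'
#' Trains fresh networks on a randomly chosen odorant under different
#' norepinephrine levels (default 4 consecutive 5 s sessions), then
#' presents the same odorant again with plasticity frozen, under each
#' recall NE level, and scores cortical rates and detection against the
#' naive (untrained) network.
#'
#' @param train_ne named vector of NE concentrations (uM) used during
#'   training; `NA` entries are skipped and the naive condition is always
#'   included.
#' @param recall_ne named vector of NE concentrations during recall.
#' @param odor_conc odor concentrations (trained and recalled at the same
#'   concentration).
#' @param n_repeats fresh network+odor instantiations.
#' @param sessions,session_ms training protocol.
#' @param cfg a [network_config()].
#' @param master_seed master seed.
#' @param n_baseline spontaneous runs for detection baselines.
#' @param duration_ms,settle_ms recall simulation timing.
#' @return Tidy data frame: `rep`, `conc`, `train` (`"naive"` or a name
#'   of `train_ne`), `train_ne_um`, `recall`, `recall_ne_um`,
#'   `population`, `rate_mean`, `detection`.
#' @export
learn_recall <- function(train_ne = c(low = 1e-2, medium = 1, high = 1e6),
                         recall_ne = c(low = 1e-2, medium = 1, high = 1e6),
                         odor_conc = c(0.2, 0.8), n_repeats = 10,
                         sessions = 4, session_ms = 5000,
                         cfg = network_config(), master_seed = 1,
                         n_baseline = 5, duration_ms = 1200,
                         settle_ms = 200) {
  stopifnot(!is.null(names(train_ne)), !is.null(names(recall_ne)))
  train_ne <- train_ne[!is.na(train_ne)]
  rows <- list()
  for (r in seq_len(n_repeats)) {
    for (ci in seq_along(odor_conc)) {
      seed <- derive_seed(master_seed, 31, r, ci)
      net <- build_network(cfg, seed = derive_seed(seed, 1))
      odor <- generate_odor(derive_seed(seed, 2),
                            concentration = odor_conc[ci], cfg = cfg)
      nets <- c(list(naive = net),
                lapply(seq_along(train_ne), function(ti) {
                  train_network(net, odor,
                                ne = ne_state(ob_um = train_ne[[ti]],
                                              pc_um = train_ne[[ti]]),
                                sessions = sessions,
                                session_ms = session_ms,
                                seed = derive_seed(seed, 3, ti))
                }))
      names(nets) <- c("naive", names(train_ne))
      for (tn in names(nets)) {
        for (rn in names(recall_ne)) {
          ne <- ne_state(ob_um = recall_ne[[rn]], pc_um = recall_ne[[rn]])
          res <- detect_odors(nets[[tn]], list(odor), ne,
                              seed = derive_seed(seed, 4, match(rn, names(recall_ne))),
                              n_baseline = n_baseline,
                              duration_ms = duration_ms,
                              settle_ms = settle_ms,
                              populations = c("mi", "pyr"))
          for (p in c("mi", "pyr")) {
            st <- res$per_odor[[1]][[p]]
            rows[[length(rows) + 1]] <- data.frame(
              rep = r, conc = odor_conc[ci], train = tn,
              train_ne_um = if (tn == "naive") NA_real_ else train_ne[[tn]],
              recall = rn, recall_ne_um = recall_ne[[rn]], population = p,
              rate_mean = st$rate_mean, detection = st$detection)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Perturbed-recall robustness curves
#'
#' Trains networks under different NE levels, then recalls progressively
#' perturbed versions of the learned odorant (normalized sensory distance
#' ladder), always at low NE, recording cortical rates and detection per
#' distance plus the sparseness of the learned normalized weights per
#' training condition.
#'
#' @param train_ne named vector of training NE concentrations (uM).
#' @param distances normalized odor distances in \[0, 1\].
#' @param odor_conc concentration of the trained/recalled odorant.
#' @param recall_ne_um NE concentration during recall (uM; the protocol
#'   always recalls at low NE).
#' @inheritParams learn_recall
#' @return List with `curve` (tidy frame: `rep`, `train`, `distance`,
#'   `population`, `rate_mean`, `detection`) and `sparseness` (per `rep`
#'   x `train` sparseness of the learned normalized weights).
#' @export
perturbation_curve <- function(train_ne = c(low = 1e-2, medium = 1,
                                            high = 1e6),
                               distances = c(0, 0.2, 0.4, 0.6, 0.8),
                               odor_conc = 0.2, recall_ne_um = 1e-2,
                               n_repeats = 10, sessions = 4,
                               session_ms = 5000, cfg = network_config(),
                               master_seed = 1, n_baseline = 5,
                               duration_ms = 1200, settle_ms = 200) {
  stopifnot(!is.null(names(train_ne)), all(distances >= 0 & distances <= 1))
  curve <- list()
  sp <- list()
  for (r in seq_len(n_repeats)) {
    seed <- derive_seed(master_seed, 41, r)
    net <- build_network(cfg, seed = derive_seed(seed, 1))
    odor <- generate_odor(derive_seed(seed, 2), concentration = odor_conc,
                          cfg = cfg)
    odors <- lapply(seq_along(distances), function(k) {
      perturb_odor(odor, distances[k], seed = derive_seed(seed, 5, k),
                   cfg = cfg)
    })
    for (ti in seq_along(train_ne)) {
      tn <- names(train_ne)[ti]
      trained <- train_network(net, odor,
                               ne = ne_state(ob_um = train_ne[[ti]],
                                             pc_um = train_ne[[ti]]),
                               sessions = sessions,
                               session_ms = session_ms,
                               seed = derive_seed(seed, 3, ti))
      sp[[length(sp) + 1]] <- data.frame(
        rep = r, train = tn, train_ne_um = train_ne[[ti]],
        sparseness = sparseness(
          trained$w_norm[trained$adjacency$pyr_pyr != 0]))
      res <- detect_odors(trained, odors,
                          ne_state(ob_um = recall_ne_um,
                                   pc_um = recall_ne_um),
                          seed = derive_seed(seed, 4, ti),
                          n_baseline = n_baseline,
                          duration_ms = duration_ms,
                          settle_ms = settle_ms,
                          populations = c("pyr"))
      for (k in seq_along(distances)) {
        st <- res$per_odor[[k]][["pyr"]]
        curve[[length(curve) + 1]] <- data.frame(
          rep = r, train = tn, train_ne_um = train_ne[[ti]],
          distance = distances[k], population = "pyr",
          rate_mean = st$rate_mean, detection = st$detection)
      }
    }
  }
  list(curve = do.call(rbind, curve), sparseness = do.call(rbind, sp))
}
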