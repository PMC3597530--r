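# Experiment suites orchestrating the computational studies end to end:
# DSI dose-response validation, theta-burst vs 20 Hz temporal-pattern
# discrimination, multi-spine spatial specificity and parameter-variation
# robustness. All suites are fully determined by their arguments and
# seeds; scaled = TRUE selects the desk-scale study conditions (coarse
# mesh, coarser tau-leap step, fewer trains) described in the vignette.

.suiteEngine <- function(scaled, t_end, seed = 1L, dt = NULL) {
  if (is.null(dt)) dt <- if (scaled) 5e-5 else 2.5e-6
  engineConfig(dt = dt, record_dt = if (scaled) 0.1 else 0.05,
               t_end = t_end, seed = seed)
}

.suiteMesh <- function(scaled, multi = FALSE, n_spines = 13, seed = 1L) {
  if (multi) {
    cfg <- if (scaled)
      meshConfig(length = 20, width = 1, nx = 25, ny = 2,
                 n_spines = n_spines, scaled = TRUE)
    else meshConfig(length = 20, width = 1, n_spines = n_spines)
    buildMultiSpineMesh(cfg, seed = seed)
  } else buildSingleSpineMesh(meshConfig(scaled = scaled))
}

#' Run an ensemble of trials over seeds
#'
#' @param model,mesh,schedule simulation inputs.
#' @param seeds integer vector of trial seeds.
#' @param config engine configuration (seed is overridden per trial).
#' @return list of \code{\linkS4class{Trajectory}} objects.
#' @export
runEnsemble <- function(model, mesh, schedule, seeds, config) {
  lapply(seeds, function(s)
    runSim(model, mesh, schedule, utils::modifyList(config, list(seed = as.integer(s)))))
}

#' Unstimulated resting-state run
#'
#' @param t_end horizon (s).
#' @param seeds trial seeds.
#' @param scaled desk-scale flag.
#' @return list with the whole-cytosol free-calcium ensemble
#'   (\code{ensembleStats} data.frame) and its time average.
#' @export
restingState <- function(t_end = 10, seeds = 1L, scaled = TRUE) {
  model <- buildNetwork()
  mesh <- .suiteMesh(scaled)
  trs <- runEnsemble(model, mesh, NULL, seeds, .suiteEngine(scaled, t_end))
  ens <- ensembleSeries(trs, "all", "Ca")
  list(series = ens, time_average = mean(ens$mean))
}

#' DSI dose-response suite
#'
#' Simulates the depolarization protocol over a grid of durations and
#' DHPG doses, and reports 2AG/active-PKC statistics, DHPG enhancement
#' ratios, and the DAG-lipase saturation diagnostic (peak whole-morphology
#' concentration of DAG-bound DAG-lipase complexes vs the total pool).
#'
#' @param durations depolarization durations (s).
#' @param dhpg_nM DHPG dose grid (nM); must include 0 for the
#'   normalization denominator.
#' @param seeds trial seeds.
#' @param scaled desk-scale flag.
#' @param tail_s recorded time after the end of the calcium injection (s).
#' @param params protocol parameters.
#' @return list with \code{table} (per-cell statistics), \code{ratios}
#'   (enhancement ratios per duration x dose) and \code{dagl_total_uM}.
#' @export
runDsiSuite <- function(durations = c(0.1, 1, 5),
                        dhpg_nM = c(0, 1000, 5000, 25000),
                        seeds = 1:3, scaled = TRUE, tail_s = 5,
                        params = protocolParams()) {
  stopifnot(0 %in% dhpg_nM)
  model <- buildNetwork()
  mesh <- .suiteMesh(scaled)
  dagl_total_uM <- model@config$pools[["DAGL"]] / 1000
  rows <- list(); ens_ag <- list()
  for (d in durations) for (g in dhpg_nM) {
    t_end <- 2 + d + tail_s
    sch <- dsiSchedule(d, g, params, t_end = t_end)
    trs <- runEnsemble(model, mesh, sch, seeds, .suiteEngine(scaled, t_end))
    key <- paste(d, g, sep = "|")
    ag <- ensembleSeries(trs, "all", "2AG")
    pkc <- ensembleSeries(trs, "all", "PKC.active")
    dagl <- ensembleSeries(trs, "all", "DAG.Ca.DAGL")
    gagtp <- ensembleSeries(trs, "all",
                            c("GaGTP", "PLC.Ca.GaGTP", "PLC.GaGTP",
                              "PLC.Ca.GaGTP.PIP2", "PLC.Ca.GaGTP.DAG"))
    ens_ag[[key]] <- ag
    win <- c(2, t_end)
    rows[[key]] <- data.frame(
      duration = d, dhpg_nM = g,
      ag_mean = windowStats(ag, win)$mean,
      ag_peak = windowStats(ag, win)$peak,
      pkc_mean = windowStats(pkc, win)$mean,
      pkc_peak = windowStats(pkc, win)$peak,
      dagl_bound_peak_uM = windowStats(dagl, win, smooth_width = 0.5)$peak / 1000,
      gagtp_peak = windowStats(gagtp, win)$peak)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  rat <- do.call(rbind, lapply(durations, function(d) {
    base <- ens_ag[[paste(d, 0, sep = "|")]]
    do.call(rbind, lapply(setdiff(dhpg_nM, 0), function(g) {
      data.frame(duration = d, dhpg_nM = g,
                 enhancement = enhancementRatio(
                   ens_ag[[paste(d, g, sep = "|")]], base,
                   window = c(2, 2 + d + tail_s)))
    }))
  }))
  list(table = tab, ratios = rat, dagl_total_uM = dagl_total_uM,
       series_2ag = ens_ag)
}

#' Temporal-pattern (plasticity) suite: theta burst vs 20 Hz
#'
#' Both protocols deliver identical calcium and ligand totals (guarded by
#' an assertion). Reports 2AG and active-PKC statistics in spine head and
#' dendritic submembrane, and the PKC:2AG index per protocol; optionally a
#' 20 Hz condition with 10 uM of exogenous fast calcium buffer.
#'
#' @param seeds trial seeds.
#' @param scaled desk-scale flag.
#' @param theta_trains,hz20_trains train counts (chosen so pulse totals
#'   match: theta delivers 40 pulses/train, 20 Hz delivers 20).
#' @param tail_s recorded tail after the last pulse (s).
#' @param bapta also run the 20 Hz protocol with 10 uM exogenous buffer.
#' @param params protocol parameters.
#' @param model optional NetworkModel override (used by the robustness
#'   suite).
#' @param dt optional tau-leap step override (s).
#' @return list of per-protocol statistics and the index table.
#' @export
runPlasticitySuite <- function(seeds = 1:3, scaled = TRUE,
                               theta_trains = 2, hz20_trains = 2 * theta_trains,
                               tail_s = if (scaled) 20 else 60,
                               bapta = FALSE, params = protocolParams(),
                               model = NULL, dt = NULL) {
  if (is.null(model)) model <- buildNetwork()
  mesh <- .suiteMesh(scaled)
  sch_tb <- thetaBurstSchedule(params, trains = theta_trains)
  sch_20 <- twentyHzSchedule(params, trains = hz20_trains)
  tot_tb <- injectedTotals(sch_tb); tot_20 <- injectedTotals(sch_20)
  if (!isTRUE(all.equal(tot_tb, tot_20)))
    stop("unequal injected totals between protocols")
  last <- function(s) max(events(s)$onset + events(s)$duration)
  t_end <- max(last(sch_tb), last(sch_20)) + tail_s
  run1 <- function(m, sch) {
    trs <- runEnsemble(m, mesh, sch, seeds, .suiteEngine(scaled, t_end, dt = dt))
    win <- c(0, t_end)
    stat <- function(region, species) {
      e <- ensembleSeries(trs, region, species)
      w <- windowStats(e, win)
      c(mean = w$mean, peak = w$peak)
    }
    pkc_sp <- stat("spine_head", "PKC.active")
    pkc_de <- stat("dendrite_sub", "PKC.active")
    ag_all <- stat("all", "2AG")
    pkc_all <- stat("all", "PKC.active")
    list(stats = data.frame(
           region = c("spine_head", "dendrite_sub", "all", "all"),
           species = c("PKC.active", "PKC.active", "2AG", "PKC.active"),
           mean = c(pkc_sp["mean"], pkc_de["mean"], ag_all["mean"], pkc_all["mean"]),
           peak = c(pkc_sp["peak"], pkc_de["peak"], ag_all["peak"], pkc_all["peak"])),
         index = pkc_all[["mean"]] / ag_all[["mean"]],
         ens = list(pkc = ensembleSeries(trs, "all", "PKC.active"),
                    ag = ensembleSeries(trs, "all", "2AG")))
  }
  out <- list(theta = run1(model, sch_tb), hz20 = run1(model, sch_20),
              t_end = t_end, window = c(0, t_end))
  if (bapta) {
    mb <- buildNetwork(networkConfig(bapta_nM = 10000,
                                     multipliers = model@config$multipliers))
    out$hz20_bapta <- run1(mb, sch_20)
  }
  out
}

#' Spatial-specificity suite on the multi-spine dendrite
#'
#' Dendritic calcium is injected along the whole dendrite (global
#' depolarization); glutamate and the synaptic calcium component target
#' only the stimulated spines. Reports per-spine active-PKC and 2AG means
#' and the PKC:2AG index.
#'
#' @param stim_spines stimulated spine indices (e.g. 1 or c(1, 8)).
#' @param protocols protocols to run.
#' @param seeds trial seeds.
#' @param scaled desk-scale flag.
#' @param n_spines number of spines on the 20 um dendrite.
#' @param theta_trains,hz20_trains,tail_s as in the plasticity suite.
#' @param params protocol parameters.
#' @param placement_seed spine-placement seed.
#' @return data.frame: protocol x spine with pkc_mean, ag_mean, index.
#' @export
runSpatialSuite <- function(stim_spines = 1,
                            protocols = c("theta_burst", "twenty_hz"),
                            seeds = 1L, scaled = TRUE, n_spines = 13,
                            theta_trains = 2, hz20_trains = 2 * theta_trains,
                            tail_s = if (scaled) 20 else 60,
                            params = protocolParams(),
                            placement_seed = 20L) {
  model <- buildNetwork()
  mesh <- .suiteMesh(scaled, multi = TRUE, n_spines = n_spines,
                     seed = placement_seed)
  if (any(stim_spines > n_spines)) stop("stimulated spine index out of range")
  res <- list()
  for (pr in protocols) {
    sch <- if (pr == "theta_burst")
      thetaBurstSchedule(params, trains = theta_trains, stim_spines = stim_spines)
    else twentyHzSchedule(params, trains = hz20_trains, stim_spines = stim_spines)
    t_end <- max(events(sch)$onset + events(sch)$duration) + tail_s
    trs <- runEnsemble(model, mesh, sch, seeds,
                       .suiteEngine(scaled, t_end, dt = if (scaled) 8e-5 else NULL))
    win <- c(0, t_end)
    for (s in seq_len(n_spines)) {
      pkc <- ensembleSeries(trs, paste0("spine:", s), "PKC.active")
      ag <- ensembleSeries(trs, paste0("spine:", s), "2AG")
      res[[paste(pr, s)]] <- data.frame(
        protocol = pr, spine = s, stimulated = s %in% stim_spines,
        pkc_mean = windowStats(pkc, win)$mean,
        ag_mean = windowStats(ag, win)$mean,
        index = pkc2agIndex(pkc, ag, win))
    }
  }
  out <- do.call(rbind, res); rownames(out) <- NULL
  out
}

#' Parameter variations for the robustness suite
#'
#' Affinity variations are applied to the forward (binding) rate of the
#' relevant row; "PSD" relocates spine-head membrane species to the PSD
#' slice; the two "Spine*" variations scale spine-membrane placement so
#' local spine concentrations match the dendritic submembrane.
#'
#' @return named list of variation descriptors.
#' @export
variationSpecs <- function() {
  list(
    Decay    = list(multipliers = c("2AG degradation.kf" = 0.5)),
    Desens05 = list(multipliers = c("mGluR desensitization.kf" = 0.5)),
    Desens02 = list(multipliers = c("mGluR desensitization.kf" = 0.2)),
    Desens4x = list(multipliers = c("mGluR desensitization.kf" = 4),
                    pools = c(Gabg = 3 * 2000)),
    DaglA    = list(multipliers = c("Calcium activates DAG lipase.kf" = 0.5)),
    DaglB    = list(multipliers = c("Calcium activates DAG lipase.kf" = 2)),
    DaglC    = list(multipliers = c("2AG production.kf" = 0.5)),
    DaglD    = list(multipliers = c("2AG production.kf" = 2)),
    LowGap   = list(multipliers = c("Hydrolysis of GaGTP.kf" = 0.5)),
    PSD      = list(relocate_psd = TRUE),
    SpinePLC = list(spine_match = c("PLC", "PIP2", "mGluR")),
    SpineDgl = list(spine_match = c("PLC", "PIP2", "mGluR", "DAGL"),
                    spine_match_add = TRUE)
  )
}

#' Build the model for a named parameter variation
#'
#' @param name variation name from \code{\link{variationSpecs}}, or
#'   "control".
#' @return a NetworkModel.
#' @export
variationModel <- function(name) {
  if (name == "control") return(buildNetwork())
  vs <- variationSpecs()[[name]]
  if (is.null(vs)) stop("unknown variation name: ", name)
  cfg <- networkConfig(pools = vs$pools, multipliers = vs$multipliers)
  model <- buildNetwork(cfg)
  if (isTRUE(vs$relocate_psd)) {
    sp <- model@species
    for (i in which(sp$compartment == "membrane")) {
      loc <- sp$localization[[i]]
      if ("spine_head" %in% loc)
        sp$localization[[i]] <- union(setdiff(loc, "spine_head"), "psd")
    }
    model@species <- sp
  }
  if (!is.null(vs$spine_match)) {
    cfgm <- model@config
    cfgm$spine_match <- vs$spine_match
    cfgm$spine_match_add <- isTRUE(vs$spine_match_add)
    model@config <- cfgm
  }
  model
}

#' Robustness suite: rank-order of the plasticity index under variations
#'
#' Re-runs the theta-burst vs 20 Hz comparison for each parameter
#' variation and reports the PKC:2AG index of both protocols.
#'
#' @param variations variation names (default: all).
#' @param seeds trial seeds.
#' @param scaled desk-scale flag.
#' @param theta_trains,hz20_trains,tail_s scaled-down train structure.
#' @param params protocol parameters.
#' @return data.frame: variation, index_theta, index_20hz, preserved.
#' @export
runRobustnessSuite <- function(variations = names(variationSpecs()),
                               seeds = 1L, scaled = TRUE,
                               theta_trains = 1, hz20_trains = 2,
                               tail_s = if (scaled) 10 else 60,
                               params = protocolParams()) {
  rows <- lapply(c("control", variations), function(v) {
    pl <- runPlasticitySuite(seeds = seeds, scaled = scaled,
                             theta_trains = theta_trains,
                             hz20_trains = hz20_trains, tail_s = tail_s,
                             params = params, model = variationModel(v),
                             dt = if (scaled) 1e-4 else NULL)
    data.frame(variation = v, index_theta = pl$theta$index,
               index_20hz = pl$hz20$index,
               preserved = pl$theta$index > pl$hz20$index)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
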