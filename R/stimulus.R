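# Stimulation protocols: timed calcium/glutamate injection schedules for
# depolarization (DSI), theta-burst and 20 Hz stimulation.
#
# Every pulse injects calcium for 3 ms into the PSD (synaptic NMDA +
# voltage-gated channels) and into the dendritic submembrane (voltage-gated
# channels), and releases mGluR ligand into the PSD. Schedules are purely
# deterministic event tables; stochasticity enters only in the engine.

#' Protocol parameters
#'
#' Defaults are the plasticity-induction values: theta-burst = 4 pulses per
#' burst at 50 Hz, 10 bursts per train with 95 ms between burst onsets, 10
#' trains 15 s apart (onset to onset); 20 Hz = 20 trains of 20 pulses at
#' 20 Hz with a 9 s gap between trains. Both deliver 400 pulses and
#' identical calcium/ligand totals. Per-pulse molecule amounts are
#' calibrated against a target single-pulse free-calcium transient (see
#' \code{\link{calibrateInjection}}); the shipped defaults come from that
#' calibration on the default single-spine mesh.
#'
#' @param pulses_per_burst,burst_hz,bursts_per_train,burst_interval,trains,train_interval
#'   theta-burst train structure (Hz and s).
#' @param pulses_per_train_20,rate_20,trains_20,train_gap_20 20 Hz train
#'   structure.
#' @param pulse_duration calcium pulse duration (s).
#' @param ca_spine,ca_dendrite calcium molecules per pulse injected into
#'   the stimulated PSD and into the dendritic submembrane.
#' @param glu_per_pulse mGluR-ligand molecules released into the PSD per
#'   pulse.
#' @param dsi_rate0 initial calcium injection rate for DSI depolarization
#'   (molecules/s, summed over spine + dendrite sites).
#' @param dsi_tau decay time constant of the DSI injection rate for the
#'   1 s and 5 s depolarizations (s).
#' @param dsi_spine_frac fraction of DSI calcium injected into the spine
#'   (membrane-area proportional by default).
#' @return list of protocol parameters.
#' @export
protocolParams <- function(pulses_per_burst = 4, burst_hz = 50,
                           bursts_per_train = 10, burst_interval = 0.095,
                           trains = 10, train_interval = 15,
                           pulses_per_train_20 = 20, rate_20 = 20,
                           trains_20 = 20, train_gap_20 = 9,
                           pulse_duration = 0.003,
                           ca_spine = 1000, ca_dendrite = 4000,
                           glu_per_pulse = 1000,
                           dsi_rate0 = 1.2e5, dsi_tau = 2,
                           dsi_spine_frac = 0.28) {
  p <- as.list(environment())
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))
                | names(p) == "dsi_spine_frac"))
  p
}

.pulseEvents <- function(onsets, params, psd_target = "psd") {
  n <- length(onsets)
  mk <- function(species, target, total)
    data.frame(species = species, target = target, kind = "add",
               onset = rep(onsets, each = 1), duration = params$pulse_duration,
               total = total, tau = NA_real_, clamp_nM = NA_real_,
               stringsAsFactors = FALSE)
  ev <- rbind(mk("Ca", psd_target, params$ca_spine),
              mk("Ca", "dendrite_sub", params$ca_dendrite),
              mk("Glu", psd_target, params$glu_per_pulse))
  ev[order(ev$onset, ev$species), ]
}

#' Theta-burst stimulation schedule
#'
#' @param params a \code{\link{protocolParams}} list.
#' @param trains optional override of the number of trains (scaled-down
#'   runs use fewer trains).
#' @param stim_spines spine indices receiving the synaptic (PSD) input;
#'   NULL targets every PSD in the mesh (single-spine morphology).
#' @return a \code{\linkS4class{StimulusSchedule}}.
#' @examples
#' sch <- thetaBurstSchedule()
#' sum(events(sch)$species == "Ca" & events(sch)$target == "psd")  # 400
#' @export
thetaBurstSchedule <- function(params = protocolParams(), trains = NULL,
                               stim_spines = NULL) {
  if (!is.null(trains)) params$trains <- trains
  burst_dur <- (params$pulses_per_burst - 1) / params$burst_hz
  if (burst_dur >= params$burst_interval)
    stop("burst duration exceeds burst interval")
  onsets <- as.vector(outer(
    as.vector(outer((seq_len(params$pulses_per_burst) - 1) / params$burst_hz,
                    (seq_len(params$bursts_per_train) - 1) * params$burst_interval,
                    "+")),
    (seq_len(params$trains) - 1) * params$train_interval, "+"))
  targets <- if (is.null(stim_spines)) "psd" else paste0("psd:", stim_spines)
  ev <- do.call(rbind, lapply(targets, function(tg) {
    e <- .pulseEvents(sort(onsets), params, tg)
    # dendritic calcium is global: emit it only once
    if (tg != targets[1]) e <- e[e$target != "dendrite_sub", ]
    e
  }))
  ev <- ev[order(ev$onset, ev$species, ev$target), ]
  rownames(ev) <- NULL
  new("StimulusSchedule", events = ev, protocol = "theta_burst", params = params)
}

#' 20 Hz stimulation schedule
#'
#' Same per-pulse composition as theta-burst; the default train structure
#' delivers the same 400-pulse total.
#'
#' @inheritParams thetaBurstSchedule
#' @return a \code{\linkS4class{StimulusSchedule}}.
#' @export
twentyHzSchedule <- function(params = protocolParams(), trains = NULL,
                             stim_spines = NULL) {
  if (!is.null(trains)) params$trains_20 <- trains
  train_dur <- params$pulses_per_train_20 / params$rate_20
  onset_step <- train_dur + params$train_gap_20
  onsets <- as.vector(outer((seq_len(params$pulses_per_train_20) - 1) / params$rate_20,
                            (seq_len(params$trains_20) - 1) * onset_step, "+"))
  targets <- if (is.null(stim_spines)) "psd" else paste0("psd:", stim_spines)
  ev <- do.call(rbind, lapply(targets, function(tg) {
    e <- .pulseEvents(sort(onsets), params, tg)
    if (tg != targets[1]) e <- e[e$target != "dendrite_sub", ]
    e
  }))
  ev <- ev[order(ev$onset, ev$species, ev$target), ]
  rownames(ev) <- NULL
  new("StimulusSchedule", events = ev, protocol = "twenty_hz", params = params)
}

#' DSI (depolarization) schedule
#'
#' DHPG (modeled as a sustained clamp of the mGluR-agonist species over the
#' whole morphology) is applied at t = 0; calcium injection into spine and
#' dendrite starts at t = 2 s. The injection rate is constant for the
#' 0.1 s depolarization and decays exponentially for the 1 s and 5 s
#' depolarizations, approximating voltage- and calcium-dependent channel
#' inactivation.
#'
#' @param depol_duration depolarization duration (s), typically 0.1, 1 or 5.
#' @param dhpg_nM DHPG concentration (nM); 0 omits the ligand event.
#' @param params a \code{\link{protocolParams}} list.
#' @param t_end end of the DHPG application window (s).
#' @return a \code{\linkS4class{StimulusSchedule}}.
#' @export
dsiSchedule <- function(depol_duration, dhpg_nM = 0,
                        params = protocolParams(), t_end = 60) {
  if (depol_duration <= 0) stop("non-positive depolarization duration")
  if (dhpg_nM < 0) stop("negative DHPG concentration")
  tau <- if (depol_duration <= 0.5) NA_real_ else params$dsi_tau
  total <- if (is.na(tau)) params$dsi_rate0 * depol_duration
           else params$dsi_rate0 * tau * (1 - exp(-depol_duration / tau))
  mkca <- function(target, frac)
    data.frame(species = "Ca", target = target, kind = "add", onset = 2,
               duration = depol_duration, total = total * frac, tau = tau,
               clamp_nM = NA_real_, stringsAsFactors = FALSE)
  ev <- rbind(mkca("spine_head", params$dsi_spine_frac * 0.8),
              mkca("psd", params$dsi_spine_frac * 0.2),
              mkca("dendrite_sub", 1 - params$dsi_spine_frac))
  if (dhpg_nM > 0) {
    ev <- rbind(data.frame(species = "Glu", target = "all", kind = "clamp",
                           onset = 0, duration = t_end, total = NA_real_,
                           tau = NA_real_, clamp_nM = dhpg_nM,
                           stringsAsFactors = FALSE), ev)
  }
  ev <- ev[order(ev$onset, ev$species, ev$target), ]
  rownames(ev) <- NULL
  new("StimulusSchedule", events = ev, protocol = "dsi",
      params = c(params, list(depol_duration = depol_duration,
                              dhpg_nM = dhpg_nM)))
}

#' Total injected molecules of a schedule, by species
#'
#' @param schedule a StimulusSchedule.
#' @return named numeric vector of total injected molecules ("add" events
#'   only; clamps are excluded).
#' @export
injectedTotals <- function(schedule) {
  ev <- schedule@events
  ev <- ev[ev$kind == "add", ]
  tapply(ev$total, ev$species, sum)
}

#' Calibrate a calcium injection amplitude against a target transient
#'
#' Secant search over the injection amplitude until the trial-mean peak
#' free calcium in the requested region is within tolerance of the target.
#' Used to fix the per-pulse and DSI injection defaults; the search is
#' monotone because peak calcium increases with amplitude.
#'
#' @param model,mesh network and mesh to simulate on.
#' @param make_schedule function(amplitude) returning a StimulusSchedule.
#' @param target_nM target peak free-calcium concentration (nM).
#' @param region region whose peak is matched.
#' @param t_end simulated horizon (s).
#' @param seeds trial seeds averaged over.
#' @param engine an \code{\link{engineConfig}} list.
#' @param tol relative tolerance (default 10\%).
#' @param max_iter maximum search iterations.
#' @param amplitude0 starting amplitude.
#' @return list with \code{amplitude}, \code{peak_nM} and \code{iterations}.
#' @export
calibrateInjection <- function(model, mesh, make_schedule, target_nM,
                               region = "spine_head", t_end = 0.2,
                               seeds = 1L, engine = engineConfig(t_end = t_end),
                               tol = 0.1, max_iter = 12, amplitude0 = 1e4) {
  rest <- 51
  if (target_nM <= rest) return(list(amplitude = 0, peak_nM = rest, iterations = 0))
  peak_for <- function(amp) {
    pk <- vapply(seeds, function(s) {
      tr <- runSim(model, mesh, make_schedule(amp),
                   utils::modifyList(engine, list(seed = s, t_end = t_end)))
      rs <- regionSummary(tr, region, "Ca")
      max(rs$conc_nM)
    }, numeric(1))
    mean(pk)
  }
  amp <- amplitude0
  pk <- peak_for(amp)
  it <- 1
  while (abs(pk - target_nM) > tol * target_nM && it < max_iter) {
    # peak elevation above rest scales close to linearly with amplitude
    amp <- amp * (target_nM - rest) / max(pk - rest, 1e-6)
    pk <- peak_for(amp)
    it <- it + 1
  }
  if (abs(pk - target_nM) > tol * target_nM)
    warning("injection calibration did not converge")
  list(amplitude = amp, peak_nM = pk, iterations = it)
}
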