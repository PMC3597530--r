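test_that("theta-burst schedule has the published train structure", {
  sch <- thetaBurstSchedule()
  ev <- events(sch)
  capsd <- ev[ev$species == "Ca" & ev$target == "psd", ]
  expect_equal(nrow(capsd), 400)               # 4 x 10 x 10 pulses
  expect_true(all(capsd$duration == 0.003))
  # within-burst onsets at 0, 20, 40, 60 ms
  expect_equal(capsd$onset[1:4], c(0, 0.02, 0.04, 0.06))
  # burst onsets 95 ms apart
  burst_onsets <- capsd$onset[seq(1, 40, by = 4)]
  expect_equal(diff(burst_onsets), rep(0.095, 9))
  # trains 15 s apart onset-to-onset
  expect_equal(capsd$onset[41] - capsd$onset[1], 15)
  # each pulse also injects dendritic calcium and PSD glutamate
  expect_equal(sum(ev$species == "Ca" & ev$target == "dendrite_sub"), 400)
  expect_equal(sum(ev$species == "Glu"), 400)
  # burst longer than the burst interval is rejected
  expect_error(thetaBurstSchedule(protocolParams(pulses_per_burst = 6)),
               "exceeds")
})

test_that("20 Hz schedule delivers the same totals as theta burst", {
  sch <- twentyHzSchedule()
  ev <- events(sch)
  capsd <- ev[ev$species == "Ca" & ev$target == "psd", ]
  expect_equal(nrow(capsd), 400)               # 20 x 20 pulses
  expect_equal(diff(capsd$onset[1:20]), rep(0.05, 19))  # 20 Hz spacing
  # 1 s train period + 9 s gap = trains repeat at a 10 s interval
  expect_equal(capsd$onset[21] - capsd$onset[1], 10)
  expect_equal(injectedTotals(sch), injectedTotals(thetaBurstSchedule()))
})

test_that("DSI schedules follow the depolarization grammar", {
  p <- protocolParams()
  # no DHPG, short depolarization: constant-rate calcium only
  s1 <- dsiSchedule(0.1, 0)
  ev <- events(s1)
  expect_true(all(ev$species == "Ca"))
  expect_true(all(is.na(ev$tau)))
  expect_equal(unique(ev$onset), 2)
  # long depolarizations decay; ligand precedes calcium by 2 s
  s5 <- dsiSchedule(5, 25000)
  ev <- events(s5)
  expect_equal(ev$onset[ev$species == "Glu"], 0)
  expect_equal(unique(ev$onset[ev$species == "Ca"]), 2)
  expect_true(all(ev$tau[ev$species == "Ca"] == p$dsi_tau))
  # rate at the end of a 5 s injection is strictly below the initial rate
  expect_lt(exp(-5 / p$dsi_tau), 1)
  # totals integrate the decaying profile
  tot <- sum(ev$total[ev$species == "Ca"])
  expect_equal(tot, p$dsi_rate0 * p$dsi_tau * (1 - exp(-5 / p$dsi_tau)),
               tolerance = 1e-9)
  expect_error(dsiSchedule(-1, 0), "duration")
  expect_error(dsiSchedule(1, -5), "negative")
})

test_that("schedules are deterministic and time-sorted", {
  expect_identical(events(thetaBurstSchedule()), events(thetaBurstSchedule()))
  for (sch in list(thetaBurstSchedule(), twentyHzSchedule(), dsiSchedule(1, 1000)))
    expect_true(!is.unsorted(events(sch)$onset))
})

test_that("a decaying injection delivers its declared total through the engine", {
  # injection-only model: one immobile species, no reactions
  rows <- reactionRows(list("A <-> B", 0))
  m <- miniModel(rows, miniSpecies(c("A", "B")))
  mesh <- boxMesh(1)
  ev <- data.frame(species = "A", target = "all", kind = "add", onset = 0.05,
                   duration = 1, total = 5000, tau = 0.3, clamp_nM = NA_real_)
  sch <- new("StimulusSchedule", events = ev, protocol = "test", params = list())
  tot <- vapply(1:20, function(s) {
    tr <- runSim(m, mesh, sch, engineConfig(dt = 1e-4, record_dt = 0.5,
                                            t_end = 1.5, seed = s))
    tr@counts[1, "A", length(tr@times)]
  }, numeric(1))
  expect_lt(abs(mean(tot) - 5000) / (sd(tot) / sqrt(20)), 4)
})

test_that("injection calibration is monotone and hits its target", {
  # pure injection + first-order clearance: peak scales linearly with
  # amplitude, so the secant search converges in a few iterations
  rows <- reactionRows(list("Ca <-> B", 20))
  side <- 0.5
  nM1 <- countsToConcentration(1, side^3 * 1e-15)
  sp <- miniSpecies(c("Ca", "B"), init = c(51, 0))
  m <- miniModel(rows, sp)
  m@species$localization <- I(rep(list("box"), 2))
  mesh <- boxMesh(1, side)
  mk <- function(amp) new("StimulusSchedule", events = data.frame(
    species = "Ca", target = "all", kind = "add", onset = 0.02,
    duration = 0.003, total = amp, tau = NA_real_, clamp_nM = NA_real_),
    protocol = "pulse", params = list())
  cal <- calibrateInjection(m, mesh, mk, target_nM = 1000, region = "box",
                            t_end = 0.05,
                            engine = engineConfig(dt = 1e-5, record_dt = 0.002,
                                                  t_end = 0.05),
                            seeds = 1:3)
  expect_lt(abs(cal$peak_nM - 1000) / 1000, 0.1)
  cal2 <- calibrateInjection(m, mesh, mk, target_nM = 2000, region = "box",
                             t_end = 0.05,
                             engine = engineConfig(dt = 1e-5, record_dt = 0.002,
                                                   t_end = 0.05),
                             seeds = 1:3)
  expect_gt(cal2$amplitude, cal$amplitude)   # larger target, larger amplitude
  # target at rest needs no injection
  cal0 <- calibrateInjection(m, mesh, mk, target_nM = 51, region = "box")
  expect_equal(cal0$amplitude, 0)
})
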