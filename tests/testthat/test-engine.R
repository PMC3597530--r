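test_that("identical seeds give bitwise-identical trajectories", {
  net <- buildNetwork()
  mesh <- buildSingleSpineMesh(meshConfig(scaled = TRUE))
  cfg <- engineConfig(dt = 1e-4, record_dt = 0.05, t_end = 0.3, seed = 11)
  t1 <- runSim(net, mesh, NULL, cfg)
  t2 <- runSim(net, mesh, NULL, cfg)
  expect_identical(trajCounts(t1), trajCounts(t2))
  t3 <- runSim(net, mesh, NULL, utils::modifyList(cfg, list(seed = 12L)))
  expect_false(identical(trajCounts(t1), trajCounts(t3)))
})

test_that("a silent system stays constant", {
  rows <- reactionRows(list("A <-> B", 0))
  m <- miniModel(rows, miniSpecies(c("A", "B")))
  X <- countMatrix(c("A", "B"), c(500L, 7L))
  tr <- runSim(m, boxMesh(1), NULL,
               engineConfig(dt = 1e-4, record_dt = 0.1, t_end = 0.5),
               counts = X)
  expect_true(all(tr@counts[1, "A", ] == 500))
  expect_true(all(tr@counts[1, "B", ] == 7))
})

test_that("pure decay matches the closed-form exponential mean", {
  res <- checkFixture("decay", n_replicates = 200, seed = 3)
  expect_true(res$pass)
  # the t = 0.1 s checkpoint sits near 1000*exp(-1) = 367.9
  i <- which.min(abs(res$detail$checkpoint - 0.1))
  expect_equal(res$detail$expected[i], 1000 * exp(-1), tolerance = 1e-6)
  expect_lt(abs(res$detail$observed[i] - 367.9) / 367.9, 0.05)
})

test_that("two coupled boxes equilibrate to a 50/50 split", {
  res <- checkFixture("two_box_diffusion", n_replicates = 150, seed = 5)
  expect_true(res$pass)
})

test_that("diffusion conserves molecule number exactly", {
  rows <- reactionRows(list("A <-> B", 0))
  m <- miniModel(rows, miniSpecies(c("A", "B"), D = c(100, 0)))
  X <- countMatrix(c("A", "B"), c(0L, 0L), nsub = 2)
  X["A", 1] <- 1000L
  tr <- runSim(m, boxMesh(2), NULL,
               engineConfig(dt = 1e-4, record_dt = 0.01, t_end = 0.2),
               counts = X)
  totals <- apply(tr@counts[, "A", ], 2, sum)
  expect_true(all(totals == 1000))
})

test_that("counts never go negative under heavy stimulation", {
  net <- buildNetwork()
  mesh <- buildSingleSpineMesh(meshConfig(scaled = TRUE))
  sch <- dsiSchedule(1, 25000)
  tr <- runSim(net, mesh, sch, engineConfig(dt = 5e-5, record_dt = 0.05,
                                            t_end = 3.5, seed = 2))
  expect_true(all(tr@counts >= 0))
})

test_that("well-mixed ensemble mean matches the deterministic oracle", {
  # reversible calcium/calbindin binding at the published rates; the ODE
  # oracle predicts the bound/free partition (Kd = 700 nM)
  rows <- reactionRows(list("Ca + B <-> BCa", 0.028, 19.6))
  sp <- miniSpecies(c("Ca", "B", "BCa"), init = c(5100, 153290, 0))
  m <- miniModel(rows, sp)
  ode <- solveReferenceOde(m, times = seq(0, 0.5, by = 0.01))
  eq <- ode[nrow(ode), ]
  # equilibrium satisfies the mass-action Kd relation with the remaining
  # free buffer
  expect_equal(eq$BCa / eq$Ca, (153290 - eq$BCa) / 700, tolerance = 1e-3)
  # in the trace-calcium limit the bound/free ratio approaches B_total/Kd
  ode2 <- solveReferenceOde(m, init_nM = c(Ca = 51), times = seq(0, 0.5, 0.01))
  eq2 <- ode2[nrow(ode2), ]
  expect_equal(eq2$BCa / eq2$Ca, 153290 / 700, tolerance = 0.02)
  mesh <- boxMesh(1, 0.25)
  trs <- lapply(1:40, function(s)
    runSim(m, mesh, NULL, engineConfig(dt = 5e-5, record_dt = 0.05,
                                       t_end = 0.5, seed = s)))
  vol <- 0.25^3 * 1e-15
  for (cp in c(0.1, 0.3, 0.5)) {
    idx <- which.min(abs(trs[[1]]@times - cp))
    obs <- vapply(trs, function(tr)
      countsToConcentration(tr@counts[1, "BCa", idx], vol), numeric(1))
    mu <- approx(ode$time, ode$BCa, cp)$y
    z <- (mean(obs) - mu) / (sd(obs) / sqrt(length(obs)))
    expect_lt(abs(z), 4)
  }
})

test_that("zero-rate ODE systems stay constant", {
  rows <- reactionRows(list("A <-> B", 0))
  m <- miniModel(rows, miniSpecies(c("A", "B"), init = c(100, 5)))
  ode <- solveReferenceOde(m, times = seq(0, 1, by = 0.1))
  expect_true(all(abs(ode$A - 100) < 1e-8))
  expect_true(all(abs(ode$B - 5) < 1e-8))
})

test_that("clamp events hold a species at the requested concentration", {
  rows <- reactionRows(list("A <-> B", 3))
  m <- miniModel(rows, miniSpecies(c("A", "B")))
  side <- 0.5
  nM1 <- countsToConcentration(1, side^3 * 1e-15)
  ev <- data.frame(species = "A", target = "all", kind = "clamp", onset = 0,
                   duration = 2, total = NA_real_, tau = NA_real_,
                   clamp_nM = 100 * nM1)
  sch <- new("StimulusSchedule", events = ev, protocol = "clamp", params = list())
  tr <- runSim(m, boxMesh(1, side), sch,
               engineConfig(dt = 1e-4, record_dt = 0.2, t_end = 1))
  expect_true(all(tr@counts[1, "A", -1] == 100))
  # conversion of A continues, fed by the clamp
  expect_gt(tr@counts[1, "B", length(tr@times)], 0)
})
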