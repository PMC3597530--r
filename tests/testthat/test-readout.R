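# a small synthetic Trajectory for readout tests
mkTraj <- function(counts, volumes, times = seq_len(dim(counts)[3]) - 1,
                   regions = rep("box", nrow(counts)), spine = NA) {
  groups <- data.frame(name = paste0("g", seq_len(dim(counts)[1])),
                       region = regions, spine = spine, volume = volumes,
                       n_sub = 1L)
  new("Trajectory", times = as.numeric(times), counts = counts,
      groups = groups, species = dimnames(counts)[[2]], seed = 1L,
      config = list(), corrections = 0)
}

test_that("count to concentration conversion is exact", {
  expect_equal(countsToConcentration(0, 1e-15), 0)
  expect_equal(countsToConcentration(1, 7.84e-18), 211.9, tolerance = 1e-3)
  expect_error(countsToConcentration(1, 0), "volume")
})

test_that("region summaries are volume-weighted", {
  counts <- array(0, dim = c(2, 1, 3), dimnames = list(NULL, "X", NULL))
  v <- 1e-15
  # 10 nM and 30 nM in two equal subvolumes -> 20 nM overall
  n10 <- round(10e-9 * 6.02214076e23 * v)
  counts[1, 1, ] <- n10; counts[2, 1, ] <- 3 * n10
  tr <- mkTraj(counts, c(v, v), regions = c("box", "box"))
  rs <- regionSummary(tr, "box", "X")
  expect_equal(rs$conc_nM, rep(20, 3), tolerance = 0.01)
  # single-group region equals that group's series
  tr2 <- mkTraj(counts, c(v, v), regions = c("a", "b"))
  expect_equal(regionSummary(tr2, "a", "X")$count, rep(n10, 3))
  expect_error(regionSummary(tr2, "nowhere", "X"), "unknown region")
  expect_error(regionSummary(tr2, "a", "Y"), "unknown species")
})

test_that("ensemble statistics follow the textbook formulas", {
  mk <- function(v) data.frame(time = 0, conc_nM = v,
                               count = v)
  ens <- ensembleStats(list(mk(2), mk(4), mk(6)))
  expect_equal(ens$mean, 4)
  expect_equal(ens$sd, 2)
  expect_equal(ens$sem, 2 / sqrt(3))
  one <- ensembleStats(list(mk(5)))
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(ensembleStats(list(data.frame(time = 0, conc_nM = 1),
                                  data.frame(time = 1, conc_nM = 1))),
               "mismatched")
})

test_that("averaging over trials shrinks fluctuations", {
  # variance of a 3-trial mean is a third of the single-trial variance
  set.seed(7)
  trials <- lapply(1:3, function(i)
    data.frame(time = 1:500, conc_nM = rpois(500, 20)))
  ens <- ensembleStats(trials)
  expect_lt(var(ens$mean), var(trials[[1]]$conc_nM) / 1.5)
})

test_that("enhancement ratio normalizes by the no-agonist response", {
  e1 <- data.frame(time = 0:10, mean = rep(4, 11))
  e0 <- data.frame(time = 0:10, mean = rep(2, 11))
  expect_equal(enhancementRatio(e1, e0), 2)
  expect_equal(enhancementRatio(e0, e0), 1)
  zero <- data.frame(time = 0:10, mean = rep(0, 11))
  expect_error(enhancementRatio(e1, zero), "not positive")
})

test_that("the plasticity index is scale-equivariant and classifies", {
  pkc <- data.frame(time = 0:10, mean = rep(6, 11))
  ag <- data.frame(time = 0:10, mean = rep(2, 11))
  expect_equal(pkc2agIndex(pkc, ag), 3)
  expect_equal(pkc2agIndex(ag, ag), 1)
  pkc2 <- pkc; pkc2$mean <- pkc$mean * 2
  expect_equal(pkc2agIndex(pkc2, ag), 2 * pkc2agIndex(pkc, ag))
  # unit invariance: scaling both series (nM -> counts) leaves it unchanged
  k <- 602.2
  expect_equal(pkc2agIndex(transform(pkc, mean = mean * k),
                           transform(ag, mean = mean * k)),
               pkc2agIndex(pkc, ag))
  expect_error(pkc2agIndex(pkc, transform(ag, mean = 0)), "2AG")
})

test_that("window statistics smooth single-sample spikes out of peaks", {
  tm <- seq(0, 10, by = 0.1)
  x <- rep(10, length(tm)); x[50] <- 1000
  ens <- data.frame(time = tm, mean = x)
  ws <- windowStats(ens, c(0, 10), smooth_width = 1)
  expect_lt(ws$peak, 150)     # the lone spike is averaged down
  expect_gt(ws$peak, 10)
  raw <- windowStats(ens, c(0, 10), smooth_width = 0)
  expect_equal(raw$peak, 1000)
})

test_that("the tidy trajectory view preserves counts and units", {
  counts <- array(seq_len(2 * 2 * 3), dim = c(2, 2, 3),
                  dimnames = list(NULL, c("X", "Y"), NULL))
  tr <- mkTraj(counts, c(1e-15, 2e-15), regions = c("a", "b"))
  df <- trajectoryToDataFrame(tr)
  expect_equal(nrow(df), 2 * 2 * 3)
  one <- df[df$group == "g2" & df$species == "Y" & df$time == 2, ]
  expect_equal(one$count, unname(counts[2, 2, 3]))
  expect_equal(one$conc_nM, unname(countsToConcentration(counts[2, 2, 3], 2e-15)))
})
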