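test_that("reaction-row expansion produces the expected elementary channels", {
  # enzyme row: binding, unbinding and catalytic channels
  ch <- expandReactionRow("Ca + PMCA <-> PMCA.Ca => PMCA + CaExt", 0.05, 7, 3.5)
  expect_equal(nrow(ch), 3)
  expect_setequal(ch$type, c("bind", "unbind", "cat"))
  expect_equal(ch$k[ch$type == "bind"], 0.05)
  expect_equal(ch$order[ch$type == "bind"], 2)
  expect_equal(ch$k[ch$type == "unbind"], 7)
  expect_equal(ch$k[ch$type == "cat"], 3.5)
  expect_equal(ch$produce[ch$type == "cat"][[1]], c(PMCA = 1L, CaExt = 1L))

  # reversible binding: exactly two channels, no catalytic channel
  ch <- expandReactionRow("Ca + Calbindin <-> Calbindin.Ca", 0.028, 19.6)
  expect_equal(nrow(ch), 2)
  expect_setequal(ch$type, c("fwd", "back"))

  # one-way first-order conversion: a single channel
  ch <- expandReactionRow("2AG <-> 2AGdeg", 5)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$order, 1)
  expect_equal(ch$k, 5)

  # paired-calcium stoichiometry consumes two molecules per firing
  ch <- expandReactionRow("Cam + 2*Ca <-> CamC.Ca2", 0.006, 9.1)
  expect_equal(ch$consume[ch$type == "fwd"][[1]], c(Cam = 1L, Ca = 2L))
  expect_equal(ch$produce[ch$type == "back"][[1]], c(Cam = 1L, Ca = 2L))

  expect_error(expandReactionRow("Ca ~ PMCA", 1), "unparseable")
  expect_error(expandReactionRow("A + B <-> C", 1, 2, kcat = 3), "intermediate")
})

test_that("the full network carries the published totals and zero-default ICs", {
  net <- buildNetwork()
  ic <- setNames(net@species$init_nM, net@species$name)
  cam <- c("Cam", "CamC.Ca2", "CamN.Ca2", "Cam.Ca4")
  expect_equal(sum(ic[cam]), 8060)
  expect_equal(sum(ic[c("PKC", "PKC.Ca", "PKC.active")]), 15000)
  expect_equal(ic[["DAG"]], 0)
  expect_equal(ic[["Ca"]], 51)
  expect_equal(ic[["CaExt"]], 2015100)
  tot <- moietyTotals(net)
  expect_equal(tot[["calmodulin"]], 8060)
  expect_equal(tot[["pkc"]], 15000)
  expect_equal(tot[["dagl"]], 1700)
})

test_that("every declared moiety is invariant under every channel", {
  net <- buildNetwork(networkConfig(bapta_nM = 10000))
  S <- stoichiometryMatrix(net)
  for (nm in names(moieties(net))) {
    m <- moieties(net)[[nm]]
    w <- setNames(numeric(nrow(net@species)), net@species$name)
    w[names(m)] <- m
    expect_true(all(abs(drop(w %*% S)) == 0), label = paste("moiety", nm))
  }
})

test_that("regenerating the rate table from the channels reproduces kf/kb/kcat", {
  tab <- reactionTable()
  net <- buildNetwork()
  ch <- channels(net)
  for (i in seq_len(nrow(tab))) {
    sub <- ch[ch$row_id == tab$row[i], ]
    kf <- sub$k[sub$type %in% c("bind", "fwd", "uni")]
    expect_equal(kf, tab$kf[i], label = tab$row[i])
    if (!is.na(tab$kb[i]))
      expect_equal(sub$k[sub$type %in% c("unbind", "back")], tab$kb[i])
    if (!is.na(tab$kcat[i]))
      expect_equal(sub$k[sub$type == "cat"], tab$kcat[i])
  }
})

test_that("propensities follow mass action with the nM conversion", {
  rows <- reactionRows(list("A <-> B", 5))
  m <- miniModel(rows, miniSpecies(c("A", "B")))
  ch <- channels(m)[1, ]
  expect_equal(propensity(ch, c(A = 100, B = 0), 1e-15), 500)
  expect_equal(propensity(ch, c(A = 0, B = 0), 1e-15), 0)

  rows <- reactionRows(list("A + B <-> C", 0.0025, 1.5))
  m <- miniModel(rows, miniSpecies(c("A", "B", "C")))
  bind <- channels(m)[1, ]
  a <- propensity(bind, c(A = 10, B = 10, C = 0), 7.84e-18)
  expect_equal(a, 0.0025 / (6.02214076e23 * 7.84e-18 * 1e-9) * 100,
               tolerance = 1e-10)
  expect_equal(round(a, 2), 52.95, tolerance = 0.02)
  expect_equal(propensity(bind, c(A = 10, B = 0, C = 0), 7.84e-18), 0)
  expect_error(propensity(bind, c(A = -1, B = 2, C = 0), 1e-15), "negative")
})

test_that("propensity is homogeneous of the reaction order", {
  rows <- reactionRows(list("A + B <-> C", 0.01, 1), list("C <-> A + B", 2))
  m <- miniModel(rows, miniSpecies(c("A", "B", "C")))
  ch <- channels(m)
  for (counts in list(c(A = 5, B = 7, C = 3), c(A = 20, B = 1, C = 9))) {
    double <- counts * 2
    for (j in seq_len(nrow(ch))) {
      a1 <- propensity(ch[j, ], counts, 1e-16)
      a2 <- propensity(ch[j, ], double, 1e-16)
      expect_equal(a2 / a1, if (ch$order[j] == 2) 4 else 2)
    }
  }
})

test_that("leak calibration balances pump efflux at resting calcium", {
  leak <- calibrateLeak(12000, 7000)
  occ <- function(kf, kb, kcat, s) kf * s / (kf * s + kb + kcat)
  influx <- leak * 1.1 * occ(0.0015, 1.1, 1.1, 2015100)
  efflux <- 12000 * 3.5 * occ(0.05, 7, 3.5, 51) +
    7000 * 5.6 * occ(0.0168, 11.2, 5.6, 51)
  expect_equal(influx, efflux, tolerance = 1e-10)
})

test_that("rate multipliers target single rows", {
  tab0 <- reactionTable()
  tab <- reactionTable(c("2AG degradation.kf" = 0.5))
  i <- which(tab$desc == "2AG degradation")
  expect_equal(tab$kf[i], tab0$kf[i] * 0.5)
  expect_equal(tab$kf[-i], tab0$kf[-i])
  expect_error(reactionTable(c("no such row.kf" = 2)), "unknown row")
})
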