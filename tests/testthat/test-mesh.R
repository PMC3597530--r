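test_that("the single-spine mesh reproduces the reference geometry", {
  mesh <- buildSingleSpineMesh()
  sv <- subvolumes(mesh)
  dend <- sv[is.na(sv$spine), ]
  expect_equal(nrow(dend), 14 * 7)
  # two outer layers along each edge define the submembrane ring
  expect_equal(sum(dend$region == "dendrite_sub"), 2 * 14 + 2 * 7 - 4)
  spine <- sv[!is.na(sv$spine), ]
  expect_equal(sum(spine$region == "spine_neck"), 3)   # 0.3 um at 0.1 um
  expect_equal(sum(spine$region %in% c("spine_head", "psd")), 6)  # 0.6 um
  expect_equal(sum(spine$region == "psd"), 1)
  # PSD is the distal slice
  expect_equal(sv$region[which.max(sv$z)], "psd")
  # total volume ~ dendrite box + spine cylinders
  vol <- 2 * 1 * 0.6 + pi * 0.1^2 * 0.3 + pi * 0.3^2 * 0.6
  expect_equal(totalVolume(mesh), vol, tolerance = 0.01)
  expect_error(buildSingleSpineMesh(meshConfig(width = 0.5)), "wider")
})

test_that("multi-spine placement is reproducible and density-driven", {
  cfg <- meshConfig(length = 20, width = 1, n_spines = 13, scaled = TRUE)
  m1 <- buildMultiSpineMesh(cfg, seed = 5)
  m2 <- buildMultiSpineMesh(cfg, seed = 5)
  expect_identical(subvolumes(m1), subvolumes(m2))
  sv <- subvolumes(m1)
  expect_equal(max(sv$spine, na.rm = TRUE), 13)
  # spine indices ordered along the dendrite
  att <- vapply(1:13, function(s) min(sv$x[!is.na(sv$spine) & sv$spine == s]),
                numeric(1))
  expect_true(all(diff(att) > 0))
  # density default rounds to 0.8 spines/um x 20 um = 16
  m3 <- buildMultiSpineMesh(meshConfig(length = 20, scaled = TRUE), seed = 1)
  expect_equal(max(subvolumes(m3)$spine, na.rm = TRUE), 16)
  # zero spines
  m0 <- buildMultiSpineMesh(meshConfig(length = 20, n_spines = 0, scaled = TRUE))
  expect_true(all(is.na(subvolumes(m0)$spine)))
})

test_that("diffusive coupling rates follow D*A/(V*d) and detailed balance", {
  mesh <- boxMesh(2, side = 0.14)
  expect_equal(couplingRate(mesh, 1, 2, 174.3), 174.3 / 0.14^2,
               tolerance = 1e-12)
  expect_equal(couplingRate(mesh, 1, 2, 174.3), 8892.86, tolerance = 1e-4)
  expect_equal(couplingRate(mesh, 1, 2, 0), 0)
  expect_error(couplingRate(mesh, 1, 2, -1), "negative")
  # non-adjacent pair on a larger mesh
  big <- buildSingleSpineMesh(meshConfig(scaled = TRUE))
  sv <- subvolumes(big)
  far <- order(sv$x)[c(1, nrow(sv) - 9)]
  expect_equal(couplingRate(big, sv$id[far[1]], sv$id[far[2]], 100), 0)
  # detailed balance across a volume jump (dendrite column <-> spine neck)
  ad <- adjacency(big)
  neck <- sv$id[sv$region == "spine_neck"][1]
  dcol <- ad$j[ad$i == neck & ad$j %in% sv$id[is.na(sv$spine)]][1]
  r12 <- couplingRate(big, dcol, neck, 10)
  r21 <- couplingRate(big, neck, dcol, 10)
  v <- function(id) sv$volume[sv$id == id]
  expect_equal(r12 * v(dcol), r21 * v(neck), tolerance = 1e-12)
})

test_that("initial placement matches expectation and localization rules", {
  net <- buildNetwork()
  mesh <- buildSingleSpineMesh()
  X <- placeInitialMolecules(mesh, net, seed = 42)
  sv <- subvolumes(mesh)
  vtot_L <- totalVolume(mesh) * 1e-15
  NA_ <- 6.02214076e23
  # whole-mesh counts match the whole-cell expectation within rounding
  for (spn in c("Ca", "Calbindin", "PKC")) {
    expected <- net@species$init_nM[net@species$name == spn] * 1e-9 * NA_ * vtot_L
    expect_lt(abs(sum(X[spn, ]) - expected), 3 * sqrt(expected) + 2)
  }
  # free calcium: 51 nM over ~1.38 um^3 is only ~42 molecules
  expect_lt(abs(sum(X["Ca", ]) - 42.3), 25)
  # membrane species only on membrane subvolumes
  expect_true(all(X["DAGL", sv$area == 0] == 0))
  expect_true(all(X["mGluR", sv$region == "dendrite_cyt"] == 0))
  # NCX excluded from the spine head
  expect_true(all(X["NCX", sv$region %in% c("spine_head", "psd")] == 0))
  expect_gt(sum(X["NCX", sv$region == "spine_neck"]), 0)
  # round-trip: whole-cytosol concentration recovers the initial value
  conc <- countsToConcentration(sum(X["Calbindin", ]), vtot_L)
  expect_equal(conc, 153290, tolerance = 0.01)
})

test_that("stochastic rounding has exact expectation", {
  net <- buildNetwork()
  mesh <- buildSingleSpineMesh(meshConfig(scaled = TRUE))
  tot <- vapply(1:40, function(s)
    sum(placeInitialMolecules(mesh, net, seed = s)["Ca", ]), numeric(1))
  vtot_L <- totalVolume(mesh) * 1e-15
  expected <- 51e-9 * 6.02214076e23 * vtot_L
  expect_lt(abs(mean(tot) - expected) / sqrt(var(tot) / 40), 4)
})

test_that("surface densities are consistent with pools and areas", {
  net <- buildNetwork()
  mesh <- buildSingleSpineMesh()
  sv <- subvolumes(mesh)
  sd_dagl <- surfaceDensity(mesh, net, "DAGL")
  area_m2 <- sum(sv$area[sv$region %in% c("dendrite_sub", "spine_head", "psd")]) * 1e-12
  mol <- 1700e-9 * totalVolume(mesh) * 1e-15 * 6.02214076e23
  expect_equal(sd_dagl, mol / 6.02214076e23 / area_m2 * 1e12)
  expect_error(surfaceDensity(mesh, net, "Ca"), "not membrane")
})

test_that("mesh text export round-trips", {
  mesh <- buildSingleSpineMesh(meshConfig(scaled = TRUE))
  pre <- file.path(tempdir(), "mesh_test")
  exportMesh(mesh, pre)
  back <- importMesh(pre)
  expect_equal(subvolumes(back), subvolumes(mesh), tolerance = 1e-12)
  expect_equal(adjacency(back), adjacency(mesh), tolerance = 1e-12)
})
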