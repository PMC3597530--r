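# Tiny fixture networks with closed-form behavior, used to validate the
# stochastic engine (ensemble means vs analytic / ODE expectations) in
# seconds. Tolerances are z-scores against the analytically known
# Monte-Carlo variance rather than hard-coded absolute bounds.

# build a minimal NetworkModel from reaction rows and explicit species
.miniModel <- function(rows, species) {
  ch <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
    expandReactionRow(rows$row[i], rows$kf[i], rows$kb[i], rows$kcat[i],
                      rows$desc[i])))
  if (is.null(ch)) ch <- expandReactionRow(rows$row[1], rows$kf[1])[0, ]
  new("NetworkModel", species = species, channels = ch,
      moieties = list(), config = list())
}

.miniSpecies <- function(names, init = 0, D = 0) {
  data.frame(name = names,
             compartment = "cytosol",
             init_nM = rep_len(init, length(names)),
             D = rep_len(D, length(names)),
             localization = I(rep(list("box"), length(names))),
             stringsAsFactors = FALSE)
}

#' A one- or two-box test mesh
#'
#' @param n_box 1 or 2 equal cubic boxes.
#' @param side box side length (um).
#' @return a \code{\linkS4class{Mesh}} with region label "box" (one box)
#'   or "box1"/"box2" (two boxes, so each box is its own recording group).
#' @export
boxMesh <- function(n_box = 1, side = 0.5) {
  sv <- data.frame(id = seq_len(n_box),
                   x = (seq_len(n_box) - 0.5) * side, y = side / 2, z = side / 2,
                   volume = side^3, area = 0,
                   region = if (n_box == 1) "box"
                            else paste0("box", seq_len(n_box)),
                   spine = NA_integer_, stringsAsFactors = FALSE)
  ad <- if (n_box == 2)
    data.frame(i = c(1L, 2L), j = c(2L, 1L), area = side^2, dist = side)
  else data.frame(i = integer(), j = integer(), area = numeric(),
                  dist = numeric())
  new("Mesh", subvolumes = sv, adjacency = ad, config = list(side = side))
}

#' Build a named engine-validation fixture
#'
#' Available fixtures: \describe{
#'   \item{decay}{A -> B at k = 10/s (the IP3 degradation rate); mean
#'     N_A(t) = N0 exp(-k t).}
#'   \item{reversible_binding}{A + B <-> C with kf 0.028 nM^-1 s^-1,
#'     kb 19.6/s (the calbindin rates); equilibrium from Kd = kb/kf.}
#'   \item{two_box_diffusion}{one diffusible species, all molecules start
#'     in box 1 of two equal boxes; long-time split 50/50.}
#'   \item{enzyme_mm}{S + E <-> ES => E + P; mean compared to the ODE
#'     oracle.}
#'   \item{conservation_full_network}{the full signaling network on the
#'     coarse single-spine mesh; every moiety total must be exactly
#'     invariant.}
#' }
#'
#' @param name fixture name.
#' @return list with \code{model}, \code{mesh}, \code{expectation}
#'   (function(t) -> named means, nM or counts as documented), and
#'   \code{tol_policy} ("z" or "exact").
#' @export
makeFixture <- function(name) {
  side <- 0.5
  V <- side^3 * 1e-15
  nM1 <- countsToConcentration(1, V)
  switch(name,
    decay = {
      rows <- data.frame(row = "A <-> B", kf = 10, kb = NA, kcat = NA,
                         desc = "decay")
      sp <- .miniSpecies(c("A", "B"), init = c(1000 * nM1, 0))
      list(model = .miniModel(rows, sp), mesh = boxMesh(1, side),
           n0 = 1000,
           expectation = function(t) c(A = 1000 * exp(-10 * t)),
           tol_policy = "z")
    },
    reversible_binding = {
      rows <- data.frame(row = "A + B <-> C", kf = 0.028, kb = 19.6,
                         kcat = NA, desc = "binding")
      a0 <- 2000; b0 <- 3000
      sp <- .miniSpecies(c("A", "B", "C"), init = c(a0 * nM1, b0 * nM1, 0))
      Kd_counts <- 19.6 / (0.028 * nM1)    # Kd expressed in molecules
      # equilibrium from the quadratic for complex count c:
      # (a0-c)(b0-c) = Kd * c
      cc <- {
        b <- -(a0 + b0 + Kd_counts)
        (-b - sqrt(b^2 - 4 * a0 * b0)) / 2
      }
      list(model = .miniModel(rows, sp), mesh = boxMesh(1, side),
           expectation = function(t) c(A = a0 - cc, B = b0 - cc, C = cc),
           tol_policy = "z")
    },
    two_box_diffusion = {
      rows <- data.frame(row = "A <-> B", kf = 0, kb = NA, kcat = NA,
                         desc = "none")
      sp <- .miniSpecies(c("A", "B"), init = 0, D = c(100, 0))
      list(model = .miniModel(rows, sp), mesh = boxMesh(2, side),
           n0 = 1000,
           expectation = function(t) c(box1 = 500, box2 = 500),
           tol_policy = "z")
    },
    enzyme_mm = {
      rows <- data.frame(row = "S + E <-> ES => E + P", kf = 0.0025,
                         kb = 1.5, kcat = 1, desc = "mm")
      sp <- .miniSpecies(c("S", "E", "ES", "P"),
                         init = c(5000 * nM1, 500 * nM1, 0, 0))
      list(model = .miniModel(rows, sp), mesh = boxMesh(1, side),
           expectation = NULL,   # compared to the ODE oracle
           tol_policy = "z")
    },
    conservation_full_network = {
      list(model = buildNetwork(), mesh = buildSingleSpineMesh(meshConfig(scaled = TRUE)),
           expectation = NULL, tol_policy = "exact")
    },
    stop("unknown fixture: ", name)
  )
}

#' Check a fixture against its closed-form expectation
#'
#' Stochastic fixtures: z-test of the ensemble mean against the
#' expectation at several checkpoints (|z| below the threshold at every
#' checkpoint). Conservation fixtures: exact equality of every moiety
#' total along the trajectory, zero tolerance.
#'
#' @param name fixture name (see \code{\link{makeFixture}}).
#' @param n_replicates ensemble size for stochastic fixtures.
#' @param seed base seed (replicate i uses seed + i).
#' @param z_max z-score threshold.
#' @return list with \code{pass} (logical), \code{detail} (data.frame of
#'   checkpoint statistics), \code{name}.
#' @export
checkFixture <- function(name, n_replicates = 200, seed = 1L, z_max = 4) {
  fx <- makeFixture(name)
  if (name == "decay") {
    k <- 10; n0 <- fx$n0
    cps <- c(0.02, 0.05, 0.1, 0.15, 0.23)
    cfg <- engineConfig(dt = 1e-4, record_dt = 0.01, t_end = 0.25)
    M <- vapply(seq_len(n_replicates), function(i) {
      X <- matrix(c(n0, 0L), ncol = 1,
                  dimnames = list(c("A", "B"), NULL))
      storage.mode(X) <- "integer"
      tr <- runSim(fx$model, fx$mesh, NULL,
                   utils::modifyList(cfg, list(seed = seed + i)), counts = X)
      idx <- vapply(cps, function(tt) which.min(abs(tr@times - tt)), 1L)
      tr@counts[1, "A", idx]
    }, numeric(length(cps)))
    mu <- n0 * exp(-k * cps)
    va <- n0 * exp(-k * cps) * (1 - exp(-k * cps))   # binomial survival
    z <- (rowMeans(M) - mu) / sqrt(va / n_replicates)
    detail <- data.frame(checkpoint = cps, expected = mu,
                         observed = rowMeans(M), z = z)
    return(list(name = name, pass = all(abs(z) < z_max), detail = detail))
  }
  if (name == "two_box_diffusion") {
    n0 <- fx$n0
    cfg <- engineConfig(dt = 1e-4, record_dt = 0.05, t_end = 0.5)
    # relaxation rate 2*D*A/(V*d) >> 1/t_end, so endpoints are equilibrated
    M <- vapply(seq_len(n_replicates), function(i) {
      X <- matrix(c(n0, 0L, 0L, 0L), nrow = 2,
                  dimnames = list(c("A", "B"), NULL))
      storage.mode(X) <- "integer"
      tr <- runSim(fx$model, fx$mesh, NULL,
                   utils::modifyList(cfg, list(seed = seed + i)), counts = X)
      tr@counts[1, "A", length(tr@times)]
    }, numeric(1))
    mu <- n0 / 2; va <- n0 / 4    # Binomial(n0, 1/2)
    z <- (mean(M) - mu) / sqrt(va / n_replicates)
    detail <- data.frame(checkpoint = 0.5, expected = mu, observed = mean(M),
                         z = z)
    return(list(name = name, pass = abs(z) < z_max, detail = detail))
  }
  if (name %in% c("reversible_binding", "enzyme_mm")) {
    cfg <- engineConfig(dt = 5e-5, record_dt = 0.05,
                        t_end = if (name == "enzyme_mm") 1 else 2)
    cps <- if (name == "enzyme_mm") c(0.2, 0.4, 0.6, 0.8, 1) else
      c(1.2, 1.4, 1.6, 1.8, 2)
    watch <- if (name == "enzyme_mm") "P" else "C"
    trs <- lapply(seq_len(n_replicates), function(i)
      runSim(fx$model, fx$mesh, NULL,
             utils::modifyList(cfg, list(seed = seed + i))))
    idx <- vapply(cps, function(tt) which.min(abs(trs[[1]]@times - tt)), 1L)
    M <- vapply(trs, function(tr) tr@counts[1, watch, idx],
                numeric(length(cps)))
    M <- matrix(M, nrow = length(cps))
    if (name == "enzyme_mm") {
      ode <- solveReferenceOde(fx$model, times = seq(0, 1, by = 0.01))
      V <- fx$mesh@subvolumes$volume * 1e-15
      mu <- approx(ode$time, ode[[watch]], cps)$y / countsToConcentration(1, V)
    } else {
      mu <- rep(fx$expectation(0)[[watch]], length(cps))
    }
    se <- apply(M, 1, sd) / sqrt(n_replicates)
    z <- (rowMeans(M) - mu) / pmax(se, 1e-9)
    detail <- data.frame(checkpoint = cps, expected = mu,
                         observed = rowMeans(M), z = z)
    return(list(name = name, pass = all(abs(z) < z_max), detail = detail))
  }
  if (name == "conservation_full_network") {
    cfg <- engineConfig(dt = 5e-5, record_dt = 0.1, t_end = 1, seed = seed)
    tr <- runSim(fx$model, fx$mesh, NULL, cfg)
    mo <- fx$model@moieties
    dev <- vapply(names(mo), function(nm) {
      m <- mo[[nm]]
      tot <- colSums(apply(tr@counts[, names(m), , drop = FALSE], c(2, 3), sum) * m)
      max(abs(tot - tot[1]))
    }, numeric(1))
    detail <- data.frame(moiety = names(mo), max_deviation = dev)
    return(list(name = name, pass = all(dev == 0), detail = detail))
  }
  stop("unknown fixture: ", name)
}

#' Run the whole fixture suite
#'
#' @param seed base seed.
#' @param n_replicates ensemble size for the stochastic fixtures.
#' @return data.frame with one row per fixture and a pass flag.
#' @export
validateEngine <- function(seed = 1L, n_replicates = 150) {
  nms <- c("decay", "reversible_binding", "two_box_diffusion", "enzyme_mm",
           "conservation_full_network")
  res <- lapply(nms, function(nm)
    checkFixture(nm, n_replicates = n_replicates, seed = seed))
  data.frame(fixture = nms,
             pass = vapply(res, `[[`, logical(1), "pass"),
             max_abs_z = vapply(res, function(r)
               if ("z" %in% names(r$detail)) max(abs(r$detail$z)) else NA_real_,
               numeric(1)))
}
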