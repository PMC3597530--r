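# R-side driver of the spatial tau-leap core: state preparation, event
# resolution, recording groups and the deterministic well-mixed ODE oracle.

#' Engine configuration
#'
#' @param dt tau-leap time step (s). The reference value is 2.5e-6 s;
#'   desk-scale suite runs use a coarser step together with the coarse
#'   mesh (see the vignette for the accuracy argument).
#' @param record_dt recording interval (s); rounded to a multiple of dt.
#' @param t_end end time (s).
#' @param seed RNG seed for the run (placement and dynamics).
#' @return list of engine settings.
#' @export
engineConfig <- function(dt = 2.5e-6, record_dt = 0.05, t_end = 1, seed = 1L) {
  stopifnot(dt > 0, record_dt >= dt, t_end > 0)
  list(dt = dt, record_dt = record_dt, t_end = t_end, seed = as.integer(seed))
}

# order the reactant pair so the typically rarer species is tested first
# (cheap zero-count skip in the core)
.prepChannels <- function(model) {
  ch <- model@channels
  sp <- model@species
  common <- c("Ca", "CaExt", "Calbindin", "Calbindin.Ca", "GluInact", "PKC",
              "Cam")
  abun <- setNames(sp$init_nM + ifelse(sp$name %in% common, 1e9, 0), sp$name)
  idx <- function(nm) match(nm, sp$name) - 1L
  np <- integer(nrow(ch)); r1 <- integer(nrow(ch)); r2 <- integer(nrow(ch))
  st_sp <- integer(0); st_d <- integer(0); st_ptr <- 0L
  cn_sp <- integer(0); cn_n <- integer(0); cn_ptr <- 0L
  for (j in seq_len(nrow(ch))) {
    cons <- ch$consume[[j]]; prod <- ch$produce[[j]]
    rs <- names(cons)
    np[j] <- length(rs)
    if (np[j] == 2 && abun[rs[1]] > abun[rs[2]]) rs <- rev(rs)
    r1[j] <- idx(rs[1])
    r2[j] <- if (np[j] == 2) idx(rs[2]) else 0L
    delta <- setNames(numeric(0), character(0))
    for (nm in names(cons)) delta[nm] <- -cons[[nm]]
    for (nm in names(prod)) delta[nm] <- (if (nm %in% names(delta)) delta[nm] else 0) + prod[[nm]]
    delta <- delta[delta != 0]
    st_sp <- c(st_sp, idx(names(delta))); st_d <- c(st_d, as.integer(delta))
    st_ptr <- c(st_ptr, length(st_sp))
    cn_sp <- c(cn_sp, idx(names(cons))); cn_n <- c(cn_n, as.integer(cons))
    cn_ptr <- c(cn_ptr, length(cn_sp))
  }
  list(np = np, r1 = r1, r2 = r2, k = ch$k,
       st_ptr = as.integer(st_ptr), st_sp = st_sp, st_d = st_d,
       cn_ptr = as.integer(cn_ptr), cn_sp = cn_sp, cn_n = cn_n)
}

# adjacency in CSR form with geometric factors A/(V_i*d)
.prepDiffusion <- function(model, mesh) {
  sv <- mesh@subvolumes
  ad <- mesh@adjacency
  n <- nrow(sv)
  ord <- order(ad$i, ad$j)
  ad <- ad[ord, ]
  g <- ad$area / (sv$volume[match(ad$i, sv$id)] * ad$dist)
  nb_ptr <- c(0L, cumsum(tabulate(match(ad$i, sv$id), nbins = n)))
  dif <- which(model@species$D > 0)
  list(diff_sp = dif - 1L, diff_D = model@species$D[dif],
       nb_ptr = as.integer(nb_ptr),
       nb_idx = match(ad$j, sv$id) - 1L, nb_g = g)
}

# map an event target string to subvolume indices and weights
.resolveTarget <- function(mesh, target, kind, conv) {
  sv <- mesh@subvolumes
  if (target == "all") {
    ids <- seq_len(nrow(sv)); w <- sv$volume
  } else {
    parts <- strsplit(target, ":", fixed = TRUE)[[1]]
    sel <- sv$region == parts[1]
    if (length(parts) > 1) sel <- sel & !is.na(sv$spine) &
        sv$spine == as.integer(parts[2])
    if (!any(sel)) stop("event targets a region absent from the mesh: ", target)
    ids <- which(sel)
    w <- if (kind == "add" && all(sv$area[ids] > 0)) sv$area[ids] else sv$volume[ids]
  }
  list(sub = ids - 1L, w = w / sum(w))
}

.prepEvents <- function(mesh, schedule, conv) {
  ev <- schedule@events
  n <- nrow(ev)
  kind <- integer(n); r0 <- numeric(n); tau <- numeric(n)
  ptr <- 0L; sub <- integer(0); wout <- numeric(0)
  for (i in seq_len(n)) {
    tg <- .resolveTarget(mesh, ev$target[i], ev$kind[i], conv)
    if (ev$kind[i] == "add") {
      kind[i] <- 0L
      d <- ev$duration[i]
      tau[i] <- ifelse(is.na(ev$tau[i]), -1, ev$tau[i])
      r0[i] <- if (tau[i] > 0) ev$total[i] / (tau[i] * (1 - exp(-d / tau[i])))
               else ev$total[i] / d
      wout <- c(wout, tg$w)
    } else {
      kind[i] <- 1L
      # clamp: per-subvolume counts realizing clamp_nM
      wout <- c(wout, round(ev$clamp_nM[i] / conv[tg$sub + 1L]))
    }
    sub <- c(sub, tg$sub)
    ptr <- c(ptr, length(sub))
  }
  list(kind = kind, sp = match(ev$species, character(0)),  # filled by caller
       species = ev$species,
       t0 = ev$onset, t1 = ev$onset + ev$duration,
       r0 = r0, tau = tau, ptr = as.integer(ptr), sub = sub, w = wout)
}

# recording groups: dendrite regions plus per-spine region groups
.makeGroups <- function(mesh) {
  sv <- mesh@subvolumes
  key <- ifelse(is.na(sv$spine), sv$region, paste0(sv$region, ":", sv$spine))
  nm <- unique(key)
  gid <- match(key, nm) - 1L
  vol <- vapply(nm, function(k) sum(sv$volume[key == k]), numeric(1)) * 1e-15
  reg <- sv$region[match(nm, key)]
  spn <- sv$spine[match(nm, key)]
  list(gid = gid,
       groups = data.frame(name = nm, region = reg, spine = spn,
                           volume = vol,
                           n_sub = as.vector(table(factor(key, levels = nm))),
                           stringsAsFactors = FALSE))
}

#' Run a stochastic reaction-diffusion simulation
#'
#' Places the initial molecules, resolves the stimulus events onto the
#' mesh, and advances the state with the fixed-step spatial tau-leap
#' method, recording group-aggregated counts on the recording grid.
#' Identical (model, mesh, schedule, config) including the seed give a
#' bitwise-identical trajectory.
#'
#' @param model a \code{\linkS4class{NetworkModel}}.
#' @param mesh a \code{\linkS4class{Mesh}}.
#' @param schedule a \code{\linkS4class{StimulusSchedule}} (or NULL for an
#'   unstimulated run).
#' @param config an \code{\link{engineConfig}} list.
#' @param counts optional initial counts matrix (species x subvolumes);
#'   by default \code{\link{placeInitialMolecules}} under the run seed.
#' @return a \code{\linkS4class{Trajectory}}.
#' @export
runSim <- function(model, mesh, schedule = NULL, config = engineConfig(),
                   counts = NULL) {
  sv <- mesh@subvolumes
  spn <- model@species$name
  if (is.null(counts)) counts <- placeInitialMolecules(mesh, model, config$seed)
  stopifnot(nrow(counts) == length(spn), ncol(counts) == nrow(sv))
  conv <- 1e9 / (AVOGADRO * sv$volume * 1e-15)   # nM per molecule
  chp <- .prepChannels(model)
  dfp <- .prepDiffusion(model, mesh)
  if (is.null(schedule)) schedule <- new("StimulusSchedule",
    events = data.frame(species = character(), target = character(),
                        kind = character(), onset = numeric(),
                        duration = numeric(), total = numeric(),
                        tau = numeric(), clamp_nM = numeric()),
    protocol = "none", params = list())
  evp <- .prepEvents(mesh, schedule, conv)
  ev_sp <- match(evp$species, spn) - 1L
  if (length(ev_sp) && anyNA(ev_sp)) stop("event species not in the model")
  grp <- .makeGroups(mesh)
  record_every <- max(1L, round(config$record_dt / config$dt))
  nsteps <- ceiling(config$t_end / config$dt)
  nsteps <- as.integer(ceiling(nsteps / record_every) * record_every)
  out <- .simCore(counts, conv,
                  chp$np, chp$r1, chp$r2, chp$k,
                  chp$st_ptr, chp$st_sp, chp$st_d,
                  chp$cn_ptr, chp$cn_sp, chp$cn_n,
                  dfp$diff_sp, dfp$diff_D, dfp$nb_ptr, dfp$nb_idx, dfp$nb_g,
                  evp$kind, ev_sp, evp$t0, evp$t1, evp$r0, evp$tau,
                  evp$ptr, evp$sub, evp$w,
                  config$dt, nsteps, record_every,
                  grp$gid, nrow(grp$groups),
                  as.double(config$seed) + 715827883)
  nrec <- out$nrec
  arr <- array(out$rec[seq_len(nrow(grp$groups) * length(spn) * nrec)],
               dim = c(nrow(grp$groups), length(spn), nrec),
               dimnames = list(grp$groups$name, spn, NULL))
  times <- seq(0, by = config$dt * record_every, length.out = nrec)
  new("Trajectory", times = times, counts = arr, groups = grp$groups,
      species = spn, seed = as.integer(config$seed), config = config,
      corrections = out$corrections)
}

#' Deterministic well-mixed mass-action oracle
#'
#' Integrates the macroscopic rate equations of the expanded channel list
#' in a single well-mixed compartment (stiff solver). Used to validate
#' ensemble means of the stochastic engine on fixture networks.
#'
#' @param model a NetworkModel.
#' @param init_nM named initial concentrations (defaults to the model's).
#' @param times output times (s).
#' @return data.frame: time plus one concentration column per species (nM).
#' @export
solveReferenceOde <- function(model, init_nM = NULL,
                              times = seq(0, 1, by = 0.01)) {
  sp <- model@species$name
  y0 <- setNames(model@species$init_nM, sp)
  if (!is.null(init_nM)) y0[names(init_nM)] <- init_nM
  S <- stoichiometryMatrix(model)
  ch <- model@channels
  r1 <- match(vapply(ch$consume, function(x) names(x)[1], character(1)), sp)
  r2i <- vapply(ch$consume, function(x)
    if (length(x) > 1) names(x)[2] else NA_character_, character(1))
  r2 <- match(r2i, sp)
  k <- ch$k
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- k * y[r1]
    two <- !is.na(r2)
    v[two] <- v[two] * y[r2[two]]
    list(drop(S %*% v))
  }
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-6)
  as.data.frame(out)
}
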