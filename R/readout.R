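# Trajectory readouts: regional concentration time series, cross-trial
# statistics, DHPG enhancement ratios and the PKC:2AG plasticity index.

#' Convert a molecule count to a concentration
#'
#' nM = count / (N_Avogadro * V) * 1e9.
#'
#' @param count molecule count.
#' @param volume volume in liters.
#' @return concentration in nM.
#' @examples
#' countsToConcentration(1, 7.84e-18)  # ~211.9 nM
#' @export
countsToConcentration <- function(count, volume) {
  if (any(volume <= 0)) stop("non-positive volume")
  count / (AVOGADRO * volume) * 1e9
}

# select recording groups for a region spec:
# "spine_head", "psd", ... | "spine:3" (head+psd of spine 3) |
# "spine" (all spine head+psd) | "all"
.groupSel <- function(groups, region) {
  if (region == "all") return(seq_len(nrow(groups)))
  parts <- strsplit(region, ":", fixed = TRUE)[[1]]
  if (parts[1] == "spine") {
    sel <- groups$region %in% c("spine_head", "psd")
    if (length(parts) > 1) sel <- sel & !is.na(groups$spine) &
        groups$spine == as.integer(parts[2])
  } else {
    sel <- groups$region == parts[1]
    if (length(parts) > 1) sel <- sel & !is.na(groups$spine) &
        groups$spine == as.integer(parts[2])
  }
  if (!any(sel)) stop("unknown region: ", region)
  which(sel)
}

#' Volume-weighted regional concentration time series
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param region region name ("dendrite_sub", "spine_head", "psd", ...),
#'   "spine:i" for the head+PSD of spine i, "spine" for all spine
#'   head+PSD volume, or "all" for the whole morphology.
#' @param species species name or vector of names (summed; e.g.
#'   \code{c("DAG.Ca.DAGL")} or several complexes).
#' @return data.frame with columns \code{time}, \code{count},
#'   \code{conc_nM} and attributes region/species/seed.
#' @export
regionSummary <- function(traj, region, species) {
  gsel <- .groupSel(traj@groups, region)
  ssel <- match(species, traj@species)
  if (anyNA(ssel)) stop("unknown species: ",
                        paste(species[is.na(ssel)], collapse = ", "))
  cnt <- apply(traj@counts[gsel, ssel, , drop = FALSE], 3, sum)
  vol <- sum(traj@groups$volume[gsel])
  out <- data.frame(time = traj@times, count = cnt,
                    conc_nM = countsToConcentration(cnt, vol))
  attr(out, "region") <- region
  attr(out, "species") <- paste(species, collapse = "+")
  attr(out, "seed") <- traj@seed
  out
}

#' Pointwise ensemble statistics across trials
#'
#' @param trials list of regionSummary data.frames on identical time grids
#'   (one per seed).
#' @return data.frame with \code{time}, \code{mean}, \code{sd}, \code{sem}
#'   (sd/sem NA for a single trial) of the concentration.
#' @export
ensembleStats <- function(trials) {
  if (!length(trials)) stop("no trials")
  tm <- trials[[1]]$time
  for (tr in trials) if (!isTRUE(all.equal(tr$time, tm)))
    stop("mismatched time grids")
  M <- vapply(trials, function(tr) tr$conc_nM, numeric(length(tm)))
  M <- matrix(M, nrow = length(tm))
  n <- ncol(M)
  data.frame(time = tm, mean = rowMeans(M),
             sd = if (n > 1) apply(M, 1, sd) else NA_real_,
             sem = if (n > 1) apply(M, 1, sd) / sqrt(n) else NA_real_,
             n = n)
}

# boxcar smoothing for peak statistics (avoids single-sample Poisson spikes)
.smooth <- function(x, time, width) {
  if (width <= 0 || length(x) < 3) return(x)
  k <- max(1L, round(width / mean(diff(time))))
  if (k <= 1) return(x)
  stats::filter(x, rep(1 / k, k), sides = 2) |>
    (\(f) { f[is.na(f)] <- x[is.na(f)]; as.numeric(f) })()
}

#' Window statistics of an ensemble-mean series
#'
#' @param ens an \code{\link{ensembleStats}} data.frame.
#' @param window numeric c(start, end) in seconds.
#' @param smooth_width boxcar width (s) applied before the peak statistic.
#' @return list with \code{mean} and \code{peak} over the window.
#' @export
windowStats <- function(ens, window = range(ens$time), smooth_width = 1) {
  sel <- ens$time >= window[1] & ens$time <= window[2]
  if (!any(sel)) stop("empty window")
  sm <- .smooth(ens$mean, ens$time, smooth_width)
  list(mean = mean(ens$mean[sel]), peak = max(sm[sel]))
}

#' DHPG enhancement ratio
#'
#' Ratio of the window-mean 2AG with DHPG to the window-mean without DHPG
#' (trial means), the same normalization used for experimental DSI
#' enhancement.
#'
#' @param with_dhpg,without_dhpg \code{\link{ensembleStats}} data.frames of
#'   the 2AG series with and without mGluR agonist.
#' @param window numeric c(start, end) in seconds covering the response.
#' @return enhancement ratio (1 when the ensembles are identical).
#' @export
enhancementRatio <- function(with_dhpg, without_dhpg,
                             window = range(with_dhpg$time)) {
  sel <- function(e) e$time >= window[1] & e$time <= window[2]
  denom <- mean(without_dhpg$mean[sel(without_dhpg)])
  if (denom <= 0) stop("denominator window-mean is not positive")
  mean(with_dhpg$mean[sel(with_dhpg)]) / denom
}

#' PKC:2AG plasticity index
#'
#' Ratio of mean active PKC to mean 2AG over the stimulation + response
#' window. An index above 2 is read as LTP-like, an index near 1 as
#' LTD-like.
#'
#' @param pkc,ag \code{\link{ensembleStats}} data.frames of active PKC and
#'   2AG for matched regions and windows.
#' @param window numeric c(start, end) seconds.
#' @param baseline optional c(pkc, ag) baseline concentrations subtracted
#'   before forming the ratio (defaults to none).
#' @return the index (scale-equivariant in the PKC series).
#' @export
pkc2agIndex <- function(pkc, ag, window = range(pkc$time), baseline = c(0, 0)) {
  sel <- function(e) e$time >= window[1] & e$time <= window[2]
  num <- mean(pkc$mean[sel(pkc)]) - baseline[1]
  den <- mean(ag$mean[sel(ag)]) - baseline[2]
  if (den <= 0) stop("zero or negative 2AG window mean")
  num / den
}

#' Extract per-seed region series and their ensemble from trajectories
#'
#' Convenience wrapper: regionSummary for each trajectory then
#' ensembleStats.
#'
#' @param trajs list of Trajectory objects (one per seed).
#' @param region,species as in \code{\link{regionSummary}}.
#' @return an \code{\link{ensembleStats}} data.frame.
#' @export
ensembleSeries <- function(trajs, region, species) {
  ensembleStats(lapply(trajs, regionSummary, region = region, species = species))
}

#' Tidy long-format view of a trajectory
#'
#' One row per (time, group, species) with counts and concentrations;
#' suitable for writing as CSV.
#'
#' @param traj a Trajectory.
#' @param species optional subset of species names.
#' @return data.frame with columns time, group, region, spine, species,
#'   count, conc_nM, seed.
#' @export
trajectoryToDataFrame <- function(traj, species = NULL) {
  if (is.null(species)) species <- traj@species
  ssel <- match(species, traj@species)
  if (anyNA(ssel)) stop("unknown species")
  g <- traj@groups
  out <- expand.grid(group = g$name, species = species,
                     time = traj@times, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  cnt <- as.vector(traj@counts[, ssel, , drop = FALSE])
  out$count <- cnt
  gi <- match(out$group, g$name)
  out$region <- g$region[gi]
  out$spine <- g$spine[gi]
  out$conc_nM <- countsToConcentration(out$count, g$volume[gi])
  out$seed <- traj@seed
  out[, c("time", "group", "region", "spine", "species", "count",
          "conc_nM", "seed")]
}
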