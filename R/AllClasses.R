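#' @import methods
#' @importFrom stats rbinom runif sd setNames
#' @importFrom utils head tail
NULL

AVOGADRO <- 6.02214076e23

#' NetworkModel: a mass-action reaction network with spatial metadata
#'
#' Holds the species table (initial concentrations or membrane surface
#' densities, diffusion constants, localization), the expanded elementary
#' reaction channels, and the conserved moieties of the network.
#'
#' @slot species data.frame with columns \code{name}, \code{compartment}
#'   ("cytosol" or "membrane"), \code{init_nM} (whole-cell equivalent
#'   concentration; for membrane species this is converted to a surface
#'   density at placement time), \code{D} (diffusion constant, um^2/s) and
#'   \code{localization} (list column of region names).
#' @slot channels data.frame of elementary channels; see
#'   \code{\link{expandReactionRow}}.
#' @slot moieties named list of conserved moieties; each entry is a named
#'   numeric vector of per-species multiplicities.
#' @slot config list of network configuration values (membrane pools,
#'   rate multipliers, optional exogenous buffer), see
#'   \code{\link{networkConfig}}.
#' @export
setClass("NetworkModel",
  representation(
    species  = "data.frame",
    channels = "data.frame",
    moieties = "list",
    config   = "list"
  )
)

setValidity("NetworkModel", function(object) {
  sp <- object@species
  ch <- object@channels
  msg <- character()
  if (anyDuplicated(sp$name)) msg <- c(msg, "duplicated species names")
  if (any(sp$D < 0)) msg <- c(msg, "negative diffusion constant")
  if (any(sp$init_nM < 0)) msg <- c(msg, "negative initial concentration")
  if (any(lengths(sp$localization) == 0)) msg <- c(msg, "empty localization")
  if (nrow(ch)) {
    refd <- unique(c(unlist(lapply(ch$consume, names)),
                     unlist(lapply(ch$produce, names))))
    if (!all(refd %in% sp$name))
      msg <- c(msg, paste("channel references unknown species:",
                          paste(setdiff(refd, sp$name), collapse = ", ")))
    if (any(ch$k < 0)) msg <- c(msg, "negative rate constant")
    if (!all(ch$order %in% 1:2)) msg <- c(msg, "channel order must be 1 or 2")
  }
  # every declared moiety must be invariant under every channel
  if (length(object@moieties) && nrow(ch)) {
    S <- stoichiometryMatrix(object)
    for (nm in names(object@moieties)) {
      m <- object@moieties[[nm]]
      w <- setNames(numeric(nrow(sp)), sp$name)
      w[names(m)] <- m
      if (any(abs(drop(w %*% S)) > 1e-9))
        msg <- c(msg, paste0("moiety '", nm, "' not conserved"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Mesh: a set of well-mixed subvolumes with diffusive couplings
#'
#' @slot subvolumes data.frame with columns \code{id}, \code{x,y,z} (center,
#'   um), \code{volume} (um^3), \code{area} (membrane area, um^2; 0 for
#'   interior subvolumes), \code{region} (one of dendrite_cyt, dendrite_sub,
#'   spine_head, spine_neck, psd) and \code{spine} (spine index or NA).
#' @slot adjacency data.frame with columns \code{i}, \code{j} (subvolume
#'   ids), \code{area} (shared interface, um^2) and \code{dist} (center
#'   distance, um). Each undirected edge appears in both orientations.
#' @slot config the MeshConfig list used to build the mesh.
#' @export
setClass("Mesh",
  representation(
    subvolumes = "data.frame",
    adjacency  = "data.frame",
    config     = "list"
  )
)

setValidity("Mesh", function(object) {
  sv <- object@subvolumes
  ad <- object@adjacency
  msg <- character()
  if (any(sv$volume <= 0)) msg <- c(msg, "subvolume with non-positive volume")
  if (any(sv$area < 0)) msg <- c(msg, "negative membrane area")
  if (nrow(ad)) {
    if (!all(ad$i %in% sv$id) || !all(ad$j %in% sv$id))
      msg <- c(msg, "adjacency references unknown subvolume")
    key <- paste(ad$i, ad$j); rkey <- paste(ad$j, ad$i)
    if (!all(rkey %in% key)) msg <- c(msg, "adjacency not symmetric")
    if (any(ad$area <= 0) || any(ad$dist <= 0))
      msg <- c(msg, "adjacency with non-positive interface area or distance")
  }
  if (length(msg)) msg else TRUE
})

#' StimulusSchedule: timed molecule injection / clamp events
#'
#' @slot events data.frame with columns \code{species}, \code{target}
#'   (region name, optionally qualified by spine index as in "psd:3", or
#'   "all"), \code{kind} ("add" or "clamp"), \code{onset} (s),
#'   \code{duration} (s), \code{total} (molecules injected over the event,
#'   for "add"), \code{tau} (decay time constant of the injection rate, s;
#'   NA for a constant rate) and \code{clamp_nM} (held concentration, for
#'   "clamp").
#' @slot protocol protocol name ("theta_burst", "twenty_hz", "dsi", ...).
#' @slot params the ProtocolParams list the schedule was generated from.
#' @export
setClass("StimulusSchedule",
  representation(
    events   = "data.frame",
    protocol = "character",
    params   = "list"
  )
)

setValidity("StimulusSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (nrow(ev)) {
    if (is.unsorted(ev$onset)) msg <- c(msg, "events not time-sorted")
    if (any(ev$duration <= 0)) msg <- c(msg, "event with non-positive duration")
    add <- ev$kind == "add"
    if (any(ev$total[add] < 0)) msg <- c(msg, "negative injection total")
    if (any(ev$clamp_nM[!add] < 0)) msg <- c(msg, "negative clamp level")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: recorded group-aggregated molecule counts over time
#'
#' @slot times sample times (s), strictly increasing.
#' @slot counts numeric array [group, species, time] of summed molecule
#'   counts per recording group.
#' @slot groups data.frame describing recording groups: \code{name},
#'   \code{region}, \code{spine}, \code{volume} (L) and \code{n_sub}.
#' @slot species species names (second array dimension).
#' @slot seed integer seed used for the run.
#' @slot config EngineConfig list used for the run.
#' @slot corrections number of tau-leap firings clipped by the
#'   negativity policy.
#' @export
setClass("Trajectory",
  representation(
    times       = "numeric",
    counts      = "array",
    groups      = "data.frame",
    species     = "character",
    seed        = "integer",
    config      = "list",
    corrections = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "sample times not strictly increasing")
  d <- dim(object@counts)
  if (length(d) != 3) msg <- c(msg, "counts must be a 3-d array")
  else {
    if (d[1] != nrow(object@groups)) msg <- c(msg, "group dimension mismatch")
    if (d[2] != length(object@species)) msg <- c(msg, "species dimension mismatch")
    if (d[3] != length(object@times)) msg <- c(msg, "time dimension mismatch")
  }
  if (length(msg)) msg else TRUE
})

# ---- generics ----

#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @export
setGeneric("moieties", function(x) standardGeneric("moieties"))
#' @export
setGeneric("subvolumes", function(x) standardGeneric("subvolumes"))
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @export
setGeneric("trajCounts", function(x) standardGeneric("trajCounts"))
#' @export
setGeneric("recordGroups", function(x) standardGeneric("recordGroups"))

#' @describeIn NetworkModel species names
#' @param x object
#' @export
setMethod("speciesNames", "NetworkModel", function(x) x@species$name)
#' @describeIn NetworkModel expanded channel table
#' @export
setMethod("channels", "NetworkModel", function(x) x@channels)
#' @describeIn NetworkModel conserved moieties
#' @export
setMethod("moieties", "NetworkModel", function(x) x@moieties)

#' @describeIn Mesh subvolume table
#' @param x object
#' @export
setMethod("subvolumes", "Mesh", function(x) x@subvolumes)
#' @describeIn Mesh adjacency table
#' @export
setMethod("adjacency", "Mesh", function(x) x@adjacency)
#' @describeIn Mesh total cytosolic volume (um^3)
#' @export
setMethod("totalVolume", "Mesh", function(x) sum(x@subvolumes$volume))
#' @describeIn Mesh region labels present in the mesh
#' @export
setMethod("regionNames", "Mesh", function(x) unique(x@subvolumes$region))

#' @describeIn StimulusSchedule event table
#' @param x object
#' @export
setMethod("events", "StimulusSchedule", function(x) x@events)

#' @describeIn Trajectory sample times (s)
#' @param x object
#' @export
setMethod("sampleTimes", "Trajectory", function(x) x@times)
#' @describeIn Trajectory counts array [group, species, time]
#' @export
setMethod("trajCounts", "Trajectory", function(x) x@counts)
#' @describeIn Trajectory recording-group table
#' @export
setMethod("recordGroups", "Trajectory", function(x) x@groups)

# ---- show ----

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", nrow(object@species), "species,",
      nrow(object@channels), "elementary channels,",
      length(object@moieties), "conserved moieties\n")
  n_mem <- sum(object@species$compartment == "membrane")
  cat("  membrane-bound species:", n_mem,
      "| diffusible species:", sum(object@species$D > 0), "\n")
})

setMethod("show", "Mesh", function(object) {
  sv <- object@subvolumes
  ns <- length(unique(sv$spine[!is.na(sv$spine)]))
  cat("Mesh:", nrow(sv), "subvolumes,", ns, "spine(s),",
      sprintf("total volume %.4g um^3\n", sum(sv$volume)))
  print(table(sv$region))
})

setMethod("show", "StimulusSchedule", function(object) {
  ev <- object@events
  cat("StimulusSchedule '", object@protocol, "': ", nrow(ev), " events",
      if (nrow(ev)) sprintf(" over [%.3g, %.3g] s", min(ev$onset),
                            max(ev$onset + ev$duration)), "\n", sep = "")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "samples x",
      nrow(object@groups), "groups x", length(object@species), "species",
      sprintf("| t in [%.3g, %.3g] s | seed %d\n",
              min(object@times), max(object@times), object@seed))
})
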