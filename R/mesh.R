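# Morphology meshes: a dendritic segment discretized into a lateral 2-D
# grid of subvolumes (single layer spanning the full depth), plus one or
# more spines discretized into 0.1 um cylindrical slices (1-D diffusion).
# The outermost ring of dendrite columns is the submembrane region; the
# distal spine-head slice is the postsynaptic density (PSD).

#' Mesh configuration
#'
#' Defaults reproduce the single-spine morphology: a 2 um long dendrite
#' (1 um wide, 0.6 um deep) subdivided laterally into 14 x 7 columns
#' (lateral size adjusted from the nominal 0.14 um to 2/14 um so the grid
#' tiles exactly), and a spine with a 0.6 um diameter head, a 0.2 um
#' diameter, 0.3 um long neck, and a PSD, in 0.1 um cylindrical slices.
#'
#' @param length,width,depth dendrite dimensions (um).
#' @param nx,ny lateral subvolume grid (defaults chosen so dx ~ dy ~ the
#'   nominal lateral size).
#' @param head_diam,head_len spine head diameter and length (um).
#' @param neck_diam,neck_len spine neck diameter and length (um).
#' @param slice spine slice thickness (um).
#' @param spine_density spines per um (multi-spine mesh).
#' @param n_spines spine count override (multi-spine mesh; the value used
#'   for the spatial-specificity analyses is 13).
#' @param scaled logical; TRUE selects the coarse mesh used for
#'   desk-scale runs (larger subvolumes, 0.15 um spine slices).
#' @return list of configuration values.
#' @export
meshConfig <- function(length = 2, width = 1, depth = 0.6,
                       nx = NULL, ny = NULL,
                       head_diam = 0.6, head_len = 0.6,
                       neck_diam = 0.2, neck_len = 0.3,
                       slice = 0.1, spine_density = 0.8, n_spines = NULL,
                       scaled = FALSE) {
  if (scaled) {
    if (is.null(nx)) nx <- max(2L, round(length / 0.4))
    if (is.null(ny)) ny <- max(2L, round(width / 0.33))
    slice <- 0.15
  } else {
    if (is.null(nx)) nx <- max(2L, round(length / 0.14))
    if (is.null(ny)) ny <- max(2L, round(width / 0.14))
  }
  stopifnot(length > 0, width > 0, depth > 0, head_diam > 0, neck_diam > 0,
            neck_len > 0, slice > 0)
  list(length = length, width = width, depth = depth, nx = as.integer(nx),
       ny = as.integer(ny), head_diam = head_diam, head_len = head_len,
       neck_diam = neck_diam, neck_len = neck_len, slice = slice,
       spine_density = spine_density, n_spines = n_spines, scaled = scaled)
}

# dendrite lateral grid as a subvolume data.frame
.dendriteGrid <- function(cfg) {
  dx <- cfg$length / cfg$nx
  dy <- cfg$width / cfg$ny
  g <- expand.grid(ix = seq_len(cfg$nx), iy = seq_len(cfg$ny))
  edge <- g$ix == 1 | g$ix == cfg$nx | g$iy == 1 | g$iy == cfg$ny
  # membrane area: exposed lateral faces of edge columns
  nface <- (g$ix == 1) + (g$ix == cfg$nx)
  wface <- (g$iy == 1) + (g$iy == cfg$ny)
  data.frame(
    id = seq_len(nrow(g)), ix = g$ix, iy = g$iy,
    x = (g$ix - 0.5) * dx, y = (g$iy - 0.5) * dy, z = cfg$depth / 2,
    volume = dx * dy * cfg$depth,
    area = nface * dy * cfg$depth + wface * dx * cfg$depth,
    region = ifelse(edge, "dendrite_sub", "dendrite_cyt"),
    spine = NA_integer_, stringsAsFactors = FALSE)
}

# append one spine (neck slices then head slices, distal slice = PSD)
# attached on top of dendrite column `col`
.addSpine <- function(sv, adj, cfg, col, spine_idx) {
  n_neck <- max(1L, round(cfg$neck_len / cfg$slice))
  n_head <- max(2L, round(cfg$head_len / cfg$slice))
  dz_neck <- cfg$neck_len / n_neck
  dz_head <- cfg$head_len / n_head
  a_neck <- pi * (cfg$neck_diam / 2)^2
  a_head <- pi * (cfg$head_diam / 2)^2
  x0 <- sv$x[col]; y0 <- sv$y[col]; ztop <- cfg$depth
  prev <- col; prev_z <- cfg$depth / 2
  prev_a <- a_neck  # contact with dendrite limited by neck cross-section
  rows <- list(); edges <- list()
  z <- ztop
  nid <- nrow(sv)
  for (k in seq_len(n_neck + n_head)) {
    in_neck <- k <= n_neck
    dz <- if (in_neck) dz_neck else dz_head
    axs <- if (in_neck) a_neck else a_head
    diam <- if (in_neck) cfg$neck_diam else cfg$head_diam
    nid <- nid + 1L
    zc <- z + dz / 2
    is_psd <- k == n_neck + n_head
    area <- pi * diam * dz + if (is_psd) a_head else 0
    rows[[k]] <- data.frame(
      id = nid, ix = NA_integer_, iy = NA_integer_, x = x0, y = y0, z = zc,
      volume = axs * dz, area = area,
      region = if (is_psd) "psd" else if (in_neck) "spine_neck" else "spine_head",
      spine = spine_idx, stringsAsFactors = FALSE)
    edges[[k]] <- data.frame(i = prev, j = nid,
                             area = min(prev_a, axs), dist = zc - prev_z)
    prev <- nid; prev_z <- zc; prev_a <- axs
    z <- z + dz
  }
  list(sv = rbind(sv, do.call(rbind, rows)),
       adj = rbind(adj, do.call(rbind, edges)))
}

.gridAdjacency <- function(g, cfg) {
  dx <- cfg$length / cfg$nx
  dy <- cfg$width / cfg$ny
  e1 <- merge(g[c("id", "ix", "iy")],
              transform(g[c("id", "ix", "iy")], ix = ix - 1L),
              by = c("ix", "iy"))
  ex <- data.frame(i = e1$id.x, j = e1$id.y, area = dy * cfg$depth, dist = dx)
  e2 <- merge(g[c("id", "ix", "iy")],
              transform(g[c("id", "ix", "iy")], iy = iy - 1L),
              by = c("ix", "iy"))
  ey <- data.frame(i = e2$id.x, j = e2$id.y, area = dx * cfg$depth, dist = dy)
  rbind(ex, ey)
}

.finishMesh <- function(sv, adj, cfg) {
  adj <- rbind(adj, data.frame(i = adj$j, j = adj$i,
                               area = adj$area, dist = adj$dist))
  sv$ix <- NULL; sv$iy <- NULL
  new("Mesh", subvolumes = sv, adjacency = adj, config = cfg)
}

#' Build the single-spine mesh
#'
#' A 2 um dendritic segment as a lateral 2-D grid (single layer spanning
#' the full depth) with one spine attached at the center column: neck
#' slices, head slices, and the distal head slice labeled PSD.
#'
#' @param config a \code{\link{meshConfig}} list.
#' @return a \code{\linkS4class{Mesh}}.
#' @examples
#' mesh <- buildSingleSpineMesh()
#' table(subvolumes(mesh)$region)
#' @export
buildSingleSpineMesh <- function(config = meshConfig()) {
  if (config$head_diam > config$width)
    stop("spine wider than the dendrite attachment site")
  g <- .dendriteGrid(config)
  adj <- .gridAdjacency(g, config)
  mid <- g$id[g$ix == ceiling(config$nx / 2) & g$iy == ceiling(config$ny / 2)]
  out <- .addSpine(g, adj, config, mid, 1L)
  .finishMesh(out$sv, out$adj, config)
}

#' Build the multi-spine mesh
#'
#' A 20 um (by default) dendrite with spines placed randomly at the given
#' density (or exact count), reproducibly under a fixed seed. Spines are
#' indexed in order of position along the dendrite; no two spines share an
#' attachment column.
#'
#' @param config a \code{\link{meshConfig}} list; use
#'   \code{meshConfig(length = 20, n_spines = 13)} for the
#'   spatial-specificity morphology.
#' @param seed placement seed.
#' @return a \code{\linkS4class{Mesh}}.
#' @export
buildMultiSpineMesh <- function(config = meshConfig(length = 20, n_spines = 13),
                                seed = 1L) {
  n <- config$n_spines
  if (is.null(n)) n <- round(config$spine_density * config$length)
  g <- .dendriteGrid(config)
  adj <- .gridAdjacency(g, config)
  if (n > 0) {
    iy0 <- ceiling(config$ny / 2)
    avail <- g$id[g$iy == iy0]
    if (n > length(avail)) stop("requested spine density unachievable on the grid")
    cols <- withr_seed(seed, sort(sample(avail, n)))
    for (s in seq_len(n)) {
      out <- .addSpine(g, adj, config, cols[s], s)
      g <- out$sv; adj <- out$adj
    }
  }
  .finishMesh(g, adj, config)
}

# evaluate expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Per-molecule diffusive jump rate between adjacent subvolumes
#'
#' Standard mesoscopic jump rate D * A / (V_i * d) for the i -> j direction,
#' which satisfies detailed balance (rate_ij * V_i = rate_ji * V_j).
#'
#' @param mesh a Mesh.
#' @param i,j subvolume ids.
#' @param D diffusion constant (um^2/s).
#' @return jump rate (s^-1); 0 for non-adjacent pairs or D = 0.
#' @export
couplingRate <- function(mesh, i, j, D) {
  if (D < 0) stop("negative diffusion constant")
  ad <- mesh@adjacency
  k <- which(ad$i == i & ad$j == j)
  if (!length(k)) return(0)
  vi <- mesh@subvolumes$volume[mesh@subvolumes$id == i]
  D * ad$area[k[1]] / (vi * ad$dist[k[1]])
}

#' Place initial molecules on a mesh
#'
#' Cytosolic species are distributed in proportion to subvolume volume;
#' membrane species in proportion to membrane area over the regions in
#' their localization set (the species' whole-cell-equivalent
#' concentration is first converted to a surface density over that area).
#' Fractional expected counts are realized by stochastic rounding, so the
#' expectation is exact.
#'
#' @param mesh a Mesh.
#' @param model a NetworkModel.
#' @param seed rounding seed.
#' @return integer matrix species x subvolumes of molecule counts.
#' @export
placeInitialMolecules <- function(mesh, model, seed = 1L) {
  sv <- mesh@subvolumes
  sp <- model@species
  vol_L <- sv$volume * 1e-15
  vtot <- sum(vol_L)
  X <- matrix(0L, nrow = nrow(sp), ncol = nrow(sv),
              dimnames = list(sp$name, NULL))
  withr_seed(seed, {
    for (i in seq_len(nrow(sp))) {
      if (sp$init_nM[i] <= 0) next
      total <- sp$init_nM[i] * 1e-9 * AVOGADRO * vtot
      if (sp$compartment[i] == "cytosol") {
        wt <- vol_L / sum(vol_L)
      } else {
        in_loc <- sv$region %in% sp$localization[[i]]
        if (!any(in_loc))
          stop("species ", sp$name[i], " localized to regions absent from mesh")
        wt <- ifelse(in_loc, sv$area, 0)
        if (sum(wt) <= 0) stop("no membrane area for species ", sp$name[i])
        # spine-matching variations: scale spine weights so the local
        # (per-volume) concentration matches the dendritic submembrane
        sm <- model@config$spine_match
        if (!is.null(sm) && sp$name[i] %in% sm) {
          spin <- in_loc & sv$region %in% c("spine_head", "spine_neck", "psd")
          dend <- in_loc & !spin
          if (any(spin) && any(dend)) {
            dens <- sum(wt[dend]) / sum(sv$volume[dend])
            w_new <- sv$volume[spin] * dens
            if (isTRUE(model@config$spine_match_add))
              total <- total * (sum(wt[dend]) + sum(w_new)) / sum(wt)
            wt[spin] <- w_new
          }
        }
        wt <- wt / sum(wt)
      }
      mu <- total * wt
      X[i, ] <- floor(mu) + (runif(length(mu)) < (mu - floor(mu)))
    }
  })
  storage.mode(X) <- "integer"
  X
}

#' Surface density implied by a membrane species' pool
#'
#' Converts a whole-cell-equivalent concentration to picomoles per m^2
#' over the membrane area of the species' localization regions.
#'
#' @param mesh a Mesh.
#' @param model a NetworkModel.
#' @param species species name.
#' @return surface density in picomoles per m^2 (picoSD).
#' @export
surfaceDensity <- function(mesh, model, species) {
  sp <- model@species
  i <- match(species, sp$name)
  if (is.na(i)) stop("unknown species: ", species)
  if (sp$compartment[i] != "membrane") stop(species, " is not membrane-bound")
  sv <- mesh@subvolumes
  area_m2 <- sum(sv$area[sv$region %in% sp$localization[[i]]]) * 1e-12
  mol <- sp$init_nM[i] * 1e-9 * sum(sv$volume) * 1e-15 * AVOGADRO
  mol / AVOGADRO / area_m2 * 1e12   # pmol per m^2
}

#' Export / import a mesh as structured text
#'
#' Writes the subvolume and adjacency tables as two tab-separated files
#' (\code{<prefix>_subvolumes.tsv}, \code{<prefix>_adjacency.tsv}) for
#' inspection and regression fixtures; \code{importMesh} reconstructs the
#' Mesh from them.
#'
#' @param mesh a Mesh.
#' @param prefix output path prefix.
#' @return \code{exportMesh}: the two file paths, invisibly;
#'   \code{importMesh}: a \code{\linkS4class{Mesh}}.
#' @export
exportMesh <- function(mesh, prefix) {
  fs <- paste0(prefix, c("_subvolumes.tsv", "_adjacency.tsv"))
  utils::write.table(mesh@subvolumes, fs[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(mesh@adjacency, fs[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(fs)
}

#' @rdname exportMesh
#' @export
importMesh <- function(prefix) {
  sv <- utils::read.table(paste0(prefix, "_subvolumes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  ad <- utils::read.table(paste0(prefix, "_adjacency.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  sv$spine <- as.integer(sv$spine)
  new("Mesh", subvolumes = sv, adjacency = ad, config = list())
}
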