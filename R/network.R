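# Reaction network: species, reaction rows, elementary-channel expansion,
# conserved moieties and mass-action propensities.
#
# All bimolecular rate constants are in nM^-1 s^-1 and unimolecular rates in
# s^-1. Rows written "A + 2*B <-> C" fire as a single second-order channel
# (propensity proportional to N_A * N_B) that consumes two B molecules per
# firing, which keeps the printed nM^-1 s^-1 units meaningful.

#' Reaction rows of the signaling network
#'
#' Returns the reaction table of the model: calcium pumps, leak and buffers
#' (calbindin, calmodulin), the mGluR/Gq G-protein cycle, phospholipase C
#' beta with its calcium/GaGTP synergy, PIP2 hydrolysis to DAG + IP3, DAG
#' lipase production of the endocannabinoid 2AG, DAG kinase, and the
#' sequential calcium-then-DAG activation of PKC.
#'
#' Row grammar: "A + B <-> C" reversible binding (kf, kb); "A <-> B"
#' reversible conversion; a missing kb makes the row one-way; "A + E <-> C
#' => E + P" an enzyme row with explicit intermediate complex C (kf, kb,
#' kcat); "A => B" a one-way conversion; "2*X" consumes two X per firing.
#'
#' @param multipliers named numeric vector of rate multipliers applied to
#'   selected rows; names are "<desc>.kf", "<desc>.kb" or "<desc>.kcat"
#'   where <desc> is the row description. Used by the robustness suite.
#' @return data.frame with columns \code{row}, \code{kf}, \code{kb},
#'   \code{kcat}, \code{desc}.
#' @export
reactionTable <- function(multipliers = NULL) {
  r <- function(row, kf, kb, kcat, desc)
    data.frame(row = row, kf = kf, kb = kb, kcat = kcat, desc = desc,
               stringsAsFactors = FALSE)
  tab <- rbind(
    r("Ca + PMCA <-> PMCA.Ca => PMCA + CaExt", 0.05, 7, 3.5, "Calcium pump"),
    r("Ca + NCX <-> NCX.Ca => NCX + CaExt", 0.0168, 11.2, 5.6, "Calcium exchanger"),
    r("CaExt + Leak <-> CaExt.Leak => Ca + Leak", 0.0015, 1.1, 1.1, "Calcium leak"),
    r("Ca + Calbindin <-> Calbindin.Ca", 0.028, 19.6, NA, "Calcium buffer"),
    # the printed C-site/N-site labels of the four calmodulin rows are kept
    # as comments; the rates are implemented exactly as printed per row
    r("Cam + 2*Ca <-> CamC.Ca2", 0.006, 9.1, NA, "Calmodulin C site 1st"),
    r("CamC.Ca2 + 2*Ca <-> Cam.Ca4", 0.1, 1000, NA, "Calmodulin N site 2nd"),
    r("Cam + 2*Ca <-> CamN.Ca2", 0.1, 1000, NA, "Calmodulin N site 1st"),
    r("CamN.Ca2 + 2*Ca <-> Cam.Ca4", 0.006, 9.1, NA, "Calmodulin C site 2nd"),
    r("Glu <-> GluInact", 2, 2e-05, NA, "mGluR agonist uptake"),
    r("Glu + mGluR <-> Glu.mGluR", 1e-04, 10, NA, "mGluR agonist binding"),
    r("Glu.mGluR <-> Glu.mGluRdesens", 0.25, 0.001, NA, "mGluR desensitization"),
    r("Glu.mGluR + Gabg <-> Glu.mGluR.Gabg => Glu.mGluR + GaGTP",
      0.015, 7.2, 0.5, "G protein activation"),
    r("PLC + Ca <-> PLC.Ca", 0.02, 120, NA, "PLC binds calcium 1st"),
    r("PLC.Ca + GaGTP <-> PLC.Ca.GaGTP", 0.1, 10, NA, "PLC binds GaGTP 2nd"),
    r("PLC + GaGTP <-> PLC.GaGTP", 0.01, 12, NA, "PLC binds GaGTP 1st"),
    r("PLC.GaGTP + Ca <-> PLC.Ca.GaGTP", 0.08, 40, NA, "PLC binds calcium 2nd"),
    r("PLC.Ca + PIP2 <-> PLC.Ca.PIP2 => PLC.Ca.DAG + IP3",
      0.006, 10, 25, "Production of DAG step 1"),
    r("PLC.Ca.DAG <-> PLC.Ca + DAG", 200, NA, NA, "Production of DAG step 2"),
    r("PLC.Ca.GaGTP + PIP2 <-> PLC.Ca.GaGTP.PIP2 => PLC.Ca.GaGTP.DAG + IP3",
      0.015, 75, 250, "Production of DAG step 1 Gq"),
    r("PLC.Ca.GaGTP.DAG <-> PLC.Ca.GaGTP + DAG", 1000, NA, NA,
      "Production of DAG step 2 Gq"),
    r("IP3 <-> IP3deg", 10, NA, NA, "Degradation of IP3"),
    r("IP3deg + PIKin <-> IP3deg.PIKin => PIP2 + PIKin", 0.002, 1, 1,
      "PIP2 regeneration by PI kinase"),
    r("PLC.GaGTP => PLC + GaGDP", 30, NA, NA, "GAP activity of PLC"),
    r("PLC.Ca.GaGTP => PLC.Ca + GaGDP", 30, NA, NA, "GAP activity of PLC Ca"),
    r("GaGTP => GaGDP", 1, NA, NA, "Hydrolysis of GaGTP"),
    r("GaGDP => Gabg", 10, NA, NA, "Regeneration of G protein"),
    r("Ca + DAGL <-> Ca.DAGL", 0.125, 50, NA, "Calcium activates DAG lipase"),
    r("DAG + Ca.DAGL <-> DAG.Ca.DAGL => Ca.DAGL + 2AG", 0.0025, 1.5, 1,
      "2AG production"),
    r("2AG <-> 2AGdeg", 5, NA, NA, "2AG degradation"),
    # the kinase is recycled by the catalytic step
    r("DAG + DagK <-> DagK.DAG => DagK + PA", 7e-04, 40, 10,
      "DAG inactivation by DAG kinase"),
    r("PKC + Ca <-> PKC.Ca", 0.02, 50, NA, "PKC binds calcium"),
    r("PKC.Ca + DAG <-> PKC.active", 1.5e-05, 0.15, NA, "PKC binds DAG")
  )
  if (!is.null(multipliers) && length(multipliers)) {
    for (nm in names(multipliers)) {
      parts <- strsplit(nm, "\\.(?=k(f|b|cat)$)", perl = TRUE)[[1]]
      if (length(parts) != 2) stop("bad multiplier name: ", nm)
      i <- which(tab$desc == parts[1])
      if (!length(i)) stop("multiplier targets unknown row: ", parts[1])
      tab[i, parts[2]] <- tab[i, parts[2]] * multipliers[[nm]]
    }
  }
  tab
}

#' Network configuration: membrane pools and options
#'
#' Membrane-bound species amounts are specified as whole-cell-equivalent
#' concentrations (nM over the total cytosolic volume) and converted to
#' surface densities (picomoles per m^2) over the membrane regions the
#' species occupies at placement time. The DAG lipase pool is 1.7 uM; the
#' Leak density is calibrated analytically (\code{\link{calibrateLeak}})
#' so that pump efflux balances leak influx at 51 nM resting free calcium.
#'
#' @param pools named numeric vector overriding default membrane pools (nM
#'   whole-cell equivalent).
#' @param bapta_nM concentration of the optional exogenous fast calcium
#'   buffer (0 disables it).
#' @param bapta_kon,bapta_Kd forward rate (nM^-1 s^-1) and dissociation
#'   constant (nM) of the exogenous buffer; defaults are literature-typical
#'   fast-buffer values.
#' @param multipliers rate multipliers passed to \code{\link{reactionTable}}.
#' @return list of configuration values.
#' @export
networkConfig <- function(pools = NULL, bapta_nM = 0,
                          bapta_kon = 0.4, bapta_Kd = 200,
                          multipliers = NULL) {
  p <- c(mGluR = 4000, Gabg = 8000, PLC = 1000, PIP2 = 20000,
         PIKin = 1000, DAGL = 1700, DagK = 1000,
         PMCA = 12000, NCX = 7000, Leak = NA)
  if (!is.null(pools)) {
    stopifnot(all(names(pools) %in% names(p)))
    p[names(pools)] <- pools
  }
  if (is.na(p[["Leak"]]))
    p[["Leak"]] <- calibrateLeak(p[["PMCA"]], p[["NCX"]])
  list(pools = p, bapta_nM = bapta_nM, bapta_kon = bapta_kon,
       bapta_Kd = bapta_Kd, multipliers = multipliers)
}

#' Calibrate the leak pool for a 51 nM resting calcium steady state
#'
#' At rest the leak influx (extracellular calcium carried in through the
#' leak channel) must balance the PMCA and NCX efflux evaluated at the
#' resting free-calcium concentration. Each transporter is a two-step
#' enzyme, so its steady-state flux per unit pool is
#' kcat * kf*Ca / (kf*Ca + kb + kcat).
#'
#' @param pmca,ncx transporter pools (nM whole-cell equivalent).
#' @param ca_rest resting free calcium (nM).
#' @param ca_ext extracellular calcium (nM).
#' @return leak pool (nM whole-cell equivalent).
#' @export
calibrateLeak <- function(pmca, ncx, ca_rest = 51, ca_ext = 2015100) {
  flux <- function(pool, kf, kb, kcat, s)
    pool * kcat * kf * s / (kf * s + kb + kcat)
  efflux <- flux(pmca, 0.05, 7, 3.5, ca_rest) +
    flux(ncx, 0.0168, 11.2, 5.6, ca_rest)
  per_leak <- 1.1 * 0.0015 * ca_ext / (0.0015 * ca_ext + 1.1 + 1.1)
  efflux / per_leak
}

# parse one side of a row into a named integer count vector
.parseSide <- function(side) {
  side <- trimws(side)
  if (side == "" || side == "0") return(setNames(integer(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  counts <- integer(0)
  for (tm in terms) {
    if (grepl("^[0-9]+\\*", tm)) {
      n <- as.integer(sub("\\*.*", "", tm))
      spn <- sub("^[0-9]+\\*", "", tm)
    } else {
      n <- 1L; spn <- tm
    }
    counts[spn] <- (if (spn %in% names(counts)) counts[[spn]] else 0L) + n
  }
  counts
}

.mkChannel <- function(name, consume, produce, k, type, row_id, desc) {
  ord <- length(consume)              # number of distinct reactant species
  if (ord > 2) stop("channel with more than two reactant species: ", name)
  data.frame(name = name, k = k, order = max(1L, ord), type = type,
             row_id = row_id, desc = desc,
             consume = I(list(consume)), produce = I(list(produce)),
             stringsAsFactors = FALSE)
}

#' Expand a reaction row into elementary channels
#'
#' Reversible rows yield forward and backward channels; enzyme rows with a
#' kcat yield binding, unbinding and catalytic channels with the explicit
#' intermediate complex; rows with a single rate yield one channel.
#'
#' @param row,kf,kb,kcat,desc one row of \code{\link{reactionTable}} (the
#'   row string and its rate constants).
#' @return data.frame of channels with columns \code{name}, \code{k},
#'   \code{order}, \code{type}, \code{row_id}, \code{desc} and list columns
#'   \code{consume}/\code{produce} (named per-firing stoichiometries).
#' @examples
#' expandReactionRow("Ca + PMCA <-> PMCA.Ca => PMCA + CaExt", 0.05, 7, 3.5)
#' @export
expandReactionRow <- function(row, kf, kb = NA, kcat = NA, desc = "") {
  row_id <- row
  has_cat <- grepl("=>", row, fixed = TRUE)
  has_rev <- grepl("<->", row, fixed = TRUE)
  if (!is.na(kcat) && !(has_cat && has_rev))
    stop("kcat given without an intermediate complex: ", row)
  out <- NULL
  if (has_rev && has_cat) {
    # A + E <-> C => E + P   (enzyme with explicit intermediate)
    if (is.na(kcat)) stop("enzyme row without kcat: ", row)
    parts <- trimws(strsplit(row, "=>", fixed = TRUE)[[1]])
    lr <- trimws(strsplit(parts[1], "<->", fixed = TRUE)[[1]])
    lhs <- .parseSide(lr[1]); mid <- .parseSide(lr[2])
    rhs <- .parseSide(parts[2])
    if (length(mid) != 1) stop("enzyme intermediate must be one complex: ", row)
    out <- rbind(
      .mkChannel(paste0(row_id, " [bind]"), lhs, mid, kf, "bind", row_id, desc),
      if (!is.na(kb))
        .mkChannel(paste0(row_id, " [unbind]"), mid, lhs, kb, "unbind", row_id, desc),
      .mkChannel(paste0(row_id, " [cat]"), mid, rhs, kcat, "cat", row_id, desc))
  } else if (has_rev) {
    lr <- trimws(strsplit(row, "<->", fixed = TRUE)[[1]])
    lhs <- .parseSide(lr[1]); rhs <- .parseSide(lr[2])
    out <- rbind(
      .mkChannel(paste0(row_id, " [fwd]"), lhs, rhs, kf, "fwd", row_id, desc),
      if (!is.na(kb))
        .mkChannel(paste0(row_id, " [back]"), rhs, lhs, kb, "back", row_id, desc))
  } else if (has_cat) {
    lr <- trimws(strsplit(row, "=>", fixed = TRUE)[[1]])
    out <- .mkChannel(paste0(row_id, " [uni]"), .parseSide(lr[1]),
                      .parseSide(lr[2]), kf, "uni", row_id, desc)
  } else stop("unparseable row pattern: ", row)
  out
}

# species table for the full model
.speciesTable <- function(config) {
  pools <- config$pools
  reg_all <- c("dendrite_cyt", "dendrite_sub", "spine_head", "spine_neck", "psd")
  reg_mem <- c("dendrite_sub", "spine_head", "psd")
  reg_ncx <- c("dendrite_sub", "spine_neck")
  cy <- function(name, init = 0, D = 0)
    data.frame(name = name, compartment = "cytosol", init_nM = init, D = D,
               localization = I(list(reg_all)), stringsAsFactors = FALSE)
  mem <- function(name, init = 0, loc = reg_mem)
    data.frame(name = name, compartment = "membrane", init_nM = init, D = 0,
               localization = I(list(loc)), stringsAsFactors = FALSE)
  sp <- rbind(
    cy("Ca", 51, 174.3),
    cy("CaExt", 2015100, 174.3),
    cy("Calbindin", 153290, 9.3),
    cy("Calbindin.Ca", 7648, 9.3),
    cy("Cam", 7940, 11),
    cy("CamC.Ca2", 60, 11),
    cy("CamN.Ca2", 60, 11),
    cy("Cam.Ca4", 0, 11),
    cy("Glu", 0, 100),
    cy("GluInact", 1019100, 100),
    cy("IP3", 0, 10.6),
    cy("IP3deg", 0, 10.6),
    cy("PKC", 15000, 14),
    cy("PKC.Ca", 0, 14),
    cy("2AG", 0, 88.6),
    cy("2AGdeg", 0, 88.6),
    mem("mGluR", pools[["mGluR"]]),
    mem("Glu.mGluR"), mem("Glu.mGluRdesens"),
    mem("Gabg", pools[["Gabg"]]),
    mem("Glu.mGluR.Gabg"), mem("GaGTP"), mem("GaGDP"),
    mem("PLC", pools[["PLC"]]),
    mem("PLC.Ca"), mem("PLC.GaGTP"), mem("PLC.Ca.GaGTP"),
    mem("PIP2", pools[["PIP2"]]),
    mem("PLC.Ca.PIP2"), mem("PLC.Ca.DAG"),
    mem("PLC.Ca.GaGTP.PIP2"), mem("PLC.Ca.GaGTP.DAG"),
    mem("DAG"), mem("PA"),
    mem("PIKin", pools[["PIKin"]]), mem("IP3deg.PIKin"),
    mem("DAGL", pools[["DAGL"]]),
    mem("Ca.DAGL"), mem("DAG.Ca.DAGL"),
    mem("DagK", pools[["DagK"]]), mem("DagK.DAG"),
    mem("PMCA", pools[["PMCA"]]), mem("PMCA.Ca"),
    mem("NCX", pools[["NCX"]], reg_ncx), mem("NCX.Ca", 0, reg_ncx),
    mem("Leak", pools[["Leak"]]), mem("CaExt.Leak"),
    mem("PKC.active")
  )
  if (config$bapta_nM > 0) {
    sp <- rbind(sp, cy("BAPTA", config$bapta_nM, 100), cy("BAPTA.Ca", 0, 100))
  }
  sp
}

.moietyList <- function(species) {
  w <- function(...) unlist(list(...))
  m <- list(
    calmodulin = w(Cam = 1, CamC.Ca2 = 1, CamN.Ca2 = 1, Cam.Ca4 = 1),
    pkc = w(PKC = 1, PKC.Ca = 1, PKC.active = 1),
    calbindin = w(Calbindin = 1, Calbindin.Ca = 1),
    mglur = w(mGluR = 1, Glu.mGluR = 1, Glu.mGluRdesens = 1, Glu.mGluR.Gabg = 1),
    gprotein = w(Gabg = 1, Glu.mGluR.Gabg = 1, GaGTP = 1, GaGDP = 1,
                 PLC.GaGTP = 1, PLC.Ca.GaGTP = 1, PLC.Ca.GaGTP.PIP2 = 1,
                 PLC.Ca.GaGTP.DAG = 1),
    plc = w(PLC = 1, PLC.Ca = 1, PLC.GaGTP = 1, PLC.Ca.GaGTP = 1,
            PLC.Ca.PIP2 = 1, PLC.Ca.DAG = 1, PLC.Ca.GaGTP.PIP2 = 1,
            PLC.Ca.GaGTP.DAG = 1),
    inositol = w(PIP2 = 1, PLC.Ca.PIP2 = 1, PLC.Ca.GaGTP.PIP2 = 1,
                 IP3 = 1, IP3deg = 1, IP3deg.PIKin = 1),
    pikin = w(PIKin = 1, IP3deg.PIKin = 1),
    dagl = w(DAGL = 1, Ca.DAGL = 1, DAG.Ca.DAGL = 1),
    dagk = w(DagK = 1, DagK.DAG = 1),
    pmca = w(PMCA = 1, PMCA.Ca = 1),
    ncx = w(NCX = 1, NCX.Ca = 1),
    leak = w(Leak = 1, CaExt.Leak = 1),
    glu = w(Glu = 1, GluInact = 1, Glu.mGluR = 1, Glu.mGluRdesens = 1,
            Glu.mGluR.Gabg = 1),
    calcium = w(Ca = 1, CaExt = 1, PMCA.Ca = 1, NCX.Ca = 1, CaExt.Leak = 1,
                Calbindin.Ca = 1, CamC.Ca2 = 2, CamN.Ca2 = 2, Cam.Ca4 = 4,
                PLC.Ca = 1, PLC.Ca.GaGTP = 1, PLC.Ca.PIP2 = 1, PLC.Ca.DAG = 1,
                PLC.Ca.GaGTP.PIP2 = 1, PLC.Ca.GaGTP.DAG = 1, Ca.DAGL = 1,
                DAG.Ca.DAGL = 1, PKC.Ca = 1, PKC.active = 1)
  )
  if ("BAPTA" %in% species) {
    m$bapta <- w(BAPTA = 1, BAPTA.Ca = 1)
    m$calcium <- c(m$calcium, w(BAPTA.Ca = 1))
  }
  m
}

#' Build the full signaling network model
#'
#' Expands every reaction row into elementary channels, applies the initial
#' concentrations (species not listed start at 0), attaches diffusion
#' constants and localizations, and declares the conserved moieties of the
#' network (validated against every channel's stoichiometry).
#'
#' @param config a \code{\link{networkConfig}} list.
#' @return a \code{\linkS4class{NetworkModel}}.
#' @examples
#' net <- buildNetwork()
#' sum(net@species$init_nM[net@species$name %in%
#'     c("Cam", "CamC.Ca2", "CamN.Ca2", "Cam.Ca4")])  # 8060 nM calmodulin
#' @export
buildNetwork <- function(config = networkConfig()) {
  tab <- reactionTable(config$multipliers)
  if (config$bapta_nM > 0) {
    koff <- config$bapta_kon * config$bapta_Kd
    tab <- rbind(tab, data.frame(row = "Ca + BAPTA <-> BAPTA.Ca",
                                 kf = config$bapta_kon, kb = koff, kcat = NA,
                                 desc = "Exogenous calcium buffer"))
  }
  ch <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    expandReactionRow(tab$row[i], tab$kf[i], tab$kb[i], tab$kcat[i], tab$desc[i])))
  sp <- .speciesTable(config)
  model <- new("NetworkModel", species = sp, channels = ch,
               moieties = .moietyList(sp$name), config = config)
  model
}

#' Stoichiometry matrix of a network
#'
#' @param model a NetworkModel.
#' @return integer matrix species x channels of net molecule changes per
#'   firing.
#' @export
stoichiometryMatrix <- function(model) {
  sp <- model@species$name
  ch <- model@channels
  S <- matrix(0L, nrow = length(sp), ncol = nrow(ch),
              dimnames = list(sp, ch$name))
  for (j in seq_len(nrow(ch))) {
    cons <- ch$consume[[j]]; prod <- ch$produce[[j]]
    S[names(cons), j] <- S[names(cons), j] - cons
    S[names(prod), j] <- S[names(prod), j] + prod
  }
  S
}

#' Moiety totals implied by the initial concentrations
#'
#' @param model a NetworkModel.
#' @return named numeric vector of whole-cell-equivalent totals (nM).
#' @export
moietyTotals <- function(model) {
  ic <- setNames(model@species$init_nM, model@species$name)
  vapply(model@moieties, function(m) sum(ic[names(m)] * m), numeric(1))
}

#' Mass-action propensity of an elementary channel
#'
#' First-order channels fire at k*N; second-order channels at
#' k_conv * N_A * N_B where k_conv converts the macroscopic nM^-1 s^-1
#' constant to a per-molecule-pair rate, k / (N_A_Avogadro * V * 1e-9).
#'
#' @param channel one row of the channel table (data.frame with
#'   \code{consume} list column, \code{k} and \code{order}).
#' @param counts named integer vector of molecule counts.
#' @param volume subvolume volume in liters.
#' @return firing rate in events per second.
#' @export
propensity <- function(channel, counts, volume) {
  if (any(counts < 0)) stop("negative molecule count")
  if (volume <= 0) stop("non-positive volume")
  cons <- channel$consume[[1]]
  n <- counts[names(cons)]
  if (any(is.na(n))) stop("count missing for species ",
                          paste(names(cons)[is.na(n)], collapse = ", "))
  if (any(n < cons)) return(0)
  if (channel$order == 1) channel$k * n[[1]]
  else channel$k / (AVOGADRO * volume * 1e-9) * prod(n)
}
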