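# shared helpers: tiny models and meshes built in code

miniSpecies <- function(names, init = 0, D = 0) {
  data.frame(name = names, compartment = "cytosol",
             init_nM = rep_len(init, length(names)),
             D = rep_len(D, length(names)),
             localization = I(rep(list("box"), length(names))),
             stringsAsFactors = FALSE)
}

miniModel <- function(rows, species) {
  ch <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
    expandReactionRow(rows$row[i], rows$kf[i], rows$kb[i], rows$kcat[i])))
  new("NetworkModel", species = species, channels = ch,
      moieties = list(), config = list())
}

reactionRows <- function(...) {
  args <- list(...)
  do.call(rbind, lapply(args, function(a)
    data.frame(row = a[[1]], kf = as.numeric(a[[2]]),
               kb = if (length(a) > 2) as.numeric(a[[3]]) else NA,
               kcat = if (length(a) > 3) as.numeric(a[[4]]) else NA,
               desc = "", stringsAsFactors = FALSE)))
}

# a fixed-count initial state helper
countMatrix <- function(species, counts, nsub = 1) {
  X <- matrix(rep(as.integer(counts), nsub), ncol = nsub,
              dimnames = list(species, NULL))
  storage.mode(X) <- "integer"
  X
}
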