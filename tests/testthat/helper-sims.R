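# shared fixtures, built once per test run

.shared <- new.env(parent = emptyenv())

sharedSim <- function() {
  if (is.null(.shared$sim))
    .shared$sim <- runTurnover(simConfig(nx = 9, ny = 9, duration = 96,
                                         burnIn = 48, seed = 11,
                                         snapshotEvery = 6))
  .shared$sim
}

sharedHoneycomb <- function() {
  if (is.null(.shared$hc))
    .shared$hc <- extractHoneycomb(sharedSim())
  .shared$hc
}

# an all-steady crystal snapshot on a small torus
crystalState <- function(lat) {
  N <- nColumns(lat)
  entry <- -(columnParity(lat) * 8) - 0.01 * seq_len(N)
  list(entry = entry, topEntry = entry,
       phase = rep(0L, N), deadline = rep(Inf, N),
       incoming = rep(NA_real_, N), count = rep(0L, N))
}

crystalHoneycomb <- function(nx = 6, ny = 6) {
  lat <- buildLattice(nx, ny)
  ftkd:::.extractFromState(crystalState(lat), lat)
}
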