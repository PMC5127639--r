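# Discrete-time stochastic SG2-layer turnover.
#
# Three local rules drive the dynamics:
#   (1) bTJs form on edges shared by two SG2 cells, tTJs on edges shared by
#       three (handled at extraction);
#   (2) an SG2 cell higher than all six adjacent SG2 cells differentiates
#       to SG1 after a waiting time ~ Uniform(0, waitMax);
#   (3) the SG3 cell below is promoted to SG2 synchronously with that
#       differentiation, so the column briefly carries two TJ polygons
#       (the double-edged configuration) until the old TJ disappears.
#
# "Higher" is tracked through entry times: on the interdigitated lattice
# the height order of two adjacent SG2 cells always equals their age order
# (the newer cell entered lower), which the honeycomb extractor re-checks.
# Because differentiation happens at the transition start (rule 3), a
# transitioning column counts its incoming cell for rule-2 comparisons; its
# exiting cell keeps its TJ (and its height) until disappearance completes.

.PHASE_STEADY <- 0L
.PHASE_WAITING <- 1L
.PHASE_TRANSITION <- 2L

#' Simulation configuration constructor
#'
#' @param waitMax uniform waiting-time bound (hr); default 9.6.
#' @param disappearance TJ disappearance duration (hr); default 2.4, the
#'   printed calibration 24 x 9.8/100 (see
#'   \code{\link{calibrateDisappearance}}).
#' @param dtMinutes frame interval (min); default 7.2.
#' @param turnoverTarget nominal turnover time (hr), reporting only.
#' @param burnIn discarded initial interval (hr); default 48.
#' @param duration measured interval (hr); default 480.
#' @param seed integer RNG seed.
#' @param nx,ny lattice dimensions; default 21 x 21 (a fault-free
#'   interdigitated torus needs nx, ny divisible by 3).
#' @param periodic logical; default TRUE.
#' @param flattenRatio cell flattening; default 0.25.
#' @param init \code{"crystal"} or \code{"iid"}; see
#'   \linkS4class{SimConfig}.
#' @param snapshotEvery full-state snapshot interval (hr); default 24.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(waitMax = 9.6, disappearance = 2.4, dtMinutes = 7.2,
                      turnoverTarget = 24, burnIn = 48, duration = 480,
                      seed = 1L, nx = 21L, ny = 21L, periodic = TRUE,
                      flattenRatio = 0.25, init = "crystal",
                      snapshotEvery = 24) {
  new("SimConfig",
      waitMax = waitMax, disappearance = disappearance, dtMinutes = dtMinutes,
      turnoverTarget = turnoverTarget, burnIn = burnIn, duration = duration,
      seed = as.integer(seed), nx = as.integer(nx), ny = as.integer(ny),
      periodic = periodic, flattenRatio = flattenRatio, init = init,
      snapshotEvery = snapshotEvery)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d x %d columns (%s), wait ~ U(0, %g hr), disappearance %g hr,\n",
    "  dt %g min, burn-in %g hr + %g hr, init '%s', seed %d\n"),
    object@nx, object@ny, if (object@periodic) "periodic" else "open",
    object@waitMax, object@disappearance, object@dtMinutes,
    object@burnIn, object@duration, object@init, object@seed))
})

#' Draw stochastic waiting times
#'
#' Waiting before SG2-to-SG1 differentiation of a locally highest cell is
#' uniform on [0, waitMax]; draws advance the R RNG stream, so a fixed seed
#' reproduces the sequence exactly.
#'
#' @param n number of draws.
#' @param waitMax upper bound (hr); default 9.6.
#' @return numeric vector of waits (hr).
#' @export
drawWait <- function(n, waitMax = 9.6) {
  if (waitMax < 0) stop("waitMax must be non-negative")
  stats::runif(n, 0, waitMax)
}

# internal state container
.initState <- function(config, lattice) {
  N <- nColumns(lattice)
  nominal <- config@turnoverTarget
  if (config@init == "crystal") {
    # height-consistent ordering: the geometrically highest parity class is
    # the oldest; bands of one third of a nominal cycle, jittered within
    entry <- -lattice@parity * nominal / 3 - drawWait(N, nominal / 3)
  } else {
    entry <- -drawWait(N, nominal)
  }
  while (anyDuplicated(entry)) entry <- entry + 1e-9 * seq_len(N)  # distinct
  list(entry = entry,            # youngest SG2 entry time (rule-2 ages)
       topEntry = entry,         # entry of the column's top (TJ-bearing) cell
       phase = rep(.PHASE_STEADY, N),
       deadline = rep(Inf, N),
       incoming = rep(NA_real_, N),
       count = integer(N))       # completed turnovers
}

#' Columns whose SG2 cell may start waiting
#'
#' A steady column is eligible when its SG2 cell is strictly older (higher)
#' than the current SG2 cell of each of its six lateral neighbours.  A
#' transitioning neighbour counts its incoming cell, which entered at the
#' transition start; a waiting neighbour keeps its old age, which makes two
#' adjacent columns never simultaneously eligible.
#'
#' @param state engine state list (entry, phase, ...).
#' @param lattice a \linkS4class{ColumnLattice}.
#' @return integer vector of eligible column ids.
#' @export
eligibleColumns <- function(state, lattice) {
  entry <- state$entry
  nbr <- lattice@nbr
  m <- entry[nbr[, 1]]
  for (s in 2:6) m <- pmin(m, entry[nbr[, s]], na.rm = TRUE)
  if (any(entry == m, na.rm = TRUE))
    stop("tied entry times between adjacent columns; initialization must guarantee distinctness")
  which(state$phase == .PHASE_STEADY & entry < m)
}

#' Advance the simulation by one frame
#'
#' Processes, in order: transition completions (phase 2: the exiting cell
#' leaves the TJ layer, the incoming cell becomes the column's top),
#' waiting deadlines reached (phase 1 begins: the SG3 below is promoted,
#' the column becomes double-edged for \code{disappearance} hours), then
#' new eligibility (waiting starts with a fresh uniform deadline).
#' Deadlines are compared at frame boundaries, so event times are
#' quantized to dt.
#'
#' @param state engine state list.
#' @param t frame time after the step (hr).
#' @param dt frame interval (hr).
#' @param config a \linkS4class{SimConfig}.
#' @param lattice a \linkS4class{ColumnLattice}.
#' @return list(state, events) where events is a data.frame of this frame's
#'   events.
#' @export
stepTurnover <- function(state, t, dt, config, lattice) {
  if (dt <= 0) stop("dt must be positive")
  ev <- list()

  done <- which(state$phase == .PHASE_TRANSITION & t >= state$deadline - 1e-9)
  if (length(done)) {
    state$topEntry[done] <- state$entry[done]
    state$phase[done] <- .PHASE_STEADY
    state$deadline[done] <- Inf
    state$count[done] <- state$count[done] + 1L
    ev[[length(ev) + 1L]] <- data.frame(time_hr = t, column_id = done,
                                        event = "transition_end")
  }

  beginT <- which(state$phase == .PHASE_WAITING & t >= state$deadline - 1e-9)
  if (length(beginT)) {
    state$phase[beginT] <- .PHASE_TRANSITION
    state$deadline[beginT] <- t + config@disappearance
    state$incoming[beginT] <- t
    state$entry[beginT] <- t       # rule 3: promotion at the moment of
                                   # differentiation; rule 2 sees the new cell
    ev[[length(ev) + 1L]] <- data.frame(time_hr = t, column_id = beginT,
                                        event = "transition_start")
  }

  elig <- eligibleColumns(state, lattice)
  if (length(elig)) {
    state$phase[elig] <- .PHASE_WAITING
    state$deadline[elig] <- t + drawWait(length(elig), config@waitMax)
    ev[[length(ev) + 1L]] <- data.frame(time_hr = t, column_id = elig,
                                        event = "wait_start")
  }

  list(state = state,
       events = if (length(ev)) do.call(rbind, ev)
                else data.frame(time_hr = numeric(0), column_id = integer(0),
                                event = character(0)))
}

#' Run a turnover simulation
#'
#' Initializes distinct entry times (height-ordered by parity class under
#' the default crystal initialization), runs \code{burnIn + duration} hours
#' at the configured frame interval, and records the event log, the
#' per-frame transitioning-column count, and full state snapshots every
#' \code{snapshotEvery} hours (plus the final frame).  Fully reproducible
#' from the seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param lattice optional prebuilt \linkS4class{ColumnLattice}.
#' @return a \linkS4class{TurnoverSim}.
#' @examples
#' sim <- runTurnover(simConfig(nx = 6, ny = 6, duration = 48, burnIn = 24))
#' doubleEdgedFraction(sim)
#' @export
runTurnover <- function(config, lattice = NULL) {
  validObject(config)
  if (is.null(lattice))
    lattice <- buildLattice(config@nx, config@ny, flattenRatio = config@flattenRatio,
                            periodic = config@periodic)
  set.seed(config@seed)
  state <- .initState(config, lattice)

  dt <- config@dtMinutes / 60
  nsteps <- round((config@burnIn + config@duration) / dt)
  snapEvery <- max(1L, round(config@snapshotEvery / dt))
  N <- nColumns(lattice)

  evAcc <- vector("list", 256L); nev <- 0L
  states <- list()
  nTrans <- integer(nsteps)
  for (s in seq_len(nsteps)) {
    t <- s * dt
    res <- stepTurnover(state, t, dt, config, lattice)
    state <- res$state
    if (nrow(res$events)) {
      nev <- nev + 1L
      if (nev > length(evAcc)) evAcc <- c(evAcc, vector("list", length(evAcc)))
      evAcc[[nev]] <- res$events
    }
    nTrans[s] <- sum(state$phase == .PHASE_TRANSITION)
    if (s %% snapEvery == 0L || s == nsteps)
      states[[length(states) + 1L]] <- c(list(time = t), state)
  }

  events <- do.call(rbind, evAcc[seq_len(nev)])
  events <- events[order(events$time_hr, events$column_id), ]
  rownames(events) <- NULL
  new("TurnoverSim", config = config, lattice = lattice, events = events,
      states = states,
      fracSeries = data.frame(time_hr = seq_len(nsteps) * dt, n_transition = nTrans))
}

#' @rdname TurnoverSim-class
setMethod("events", "TurnoverSim", function(x) x@events)

#' @rdname TurnoverSim-class
setMethod("snapshotTimes", "TurnoverSim",
          function(x) vapply(x@states, `[[`, 0, "time"))

setMethod("show", "TurnoverSim", function(object) {
  cat(sprintf("TurnoverSim: %d columns, %g hr simulated, %d events, %d snapshots\n",
              nColumns(object@lattice),
              object@config@burnIn + object@config@duration,
              nrow(object@events), length(object@states)))
  cat(sprintf("  double-edged fraction (post burn-in): %.2f%%\n",
              doubleEdgedFraction(object)))
})

#' Full engine state at a stored snapshot time
#'
#' @param sim a \linkS4class{TurnoverSim}.
#' @param time snapshot time (hr); must be one of \code{snapshotTimes(sim)}.
#' @return state list (time, entry, topEntry, phase, deadline, incoming,
#'   count).
#' @export
snapshotAt <- function(sim, time) {
  ts <- snapshotTimes(sim)
  k <- which(abs(ts - time) < 1e-9)
  if (!length(k)) stop("no snapshot stored at t = ", time,
                       "; available: ", paste(round(ts, 3), collapse = ", "))
  sim@states[[k[1]]]
}

#' Time-averaged double-edged polygon percentage
#'
#' The double-edged fraction of a frame is the number of transitioning
#' columns over the total polygon count, a double-edged pair counting as
#' one polygon; averaged over all frames after burn-in.
#'
#' @param sim a \linkS4class{TurnoverSim}.
#' @return percentage in [0, 100].
#' @export
doubleEdgedFraction <- function(sim) {
  fr <- sim@fracSeries
  keep <- fr$time_hr > sim@config@burnIn
  100 * mean(fr$n_transition[keep]) / nColumns(sim@lattice)
}

#' TJ-disappearance duration implied by turnover time and double-edged share
#'
#' At steady state a column spends \code{doubleEdgedPercent/100} of each
#' turnover period in the double-edged configuration, so the disappearance
#' duration is their product.  The nominal calibration (24 hr, 9.8%) gives
#' 2.352 hr, printed (and used by the model default) as 2.4 hr.
#'
#' @param turnoverHours mean turnover period (hr).
#' @param doubleEdgedPercent percentage of double-edged polygons.
#' @return list(exact, rounded): the raw product and its 1-decimal rounding.
#' @examples
#' calibrateDisappearance(24, 9.8)   # $exact 2.352, $rounded 2.4
#' @export
calibrateDisappearance <- function(turnoverHours, doubleEdgedPercent) {
  if (turnoverHours <= 0 || doubleEdgedPercent < 0)
    stop("turnoverHours must be positive and doubleEdgedPercent non-negative")
  exact <- turnoverHours * doubleEdgedPercent / 100
  list(exact = exact, rounded = round(exact, 1))
}

#' Per-cell SG2 residence times
#'
#' A cell enters the SG2 layer when it is promoted at a transition start
#' and differentiates to SG1 at the column's next transition start (rule
#' 3 synchronizes the two), so residence times are the intervals between
#' successive transition-start events in each column.  Only intervals
#' beginning after burn-in are kept.  The interval from a cell's promotion
#' until its TJ has fully disappeared is longer by the fixed disappearance
#' duration.
#'
#' @param sim a \linkS4class{TurnoverSim}, or an event-log data.frame with
#'   columns time_hr, column_id, event (then \code{burnIn} applies).
#' @param burnIn discard intervals starting before this time (hr).
#' @return numeric vector of residence times (hr).
#' @export
residenceTimes <- function(sim, burnIn = NULL) {
  if (is(sim, "TurnoverSim")) {
    ev <- sim@events
    if (is.null(burnIn)) burnIn <- sim@config@burnIn
  } else {
    ev <- sim
    if (!all(c("time_hr", "column_id", "event") %in% names(ev)))
      stop("event log must have time_hr, column_id, event")
    if (is.null(burnIn)) burnIn <- 0
  }
  st <- ev[ev$event == "transition_start", ]
  if (!nrow(st)) return(numeric(0))
  sp <- split(st$time_hr, st$column_id)
  res <- unlist(lapply(sp, function(v) {
    v <- sort(v); d <- diff(v)
    d[v[-length(v)] >= burnIn]
  }), use.names = FALSE)
  if (is.null(res)) numeric(0) else res
}

#' Summary of residence times
#'
#' @param sim a \linkS4class{TurnoverSim}.
#' @return data.frame(mean_hr, sem_hr, n).
#' @export
residenceSummary <- function(sim) {
  r <- residenceTimes(sim)
  data.frame(mean_hr = mean(r), sem_hr = stats::sd(r) / sqrt(length(r)),
             n = length(r))
}
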