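# The main simulation driver: alternate dry and wet phases, sample metrics
# once per cycle at the end of the wet phase, keep the element ledgers
# honest, and return a classed result object.

#' Run a wet-dry cycling simulation
#'
#' Alternates [run_dry_phase()] and [run_wet_phase()] for `n_cycles`
#' hydration-dehydration cycles, recording per-cycle system metrics and the
#' lineage registry. Runs are deterministic given (`params`, `seed`).
#'
#' @param params A [usr_params()] object.
#' @param n_cycles Cycles to run (defaults to `params$n_cycles`).
#' @param state Optional starting `usr_state` (continuation of an earlier
#'   run or loaded checkpoint); a fresh homogeneous state otherwise.
#' @param tracker Optional `species_tracker` matching `state`.
#' @param seed Seed for this run (defaults to `params$seed`).
#' @param log_events Record a typed event log (assembly, replication,
#'   hydrolysis, hop, catalysis) -- needed for event audits; off by default.
#' @param track_id Optional lineage ID whose global copy number is recorded
#'   per cycle in the history column `tracked`.
#' @param stop_when_extinct If `TRUE` together with `track_id`, the run ends
#'   at the end of the cycle in which the tracked lineage dies out.
#' @param snapshot_every Record the total polymer density grid every this
#'   many cycles (0 = never).
#' @param check_conservation Verify both element ledgers against their
#'   initial totals after every cycle (1e-6 relative tolerance) and stop on
#'   violation.
#' @return An object of class `usr_sim`: list with `params`, `history`
#'   (per-cycle metrics data frame), `lineages` ([lineages_df()]), `state`
#'   (final `usr_state`), `tracker`, `events` (data frame or `NULL`),
#'   `snapshots` (named list of matrices).
#' @examples
#' sim <- usr_simulate(usr_params(lattice_side = 4, n_cycles = 20, seed = 7))
#' tail(sim$history, 3)
#' @export
usr_simulate <- function(params,
                         n_cycles = params$n_cycles,
                         state = NULL,
                         tracker = NULL,
                         seed = params$seed,
                         log_events = FALSE,
                         track_id = NULL,
                         stop_when_extinct = FALSE,
                         snapshot_every = 0,
                         check_conservation = TRUE) {
  validate_params(params)
  if (is.null(state)) state <- init_state(params)
  if (is.null(tracker)) tracker <- new_species_tracker()
  set.seed(seed)
  log <- if (log_events) new_event_log() else NULL
  ledger0 <- conserved_totals(state, params)
  first <- state$cycle + 1L
  last <- state$cycle + as.integer(n_cycles)
  hist <- vector("list", n_cycles)
  snapshots <- list()
  i <- 0L
  cyc <- state$cycle
  while (cyc < last) {
    cyc <- cyc + 1L
    state$cycle <- cyc
    ids_before <- tracker$n
    run_dry_phase(state, params, tracker, log)
    run_wet_phase(state, params, tracker, log)
    i <- i + 1L
    hist[[i]] <- cycle_metrics(state, tracker, ids_before,
                               if (!is.null(track_id)) track_id else NA)
    if (snapshot_every > 0 && cyc %% snapshot_every == 0L)
      snapshots[[as.character(cyc)]] <- matrix(state$site_pol, state$n, state$n)
    if (check_conservation)
      assert_conserved(state, params, ledger0, cyc)
    if (!is.null(track_id) && stop_when_extinct &&
        tracker$count[track_id] <= 0) break
  }
  history <- do.call(rbind, hist[seq_len(i)])
  if (is.null(history)) history <- empty_history()
  out <- list(params = params, history = history,
              lineages = lineages_df(tracker), state = state,
              tracker = tracker,
              events = if (log_events) events_df(log) else NULL,
              snapshots = snapshots, seed = seed)
  class(out) <- "usr_sim"
  out
}

cycle_metrics <- function(state, tracker, ids_before, track_id = NA) {
  n <- tracker$n
  counts <- if (n) tracker$count[seq_len(n)] else numeric(0)
  total <- sum(state$site_pol)
  extant <- sum(counts > 0)
  df <- data.frame(
    cycle = state$cycle,
    total_population = total,
    extant_species = extant,
    avg_species_population = if (extant > 0) total / extant else 0,
    exploration = n - ids_before,
    avg_local_diversity = average_local_diversity(state),
    free_A = sum(state$A), free_B = sum(state$B),
    proto_A = sum(state$pA), proto_B = sum(state$pB)
  )
  if (!is.na(track_id)) {
    df$tracked <- if (track_id <= n) tracker$count[track_id] else 0
    # flagged lineages keep a full per-cycle series
    key <- as.character(track_id)
    tracker$series[[key]] <- c(tracker$series[[key]], df$tracked)
  }
  df
}

empty_history <- function() {
  data.frame(cycle = integer(0), total_population = numeric(0),
             extant_species = numeric(0), avg_species_population = numeric(0),
             exploration = numeric(0), avg_local_diversity = numeric(0),
             free_A = numeric(0), free_B = numeric(0),
             proto_A = numeric(0), proto_B = numeric(0))
}

assert_conserved <- function(state, params, ledger0, cyc) {
  led <- conserved_totals(state, params)
  relA <- abs(led$total_A - ledger0$total_A) / max(1, ledger0$total_A)
  relB <- abs(led$total_B - ledger0$total_B) / max(1, ledger0$total_B)
  if (relA > 1e-6 || relB > 1e-6)
    stop(sprintf(
      "element conservation violated at cycle %d (rel. drift A=%.3g B=%.3g)",
      cyc, relA, relB))
  invisible(led)
}

#' @export
print.usr_sim <- function(x, ...) {
  h <- x$history
  cat(sprintf("wet-dry cycle simulation: %d x %d lattice, %d cycles\n",
              x$params$lattice_side, x$params$lattice_side, nrow(h)))
  if (nrow(h)) {
    f <- h[nrow(h), ]
    cat(sprintf("  final: %g polymers, %d extant species, %d lineages ever\n",
                f$total_population, f$extant_species, x$tracker$n))
    cat(sprintf("  free monomers: A=%.1f B=%.1f\n", f$free_A, f$free_B))
  }
  invisible(x)
}

#' @export
summary.usr_sim <- function(object, t0 = NULL, ...) {
  h <- object$history
  if (!nrow(h)) return(invisible(object))
  if (is.null(t0)) t0 <- h$cycle[max(1L, floor(nrow(h) / 2))]
  out <- quasi_steady_state_summary(object, t0)
  cat(sprintf("quasi-steady-state window: cycles %d-%d\n", t0, max(h$cycle)))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
as.data.frame.usr_sim <- function(x, ...) x$history

#' Plot per-cycle metrics of a simulation
#'
#' @param x A `usr_sim` object.
#' @param which Metric columns to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.usr_sim <- function(x, which = c("total_population", "extant_species",
                                      "exploration", "avg_local_diversity"),
                         ...) {
  h <- x$history
  if (!nrow(h)) return(invisible(x))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in which)
    graphics::plot(h$cycle, h[[m]], type = "l", xlab = "cycle", ylab = m, ...)
  invisible(x)
}
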