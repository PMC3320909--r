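# Experiment drivers: kinetic/diffusive parameter sweeps and
# functional-synthetase selection runs.

#' Define a parameter sweep
#'
#' @param grid Data frame whose columns name `usr_params` fields (e.g. `k_r`,
#'   `k_h` or `d_m`, `d_p`); one row per grid point.
#' @param reps Independent realizations per point.
#' @param t0 First cycle of the quasi-steady-state averaging window.
#' @param base_params `usr_params` supplying all remaining fields.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(grid, reps, t0, base_params) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, reps >= 1L)
  unknown <- setdiff(names(grid), names(base_params))
  if (length(unknown))
    stop("grid columns are not parameter fields: ",
         paste(unknown, collapse = ", "))
  # validate every point up front (d_p <= d_m etc.)
  for (i in seq_len(nrow(grid)))
    do.call(update_params, c(list(base_params), as.list(grid[i, , drop = FALSE])))
  structure(list(grid = grid, reps = as.integer(reps), t0 = as.integer(t0),
                 base_params = base_params),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For every grid point, runs `reps` independent realizations (seeds derived
#' from the base seed), summarizes each over the quasi-steady-state window,
#' and reports per-point ensemble means with sample standard deviations for
#' the six system metrics.
#'
#' @param spec A [sweep_spec()].
#' @param raw Also return the per-run window averages.
#' @return Data frame with one row per grid point: the grid columns, then
#'   `<metric>_mean` and `<metric>_sd` for the six metrics. With
#'   `raw = TRUE`, a list `(summary, raw)`.
#' @export
run_sweep <- function(spec, raw = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  metrics <- c("lifetime_mean", "avg_species_population", "extant_species",
               "total_population", "exploration", "avg_local_diversity")
  per_run <- list()
  rows <- vector("list", nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    p <- do.call(update_params,
                 c(list(spec$base_params),
                   as.list(spec$grid[i, , drop = FALSE])))
    vals <- vector("list", spec$reps)
    for (r in seq_len(spec$reps)) {
      seed <- (spec$base_params$seed + 7919L * i + r) %% 2147483647L
      sim <- usr_simulate(p, seed = seed)
      q <- quasi_steady_state_summary(sim, spec$t0)
      vals[[r]] <- cbind(spec$grid[i, , drop = FALSE], rep = r,
                         q[, c(metrics, "lifetime_censored")],
                         row.names = NULL)
    }
    vals <- do.call(rbind, vals)
    per_run[[i]] <- vals
    row <- spec$grid[i, , drop = FALSE]
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(vals[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(vals[[m]])
    }
    rows[[i]] <- row
  }
  summ <- do.call(rbind, rows)
  rownames(summ) <- NULL
  if (raw) list(summary = summ, raw = do.call(rbind, per_run)) else summ
}

#' Define a synthetase inoculation
#'
#' @param kind `"A"` (A-synthetase: converts pA to A), `"B"` (B-synthetase),
#'   or `"none"` (matched nonfunctional control).
#' @param insertion_cycle Cycle at which the sequence is inserted (the base
#'   run is checkpointed there).
#' @param proto_add Proto-monomers added to every site at inoculation, before
#'   the insertion site is chosen (models tapping a previously unused
#'   resource).
#' @param k_cat Optional override of the catalysis rate constant.
#' @return Object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(kind = c("A", "B", "none"), insertion_cycle,
                        proto_add = 60, k_cat = NULL) {
  kind <- match.arg(kind)
  stopifnot(insertion_cycle >= 1, proto_add >= 0)
  structure(list(kind = kind, insertion_cycle = as.integer(insertion_cycle),
                 proto_add = as.numeric(proto_add), k_cat = k_cat),
            class = "enzyme_spec")
}

#' Inoculate a state with a single (possibly functional) sequence
#'
#' Adds the proto-monomer resource to every site, then inserts one polymer of
#' a new flagged lineage as a spontaneous-assembly event: the site is drawn
#' with probability proportional to the spontaneous-assembly propensity
#' `k_s * A * B` among sites satisfying the resource gate, and `L/2` monomers
#' of each species are consumed there.
#'
#' @param state A `usr_state` (modified in place).
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @param enzyme An [enzyme_spec()].
#' @param site Optional fixed insertion site (used for matched controls);
#'   drawn by propensity when `NULL`.
#' @param log Optional event log.
#' @return List with `id` (new lineage) and `site` (insertion site).
#' @export
inoculate <- function(state, params, tracker, enzyme, site = NULL,
                      log = NULL) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  L2 <- params$polymer_length / 2
  if (enzyme$proto_add > 0) {
    pool <- if (enzyme$kind == "B") "pB" else "pA"
    state[[pool]] <- state[[pool]] + enzyme$proto_add
  }
  if (is.null(site)) {
    w <- params$k_s * as.vector(state$A) * as.vector(state$B)
    w[as.vector(state$A) < L2 | as.vector(state$B) < L2] <- 0
    if (sum(w) <= 0)
      stop("inoculation impossible: no site satisfies the assembly gate")
    site <- wsample(w)
  }
  flag <- if (enzyme$kind == "none") "none" else enzyme$kind
  id <- apply_assembly(state, site, params, tracker, state$cycle, flag)
  if (!is.null(log)) log_event(log, state$cycle, 0, site, "inoculation", id)
  list(id = id, site = site)
}

#' Functional-selection experiment
#'
#' Runs a base (nonfunctional) simulation to the insertion cycle, then for
#' each replicate inoculates a synthetase and, from the same checkpoint and
#' at the same lattice site, a matched nonfunctional control, continuing each
#' arm until the inoculated lineage dies out (or a cycle cap). A background
#' arm continues the checkpoint without any inoculation to measure ordinary
#' species statistics under identical conditions.
#'
#' @param params Base `usr_params` (the enzyme's `k_cat` is taken from here
#'   unless the spec overrides it).
#' @param enzyme An [enzyme_spec()] with `kind` `"A"` or `"B"`.
#' @param n_runs Replicates per arm.
#' @param max_cycles Survival cap for each inoculated lineage.
#' @param control Run the matched nonfunctional arm.
#' @param background Run the no-inoculation background arm.
#' @param background_cycles Cycles for each background continuation.
#' @return Object of class `functional_experiment`: data frames `enzyme` and
#'   `control` (per replicate: `lifetime`, `censored`, `mean_population` over
#'   the lineage's lifetime, `mean_extant`, `mean_exploration`,
#'   `final_total_population`, `site`), `background` (per replicate
#'   quasi-steady-state summaries), and the checkpointed `base` run.
#' @export
functional_experiment <- function(params, enzyme, n_runs = 10,
                                  max_cycles = 10000L,
                                  control = TRUE, background = TRUE,
                                  background_cycles = 200L) {
  stopifnot(inherits(enzyme, "enzyme_spec"), enzyme$kind %in% c("A", "B"))
  if (!is.null(enzyme$k_cat)) params <- update_params(params, k_cat = enzyme$k_cat)
  base <- usr_simulate(params, n_cycles = enzyme$insertion_cycle,
                       seed = params$seed)
  arm <- function(r, kind, site) {
    st <- clone_state(base$state)
    tr <- clone_tracker(base$tracker)
    seed <- (params$seed + 104729L * r +
               if (kind == "none") 499979L else 0L) %% 2147483647L
    set.seed(seed)
    spec_r <- enzyme
    spec_r$kind <- kind
    ino <- inoculate(st, params, tr, spec_r, site = site)
    cont <- usr_simulate(params, n_cycles = max_cycles, state = st,
                         tracker = tr, seed = seed + 1L,
                         track_id = ino$id, stop_when_extinct = TRUE)
    h <- cont$history
    alive <- h$tracked > 0
    ext <- tr$extinct[ino$id]
    lifetime <- if (is.na(ext)) nrow(h) else ext - tr$birth[ino$id]
    data.frame(
      rep = r, site = ino$site, id = ino$id,
      lifetime = lifetime, censored = is.na(ext),
      mean_population = if (any(alive)) mean(h$tracked[alive]) else 0,
      mean_extant = if (any(alive)) mean(h$extant_species[alive]) else NA,
      mean_exploration = if (any(alive)) mean(h$exploration[alive]) else NA,
      final_total_population = h$total_population[nrow(h)]
    )
  }
  enz_rows <- vector("list", n_runs)
  ctl_rows <- vector("list", n_runs)
  bg_rows <- vector("list", if (background) n_runs else 0L)
  for (r in seq_len(n_runs)) {
    enz_rows[[r]] <- arm(r, enzyme$kind, site = NULL)
    if (control)
      ctl_rows[[r]] <- arm(r, "none", site = enz_rows[[r]]$site)
    if (background) {
      st <- clone_state(base$state)
      tr <- clone_tracker(base$tracker)
      seed <- (params$seed + 224737L * r) %% 2147483647L
      cont <- usr_simulate(params, n_cycles = background_cycles, state = st,
                           tracker = tr, seed = seed)
      bg_rows[[r]] <- cbind(rep = r,
                            quasi_steady_state_summary(cont,
                                                       enzyme$insertion_cycle + 1L))
    }
  }
  structure(list(enzyme = do.call(rbind, enz_rows),
                 control = if (control) do.call(rbind, ctl_rows),
                 background = if (background) do.call(rbind, bg_rows),
                 base = base, spec = enzyme, params = params),
            class = "functional_experiment")
}

#' @export
print.functional_experiment <- function(x, ...) {
  cat(sprintf("functional selection: %s-synthetase inserted at cycle %d, %d reps\n",
              x$spec$kind, x$spec$insertion_cycle, nrow(x$enzyme)))
  cat(sprintf("  synthetase lifetime: mean %.1f cycles (%d censored)\n",
              mean(x$enzyme$lifetime), sum(x$enzyme$censored)))
  if (!is.null(x$control))
    cat(sprintf("  matched control lifetime: mean %.1f cycles (%d censored)\n",
                mean(x$control$lifetime), sum(x$control$censored)))
  if (!is.null(x$background))
    cat(sprintf("  background mean species population: %.2f\n",
                mean(x$background$avg_species_population)))
  invisible(x)
}
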