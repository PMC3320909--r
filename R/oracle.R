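# Fully stochastic reference implementation.
#
# Every monomer is an explicit particle with integer per-site counts; wet
# phase monomer hops are stochastic events at rate d_m per monomer (direction
# uniform over the 4 periodic neighbours). The dry phase is identical to the
# hybrid engine's (it is already exact and keeps integer counts). Used to
# validate the hybrid engine's coarse-grained monomer transport on small
# lattices.
#
# When no catalysis channel is active, no wet-phase propensity reads a
# monomer count, so monomer random walks are independent of the polymer
# process: the polymer channels are simulated by exact SSA, and each
# monomer's endpoint is then sampled exactly (Poisson number of hops over its
# residence time, uniform steps; monomers released by hydrolysis walk only
# for the remainder of the phase). This is an exact-law shortcut, not an
# approximation. With catalysis active, the oracle falls back to full
# event-by-event SSA over all channels.

#' Run a fully stochastic simulation
#'
#' Same model as [usr_simulate()], but with explicit integer monomer
#' transport in the wet phase instead of the hybrid engine's mass-action
#' fields. Tractable only on small lattices; guarded by `cap`.
#'
#' @param params A [usr_params()] object (integer-valued initial counts
#'   required).
#' @param n_cycles Cycles to run.
#' @param seed Run seed.
#' @param cap Refusal guard: `sites * total monomer units` must not exceed
#'   this.
#' @param check_conservation Assert both element ledgers every cycle
#'   (exactly, in integers).
#' @return A `usr_sim` object (history, lineages, final state).
#' @export
oracle_simulate <- function(params, n_cycles = params$n_cycles,
                            seed = params$seed, cap = 5e7,
                            check_conservation = TRUE) {
  validate_params(params)
  for (nm in c("init_A", "init_B", "init_pA", "init_pB"))
    if (params[[nm]] != round(params[[nm]]))
      stop("oracle requires integer initial counts")
  N <- params$lattice_side^2
  load <- N * (params$init_A + params$init_B + params$init_pA + params$init_pB)
  if (N * load > cap)
    stop("oracle cap exceeded (", N * load, " > ", cap,
         "); reduce the lattice or monomer load, or raise `cap`")
  state <- init_state(params)
  tracker <- new_species_tracker()
  set.seed(seed)
  ledger0 <- conserved_totals(state, params)
  hist <- vector("list", n_cycles)
  for (i in seq_len(n_cycles)) {
    state$cycle <- state$cycle + 1L
    ids_before <- tracker$n
    run_dry_phase(state, params, tracker, NULL)
    oracle_wet_phase(state, params, tracker)
    hist[[i]] <- cycle_metrics(state, tracker, ids_before)
    if (check_conservation) {
      led <- conserved_totals(state, params)
      if (led$total_A != ledger0$total_A || led$total_B != ledger0$total_B)
        stop("oracle conservation violated at cycle ", state$cycle)
    }
  }
  out <- list(params = params, history = do.call(rbind, hist),
              lineages = lineages_df(tracker), state = state,
              tracker = tracker, events = NULL, snapshots = list(),
              seed = seed)
  class(out) <- "usr_sim"
  out
}

#' Run one fully stochastic wet phase
#'
#' @param state A `usr_state` with integer-valued monomer fields (modified
#'   in place).
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @return Invisibly, the state.
#' @export
oracle_wet_phase <- function(state, params, tracker) {
  cat_on <- params$k_cat > 0 &&
    ((sum(state$enzA) > 0 && sum(state$pA) > 0) ||
     (sum(state$enzB) > 0 && sum(state$pB) > 0))
  if (cat_on) oracle_wet_full_ssa(state, params, tracker)
  else oracle_wet_decomposed(state, params, tracker)
}

# Exact decomposition: polymer-only SSA, then independent monomer walks.
oracle_wet_decomposed <- function(state, params, tracker) {
  dur <- params$wet_duration
  k_h <- params$k_h; d_p <- params$d_p
  L2 <- params$polymer_length / 2
  rel_site <- integer(0); rel_t <- numeric(0)  # hydrolysis releases
  t <- 0
  repeat {
    P <- sum(state$site_pol)
    a_tot <- (k_h + d_p) * P
    if (a_tot <= 0) break
    t <- t + stats::rexp(1, a_tot)
    if (t > dur) break
    ev <- draw_site_lineage(state)
    if (stats::runif(1) * (k_h + d_p) < k_h) {
      # do the bookkeeping by hand: released monomers must not enter the
      # field until they have been walked for their remaining time
      apply_hydrolysis(state, ev$site, ev$id, params, tracker)
      state$A[ev$site] <- state$A[ev$site] - L2
      state$B[ev$site] <- state$B[ev$site] - L2
      rel_site <- c(rel_site, ev$site); rel_t <- c(rel_t, dur - t)
    } else {
      apply_hop(state, ev$site, ev$id, params, tracker)
    }
  }
  n <- state$n
  rel_each <- rep(rel_site, each = L2)
  rt_each <- rep(rel_t, each = L2)
  state$A <- oracle_walk_monomers(state$A, params$d_m, dur, n,
                                  rel_each, rt_each)
  state$B <- oracle_walk_monomers(state$B, params$d_m, dur, n,
                                  rel_each, rt_each)
  state$pA <- oracle_walk_monomers(state$pA, params$d_m, dur, n)
  state$pB <- oracle_walk_monomers(state$pB, params$d_m, dur, n)
  invisible(state)
}

# Walk every monomer of one species: Poisson(d*t) hops each, steps uniform
# over the 4 neighbours; extra monomers (site, time) join mid-phase.
oracle_walk_monomers <- function(M, d, dur, n, extra_sites = integer(0),
                                 extra_t = numeric(0)) {
  total <- sum(M) + length(extra_sites)
  if (total == 0) return(M)
  if (d <= 0 || n == 1L) {
    if (length(extra_sites)) {
      add <- tabulate(extra_sites, nbins = n * n)
      M <- M + matrix(add, n, n)
    }
    return(M)
  }
  s0 <- c(rep(seq_len(n * n), as.vector(M)), extra_sites)
  tt <- c(rep(dur, sum(M)), extra_t)
  hops <- stats::rpois(length(s0), d * tt)
  H <- sum(hops)
  dxt <- integer(length(s0)); dyt <- integer(length(s0))
  if (H > 0) {
    dirs <- sample.int(4L, H, replace = TRUE)
    stepx <- c(1L, -1L, 0L, 0L)[dirs]
    stepy <- c(0L, 0L, 1L, -1L)[dirs]
    m <- rep(seq_along(s0), hops)
    agg <- rowsum(cbind(stepx, stepy), m)
    idx <- as.integer(rownames(agg))
    dxt[idx] <- agg[, 1]; dyt[idx] <- agg[, 2]
  }
  r0 <- (s0 - 1L) %% n
  c0 <- (s0 - 1L) %/% n
  s1 <- ((r0 + dxt) %% n) + ((c0 + dyt) %% n) * n + 1L
  matrix(tabulate(s1, nbins = n * n), n, n)
}

# Full SSA: every monomer hop, polymer event and catalysis is an explicit
# event. Slow; used when catalysis couples monomer counts to event rates.
oracle_wet_full_ssa <- function(state, params, tracker) {
  dur <- params$wet_duration
  k_h <- params$k_h; d_p <- params$d_p; d_m <- params$d_m
  k_cat <- params$k_cat
  n <- state$n
  hop_monomer <- function(field) {
    s <- wsample(as.vector(state[[field]]))
    dest <- state$nbr[s, sample.int(4L, 1L)]
    state[[field]][s] <- state[[field]][s] - 1
    state[[field]][dest] <- state[[field]][dest] + 1
  }
  t <- 0
  repeat {
    P <- sum(state$site_pol)
    mA <- sum(state$A); mB <- sum(state$B)
    mpA <- sum(state$pA); mpB <- sum(state$pB)
    a_hyd <- k_h * P
    a_hop <- d_p * P
    a_mA <- d_m * mA; a_mB <- d_m * mB
    a_mpA <- d_m * mpA; a_mpB <- d_m * mpB
    catA <- k_cat * as.vector(state$pA) * state$enzA
    catB <- k_cat * as.vector(state$pB) * state$enzB
    a_cA <- sum(catA); a_cB <- sum(catB)
    a_tot <- a_hyd + a_hop + a_mA + a_mB + a_mpA + a_mpB + a_cA + a_cB
    if (a_tot <= 0) break
    t <- t + stats::rexp(1, a_tot)
    if (t > dur) break
    u <- stats::runif(1) * a_tot
    if (u < a_hyd) {
      ev <- draw_site_lineage(state)
      apply_hydrolysis(state, ev$site, ev$id, params, tracker)
    } else if (u < a_hyd + a_hop) {
      ev <- draw_site_lineage(state)
      apply_hop(state, ev$site, ev$id, params, tracker)
    } else if (u < a_hyd + a_hop + a_mA) {
      hop_monomer("A")
    } else if (u < a_hyd + a_hop + a_mA + a_mB) {
      hop_monomer("B")
    } else if (u < a_hyd + a_hop + a_mA + a_mB + a_mpA) {
      hop_monomer("pA")
    } else if (u < a_hyd + a_hop + a_mA + a_mB + a_mpA + a_mpB) {
      hop_monomer("pB")
    } else if (u < a_hyd + a_hop + a_mA + a_mB + a_mpA + a_mpB + a_cA) {
      apply_catalysis(state, wsample(catA), "A")
    } else {
      apply_catalysis(state, wsample(catB), "B")
    }
  }
  invisible(state)
}

#' Compare the hybrid engine with the fully stochastic oracle
#'
#' Runs `n_reps` independent realizations of both engines under identical
#' parameters and compares the end-of-run distributions of total population,
#' extant species and average local diversity with two-sample rank tests.
#'
#' @param params A `usr_params` within the oracle's tractability cap.
#' @param n_cycles Cycles per realization.
#' @param n_reps Realizations per engine.
#' @param alpha Significance level for the pass/fail verdict.
#' @param seed Base seed (hybrid uses `seed + rep`, oracle `seed + 5e5 + rep`).
#' @return Object of class `engine_comparison`: data frame `tests` with one
#'   row per statistic (`statistic`, `p_value`, `pass`), plus the raw
#'   per-rep statistic matrices.
#' @export
compare_hybrid_to_oracle <- function(params, n_cycles = 100, n_reps = 200,
                                     alpha = 0.01, seed = params$seed) {
  stat_names <- c("total_population", "extant_species", "avg_local_diversity")
  collect <- function(sim) {
    f <- sim$history[nrow(sim$history), ]
    c(total_population = f$total_population,
      extant_species = f$extant_species,
      avg_local_diversity = f$avg_local_diversity)
  }
  hyb <- matrix(NA_real_, n_reps, 3, dimnames = list(NULL, stat_names))
  orc <- matrix(NA_real_, n_reps, 3, dimnames = list(NULL, stat_names))
  for (r in seq_len(n_reps)) {
    hyb[r, ] <- collect(usr_simulate(params, n_cycles = n_cycles,
                                     seed = (seed + r) %% 2147483647L,
                                     check_conservation = FALSE))
    orc[r, ] <- collect(oracle_simulate(params, n_cycles = n_cycles,
                                        seed = (seed + 500000L + r) %% 2147483647L,
                                        check_conservation = FALSE))
  }
  tests <- do.call(rbind, lapply(stat_names, function(s) {
    p <- stats::wilcox.test(hyb[, s], orc[, s], exact = FALSE)$p.value
    data.frame(statistic = s, p_value = p, pass = p > alpha)
  }))
  structure(list(tests = tests, hybrid = hyb, oracle = orc, alpha = alpha),
            class = "engine_comparison")
}

#' @export
print.engine_comparison <- function(x, ...) {
  cat(sprintf("hybrid vs full-SSA oracle (%d reps/engine, alpha=%.3g)\n",
              nrow(x$hybrid), x$alpha))
  print(x$tests, row.names = FALSE)
  cat(if (all(x$tests$pass)) "PASS: engines statistically indistinguishable\n"
      else "FAIL: distributions differ\n")
  invisible(x)
}
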