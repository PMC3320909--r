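# Experiment drivers: the cycle driver, sweeps, inoculation, selection runs.

test_that("a zero-cycle run returns the initial state and an empty history", {
  p <- usr_params(lattice_side = 3, n_cycles = 0)
  sim <- usr_simulate(p)
  expect_equal(nrow(sim$history), 0L)
  expect_equal(sim$state$cycle, 0L)
  expect_true(all(sim$state$A == 60))
})

test_that("identically seeded runs are identical, event for event", {
  p <- usr_params(lattice_side = 4, n_cycles = 25, seed = 1234)
  a <- usr_simulate(p, log_events = TRUE)
  b <- usr_simulate(p, log_events = TRUE)
  expect_identical(a$history, b$history)
  expect_identical(a$events, b$events)
  expect_identical(a$lineages, b$lineages)
  # a different seed gives a different realization
  c <- usr_simulate(p, seed = 4321)
  expect_false(identical(a$history, c$history))
})

test_that("the population plateaus while sequence composition keeps turning over", {
  p <- usr_params(lattice_side = 8, n_cycles = 200, seed = 6)
  sim <- usr_simulate(p)
  h <- sim$history
  early <- mean(h$total_population[h$cycle %in% 96:120])
  late <- mean(h$total_population[h$cycle %in% 176:200])
  expect_lt(abs(late - early) / early, 0.25)          # plateau
  expect_gt(sum(h$exploration[h$cycle > 100]), 0)     # still exploring
  # new lineages born after the plateau was reached
  expect_gt(sum(sim$lineages$birth > 100), 0)
})

test_that("a 1x1 sweep composes run + window summary, and shapes are right", {
  base <- usr_params(lattice_side = 3, n_cycles = 30, seed = 77)
  sp <- sweep_spec(data.frame(k_h = 0.2), reps = 1, t0 = 15,
                   base_params = base)
  res <- run_sweep(sp)
  expect_equal(nrow(res), 1L)
  direct <- quasi_steady_state_summary(
    usr_simulate(update_params(base, k_h = 0.2),
                 seed = (base$seed + 7919L + 1L) %% 2147483647L), 15)
  expect_equal(res$total_population_mean, direct$total_population)
  expect_equal(res$avg_local_diversity_mean, direct$avg_local_diversity)
  # 2x2 grid, 2 reps: 4 rows, mean and sd columns for the six metrics
  grid <- expand.grid(k_r = c(0, 5e-4), k_h = c(0.1, 0.3))
  res2 <- run_sweep(sweep_spec(grid, reps = 2, t0 = 15, base_params = base))
  expect_equal(nrow(res2), 4L)
  expect_true(all(c("lifetime_mean_mean", "lifetime_mean_sd",
                    "extant_species_mean", "extant_species_sd",
                    "avg_local_diversity_mean") %in% names(res2)))
  # invalid grids are rejected up front
  expect_error(sweep_spec(data.frame(d_p = 2), 1, 10, base), "d_p")
  expect_error(sweep_spec(data.frame(bogus = 1), 1, 10, base), "bogus")
})

test_that("without replication every species has exactly one copy, ever", {
  p <- usr_params(lattice_side = 6, n_cycles = 60, k_r = 0, seed = 8)
  sim <- usr_simulate(p, log_events = TRUE)
  expect_false(any(sim$events$kind == "replication"))
  expect_true(all(sim$history$extant_species == sim$history$total_population))
  expect_true(all(sim$history$avg_species_population %in% c(0, 1)))
})

test_that("inoculation adds the proto resource then inserts by assembly propensity", {
  p <- usr_params(lattice_side = 3)
  st <- init_state(p)
  # make the site weights unequal: w proportional to A*B among gated sites
  st$A[] <- 20; st$B[] <- 20
  st$A[1] <- 40             # w1 = 2 * others
  st$A[2] <- 5              # gated out
  tr <- new_species_tracker()
  spec <- enzyme_spec("A", insertion_cycle = 5, proto_add = 60)
  set.seed(3)
  draws <- vapply(1:4000, function(i) {
    st2 <- usrsim:::clone_state(st)
    tr2 <- new_species_tracker()
    inoculate(st2, p, tr2, spec)$site
  }, integer(1))
  expect_false(any(draws == 2))
  w <- c(40 * 20, 0, rep(20 * 20, 7)); w <- w / sum(w)
  tab <- tabulate(draws, 9)
  expect_gt(stats::chisq.test(tab[-2], p = w[-2])$p.value, 0.001)
  # proto resource added to every site, insertion consumes L/2 of each monomer
  st3 <- usrsim:::clone_state(st)
  tr3 <- new_species_tracker()
  ino <- inoculate(st3, p, tr3, spec, site = 1)
  expect_true(all(st3$pA == 60))
  expect_equal(st3$A[1], 30)
  expect_equal(st3$B[1], 10)
  expect_equal(tr3$func[ino$id], "A")
  expect_equal(st3$enzA[1], 1)
  # no gated site: inoculation is impossible
  st4 <- init_state(p); st4$A[] <- 3
  expect_error(inoculate(st4, p, new_species_tracker(), spec),
               "impossible")
})

test_that("a flagged lineage with k_cat = 0 behaves like the control", {
  # the functional flag alone must not change the law of the dynamics
  p <- usr_params(lattice_side = 4, n_cycles = 40, seed = 50, k_cat = 0)
  enz <- enzyme_spec("A", insertion_cycle = 40, proto_add = 0)
  fe <- functional_experiment(p, enz, n_runs = 6, max_cycles = 150,
                              background = FALSE)
  expect_gt(stats::wilcox.test(fe$enzyme$lifetime, fe$control$lifetime,
                               exact = FALSE)$p.value, 0.01)
})

test_that("a two-synthetase scenario runs and conserves both element ledgers", {
  p <- usr_params(lattice_side = 4, n_cycles = 30, seed = 13, init_pB = 60)
  base <- usr_simulate(p)
  st <- base$state; tr <- base$tracker
  led0 <- conserved_totals(st, p)
  set.seed(4)
  inoculate(st, p, tr, enzyme_spec("A", 30, proto_add = 60))
  sim2 <- usr_simulate(p, n_cycles = 15, state = st, tracker = tr, seed = 14)
  set.seed(5)
  inoculate(sim2$state, p, tr, enzyme_spec("B", 45, proto_add = 0))
  sim3 <- usr_simulate(p, n_cycles = 15, state = sim2$state, tracker = tr,
                       seed = 15)
  led <- conserved_totals(sim3$state, p)
  expect_lt(rel_err(led$total_A, led0$total_A + 16 * 60), 1e-9)
  expect_lt(rel_err(led$total_B, led0$total_B), 1e-9)
  # proto-B pool is actually being consumed by the B-synthetase
  expect_lt(sum(sim3$state$pB), 16 * 60)
})
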