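# Hydrated-phase engine: rare-event bookkeeping, monomer diffusion, hybrid
# stepping.

test_that("hydrolysis and catalysis propensities are linear in their inputs", {
  p <- usr_params(k_h = 0.1, k_cat = 2)
  expect_equal(hydrolysis_propensity(5, p), 0.5)
  expect_equal(hydrolysis_propensity(0, p), 0)
  expect_equal(catalysis_propensity(60, 1, p), 120)
  expect_equal(catalysis_propensity(60, 0, p), 0)
})

test_that("hydrolysis recycles monomers to the same site and records extinction", {
  p <- usr_params(lattice_side = 2)
  st <- init_state(p)
  st$A[] <- 0; st$B[] <- 0
  tr <- new_species_tracker()
  seed_polymers(st, tr, data.frame(site = 1, count = 2), cycle = 1L)
  st$cycle <- 4L
  led0 <- conserved_totals(st, p)
  apply_hydrolysis(st, 1, 1L, p, tr)
  expect_equal(unname(st$pol[[1]]["1"]), 1)
  expect_equal(st$A[1], 10)
  expect_equal(st$B[1], 10)
  expect_equal(st$A[2], 0)  # strictly localized recycling
  expect_equal(conserved_totals(st, p)$total_A, led0$total_A)
  expect_true(is.na(tr$extinct[1]))
  # last copy: lineage closes with extinction = first cycle without a copy
  apply_hydrolysis(st, 1, 1L, p, tr)
  expect_identical(tr$extinct[1], 5L)
  expect_error(apply_hydrolysis(st, 1, 1L, p, tr), "absent")
})

test_that("polymers never hop when d_p = 0, and a 1x1 hop is a no-op", {
  p <- usr_params(lattice_side = 4, d_p = 0, n_cycles = 40, seed = 2)
  sim <- usr_simulate(p, log_events = TRUE)
  expect_false(any(sim$events$kind == "hop"))
  # polymers are stuck on their nucleation sites: every lineage occupies
  # exactly the site where it was born
  tab <- polymer_table(sim$state)
  born <- sim$events[sim$events$kind == "assembly", ]
  expect_true(all(tab$site == born$site[match(tab$lineage, born$lineage)]))
  # degenerate lattice: hopping returns to the same site
  p1 <- usr_params(lattice_side = 1)
  st <- init_state(p1)
  tr <- new_species_tracker()
  seed_polymers(st, tr, data.frame(site = 1, count = 1))
  set.seed(1)
  expect_equal(apply_hop(st, 1, 1L, p1, tr), 1L)
  expect_equal(unname(st$pol[[1]]["1"]), 1)
})

test_that("hop directions are uniform over the four periodic neighbours", {
  p <- usr_params(lattice_side = 5)
  st <- init_state(p)
  tr <- new_species_tracker()
  seed_polymers(st, tr, data.frame(site = 13, count = 1))
  set.seed(42)
  nbr <- st$nbr[13, ]
  tally <- setNames(numeric(4), as.character(nbr))
  for (i in 1:10000) {
    dest <- apply_hop(st, 13, 1L, p, tr)
    tally[as.character(dest)] <- tally[as.character(dest)] + 1
    # move it back
    st$pol[dest] <- list(NULL)
    st$pol[[13]] <- c("1" = 1)
    st$site_pol[] <- 0; st$site_pol[13] <- 1
  }
  expect_gt(stats::chisq.test(tally)$p.value, 0.001)
})

test_that("catalysis transfers one proto-monomer unit to the free pool", {
  p <- usr_params(lattice_side = 2, init_pA = 60)
  st <- init_state(p)
  st$A[] <- 0
  tr <- new_species_tracker()
  seed_polymers(st, tr, data.frame(site = 1, count = 1), functional = "A")
  led0 <- conserved_totals(st, p)
  apply_catalysis(st, 1, "A")
  expect_equal(st$pA[1], 59)
  expect_equal(st$A[1], 1)
  expect_equal(conserved_totals(st, p)$total_A, led0$total_A)
})

test_that("monomer diffusion is conservative, fixed on uniform fields, and exact", {
  p <- usr_params(lattice_side = 5, d_m = 1)
  U <- matrix(7, 5, 5)
  expect_equal(diffuse_monomers(U, 1, p), U)
  M <- matrix(0, 5, 5); M[13] <- 100
  out <- diffuse_monomers(M, 1, p)
  expect_equal(sum(out), 100, tolerance = 1e-12)
  expect_true(all(out >= 0))
  # independent oracle: dense matrix exponential of the 25x25 generator
  skip_if_not_installed("Matrix")
  nb <- usrsim:::make_neighbors(5)
  G <- matrix(0, 25, 25)
  for (s in 1:25) {
    G[s, s] <- -1
    for (d in nb[s, ]) G[d, s] <- G[d, s] + 0.25
  }
  ref <- as.vector(as.matrix(Matrix::expm(G)) %*% as.vector(M))
  expect_lt(max(abs(as.vector(out) - ref)), 1e-6)
  # negative input is a configuration error
  expect_error(diffuse_monomers(matrix(-1, 5, 5), 1, p), "negative")
})

test_that("with all rare-event channels off only monomers move", {
  p <- usr_params(lattice_side = 4, k_h = 0, d_p = 0, k_s = 0, k_r = 0)
  st <- init_state(p)
  st$A[1] <- 200  # inhomogeneous so diffusion is visible
  tr <- new_species_tracker()
  seed_polymers(st, tr, data.frame(site = c(2, 7), count = c(3, 1)))
  pol_before <- lapply(st$pol, identity)
  set.seed(5)
  run_wet_phase(st, p, tr)
  expect_identical(st$pol, pol_before)
  expect_lt(st$A[1], 200)                     # diffusion happened
  expect_equal(sum(st$A), 200 + 15 * 60)      # and conserved mass
})

test_that("pure decay matches the exponential closed form", {
  # P0 polymers, no assembly/replication: E[N(t)] = P0 * exp(-k_h * t)
  p <- usr_params(lattice_side = 2, k_s = 0, k_r = 0, k_h = 0.3, d_p = 0.02)
  P0 <- 40; t_end <- 3
  set.seed(60)
  finals <- vapply(1:300, function(r) {
    st <- init_state(p)
    tr <- new_species_tracker()
    seed_polymers(st, tr, data.frame(site = 1:4, count = rep(10, 4)),
                  cycle = 1L)
    for (cyc in seq_len(t_end)) {
      st$cycle <- cyc
      run_wet_phase(st, p, tr)
    }
    sum(st$site_pol)
  }, numeric(1))
  expected <- P0 * exp(-p$k_h * t_end)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se + 1e-9)
})

test_that("a saturating synthetase converts nearly all local proto-monomer", {
  # default k_cat: one enzyme converts >= 99% of its site's pA in one phase
  p <- usr_params(lattice_side = 3, init_pA = 60, d_m = 0, d_p = 0)
  set.seed(12)
  left <- vapply(1:20, function(r) {
    st <- init_state(p)
    tr <- new_species_tracker()
    seed_polymers(st, tr, data.frame(site = 5, count = 1), functional = "A")
    run_wet_phase(st, p, tr)
    st$pA[5]
  }, numeric(1))
  expect_lt(mean(left), 0.6)  # >= 99% of 60 converted in expectation
  # without the enzyme the pool is untouched
  st <- init_state(p)
  run_wet_phase(st, p, new_species_tracker())
  expect_equal(st$pA[5], 60)
})

test_that("mean species lifetime is non-increasing in the hydrolysis rate", {
  mean_life <- function(k_h, reps) {
    p <- usr_params(lattice_side = 1, k_s = 0, k_r = 0, k_h = k_h,
                    d_m = 0, d_p = 0, init_A = 0, init_B = 0)
    vapply(seq_len(reps), function(r) {
      st <- init_state(p)
      tr <- new_species_tracker()
      seed_polymers(st, tr, data.frame(site = 1, count = 1), cycle = 1L)
      cyc <- 0L
      while (tr$count[1] > 0) {
        cyc <- cyc + 1L
        st$cycle <- cyc
        run_wet_phase(st, p, tr)
      }
      tr$extinct[1] - tr$birth[1]
    }, numeric(1))
  }
  set.seed(9)
  m <- vapply(c(0.2, 0.5, 1.5), function(k) mean(mean_life(k, 800)), numeric(1))
  expect_true(all(diff(m) < 0))
})
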