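# Hydrated phase: hybrid kinetic Monte Carlo engine.
#
# Monomer (and proto-monomer) site hopping is coarse-grained as mass-action
# transport on the periodic lattice and integrated with the exact propagator
# of the discrete Laplacian (the generator is circulant, so the 2-D FFT
# diagonalizes it). Rare events -- polymer hydrolysis, polymer hopping, and
# enzymatic catalysis -- are simulated stochastically over that background:
# propensities are recomputed after every event and the monomer fields are
# advanced between events. Because hydrolysis and hopping propensities depend
# only on polymer counts, their treatment is exact; the catalysis propensity
# reads the diffusing proto-monomer field, so while a catalysis channel is
# active the exponential waiting times are additionally capped at
# `wet_substep`, the piecewise-constant propensity window of the hybrid
# scheme (the process law converges to the exact coupled law as
# `wet_substep -> 0`).

#' Hydrolysis propensity
#'
#' First-order, all-or-none degradation: `k_h * count`.
#'
#' @param count Polymer copies in the channel.
#' @param params A [usr_params()] object.
#' @return Non-negative propensity.
#' @export
hydrolysis_propensity <- function(count, params) params$k_h * count

#' Catalysis propensity
#'
#' `k_cat * proto * enzymes`: second-order conversion of a proto-monomer pool
#' by the synthetase copies on the same site.
#'
#' @param pA Proto-monomer count on the site.
#' @param enzymes Synthetase copies on the site.
#' @param params A [usr_params()] object.
#' @return Non-negative propensity.
#' @export
catalysis_propensity <- function(pA, enzymes, params) params$k_cat * pA * enzymes

#' Apply a hydrolysis event
#'
#' Removes one copy of the lineage at the site and returns its `L/2` A and
#' `L/2` B residues to the free monomer pools of the same site (localized
#' recycling). If the lineage's global copy number reaches zero its
#' extinction cycle is recorded as `cycle + 1` (the first cycle with no
#' copies).
#'
#' @param state A `usr_state` (modified in place).
#' @param site Site index.
#' @param lineage_id Lineage losing a copy.
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @return Invisibly, the state.
#' @export
apply_hydrolysis <- function(state, site, lineage_id, params, tracker) {
  nm <- as.character(lineage_id)
  v <- state$pol[[site]]
  if (is.null(v) || is.na(v[nm]) || v[nm] < 1)
    stop("internal inconsistency: hydrolysis of an absent polymer")
  L2 <- params$polymer_length / 2
  if (v[nm] > 1) v[nm] <- v[nm] - 1 else v <- v[names(v) != nm]
  state$pol[[site]] <- v
  state$site_pol[site] <- state$site_pol[site] - 1
  state$A[site] <- state$A[site] + L2
  state$B[site] <- state$B[site] + L2
  tracker$count[lineage_id] <- tracker$count[lineage_id] - 1
  if (tracker$count[lineage_id] <= 0)
    tracker$extinct[lineage_id] <- state$cycle + 1L
  fl <- tracker$func[lineage_id]
  if (fl == "A") state$enzA[site] <- state$enzA[site] - 1
  if (fl == "B") state$enzB[site] <- state$enzB[site] - 1
  invisible(state)
}

#' Apply a polymer hop
#'
#' Moves one copy of the lineage to a uniformly chosen one of the four
#' periodic neighbours.
#'
#' @inheritParams apply_hydrolysis
#' @return The destination site index.
#' @export
apply_hop <- function(state, site, lineage_id, params, tracker) {
  nm <- as.character(lineage_id)
  v <- state$pol[[site]]
  if (is.null(v) || is.na(v[nm]) || v[nm] < 1)
    stop("internal inconsistency: hop of an absent polymer")
  dest <- unname(state$nbr[site, sample.int(4L, 1L)])
  if (dest == site) return(dest)  # 1x1 lattice: a hop is a no-op
  if (v[nm] > 1) v[nm] <- v[nm] - 1 else v <- v[names(v) != nm]
  state$pol[[site]] <- v
  w <- state$pol[[dest]]
  if (is.null(w)) w <- numeric(0)
  w[nm] <- if (is.na(w[nm])) 1 else w[nm] + 1
  state$pol[[dest]] <- w
  state$site_pol[site] <- state$site_pol[site] - 1
  state$site_pol[dest] <- state$site_pol[dest] + 1
  fl <- tracker$func[lineage_id]
  if (fl == "A") {
    state$enzA[site] <- state$enzA[site] - 1
    state$enzA[dest] <- state$enzA[dest] + 1
  }
  if (fl == "B") {
    state$enzB[site] <- state$enzB[site] - 1
    state$enzB[dest] <- state$enzB[dest] + 1
  }
  dest
}

#' Apply a catalysis event
#'
#' Converts one unit of the proto-monomer pool into the corresponding free
#' monomer on the same site. With the hybrid engine's real-valued fields the
#' transferred amount is `min(1, pool)` so the pool can be drained exactly
#' without going negative.
#'
#' @param state A `usr_state` (modified in place).
#' @param site Site index.
#' @param kind `"A"` (pA -> A) or `"B"` (pB -> B).
#' @return Invisibly, the state.
#' @export
apply_catalysis <- function(state, site, kind = "A") {
  if (kind == "A") {
    amt <- min(1, state$pA[site])
    if (amt <= 0) stop("internal inconsistency: catalysis with no proto-A")
    state$pA[site] <- state$pA[site] - amt
    state$A[site] <- state$A[site] + amt
  } else {
    amt <- min(1, state$pB[site])
    if (amt <= 0) stop("internal inconsistency: catalysis with no proto-B")
    state$pB[site] <- state$pB[site] - amt
    state$B[site] <- state$B[site] + amt
  }
  invisible(state)
}

## ------------------------------------------------------- monomer diffusion

# Exact propagator of dX/dt = (d/4) sum_{y ~ x} X_y - d X on the n x n torus.
diffusion_step_matrix <- function(M, dt, d) {
  if (d <= 0 || dt <= 0) return(M)
  n <- nrow(M)
  if (n == 1L) return(M)
  lam <- cos(2 * pi * (seq_len(n) - 1L) / n)
  decay <- exp(dt * d * (outer(lam, lam, "+") / 2 - 1))
  out <- Re(stats::fft(stats::fft(M) * decay, inverse = TRUE)) / length(M)
  out[out < 0] <- 0  # FFT roundoff, magnitude ~1e-15
  out
}

#' Diffuse monomer fields
#'
#' Advances one field (or a list of fields) by the mass-action hopping law
#' `dX_x/dt = (d_m/4) * sum_{y in N(x)} X_y - d_m * X_x` over `dt`, using the
#' exact spectral propagator of the periodic-lattice Laplacian. The global
#' sum of each field is conserved to machine precision and non-negativity is
#' preserved.
#'
#' @param fields A numeric matrix, or a list of numeric matrices.
#' @param dt Time step (> 0).
#' @param params A [usr_params()] object (`d_m` is used).
#' @return Fields of the same shape, advanced by `dt`.
#' @examples
#' p <- usr_params(lattice_side = 5, d_m = 1)
#' M <- matrix(0, 5, 5); M[13] <- 100
#' sum(diffuse_monomers(M, 1, p))  # mass conserved: 100
#' @export
diffuse_monomers <- function(fields, dt, params) {
  stopifnot(dt > 0)
  step <- function(M) {
    if (any(M < 0)) stop("numerical configuration error: negative field value")
    diffusion_step_matrix(M, dt, params$d_m)
  }
  if (is.matrix(fields)) step(fields) else lapply(fields, step)
}

## --------------------------------------------------------------- the phase

# One weighted draw of (site, lineage) proportional to per-site polymer counts.
draw_site_lineage <- function(state) {
  s <- wsample(state$site_pol)
  v <- state$pol[[s]]
  k <- if (length(v) == 1L) 1L else wsample(v)
  list(site = s, id = as.integer(names(v)[k]))
}

# Advance all monomer fields in place by dt.
advance_fields <- function(state, dt, d_m) {
  if (d_m <= 0 || dt <= 0 || state$n == 1L) return(invisible(state))
  state$A <- diffusion_step_matrix(state$A, dt, d_m)
  state$B <- diffusion_step_matrix(state$B, dt, d_m)
  if (sum(state$pA) > 0) state$pA <- diffusion_step_matrix(state$pA, dt, d_m)
  if (sum(state$pB) > 0) state$pB <- diffusion_step_matrix(state$pB, dt, d_m)
  invisible(state)
}

#' Run one hydrated phase
#'
#' Advances the state by `wet_duration` with the hybrid engine: stochastic
#' hydrolysis, polymer hopping and catalysis over deterministically diffusing
#' monomer fields. See the package vignette for the operator-splitting
#' scheme and its convergence property.
#'
#' @param state A `usr_state` (modified in place).
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @param log Optional event log environment.
#' @return Invisibly, the state.
#' @export
run_wet_phase <- function(state, params, tracker, log = NULL) {
  dur <- params$wet_duration
  k_h <- params$k_h; d_p <- params$d_p; k_cat <- params$k_cat
  d_m <- params$d_m
  cyc <- state$cycle
  tcur <- 0
  repeat {
    catA_on <- k_cat > 0 && sum(state$enzA) > 0 && sum(state$pA) > 1e-12
    catB_on <- k_cat > 0 && sum(state$enzB) > 0 && sum(state$pB) > 1e-12
    dt <- min(if (catA_on || catB_on) params$wet_substep else dur,
              dur - tcur)
    tloc <- 0
    repeat {
      P <- sum(state$site_pol)
      a_h <- k_h * P
      a_p <- d_p * P
      catA <- if (catA_on) k_cat * as.vector(state$pA) * state$enzA else 0
      catB <- if (catB_on) k_cat * as.vector(state$pB) * state$enzB else 0
      a_cA <- sum(catA); a_cB <- sum(catB)
      a_tot <- a_h + a_p + a_cA + a_cB
      if (a_tot <= 0) {
        advance_fields(state, dt - tloc, d_m)
        break
      }
      w <- stats::rexp(1, a_tot)
      if (tloc + w > dt) {
        advance_fields(state, dt - tloc, d_m)
        break
      }
      advance_fields(state, w, d_m)
      tloc <- tloc + w
      u <- stats::runif(1) * a_tot
      if (u < a_h) {
        ev <- draw_site_lineage(state)
        apply_hydrolysis(state, ev$site, ev$id, params, tracker)
        if (!is.null(log))
          log_event(log, cyc, tcur + tloc, ev$site, "hydrolysis", ev$id)
      } else if (u < a_h + a_p) {
        ev <- draw_site_lineage(state)
        dest <- apply_hop(state, ev$site, ev$id, params, tracker)
        if (!is.null(log))
          log_event(log, cyc, tcur + tloc, ev$site, "hop", ev$id, dest)
      } else if (u < a_h + a_p + a_cA) {
        s <- wsample(catA)
        apply_catalysis(state, s, "A")
        if (!is.null(log)) log_event(log, cyc, tcur + tloc, s, "catalysis")
        catA_on <- sum(state$pA) > 1e-12 && sum(state$enzA) > 0
      } else {
        s <- wsample(catB)
        apply_catalysis(state, s, "B")
        if (!is.null(log)) log_event(log, cyc, tcur + tloc, s, "catalysis")
        catB_on <- sum(state$pB) > 1e-12 && sum(state$enzB) > 0
      }
    }
    tcur <- tcur + dt
    if (tcur >= dur - 1e-12) break
  }
  invisible(state)
}
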