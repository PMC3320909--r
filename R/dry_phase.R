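# Dehydrated phase: per-site Gillespie simulation of spontaneous assembly and
# universal (sequence-independent) template-directed replication.
#
# During the dry phase lattice sites are diffusively isolated, so each site is
# an independent well-mixed reactor simulated with the standard SSA:
# exponential waiting times from the total propensity, events chosen
# proportionally to their propensities, propensities recomputed after every
# event, until the elapsed time exceeds the phase duration.
#
# Resource gate: neither channel can fire on a site holding fewer than L/2
# monomers of either species -- a full-length polymer cannot be built there.
# Template sequestration: a template used for replication, and the fresh copy
# it produced (and any newly assembled polymer), are unavailable as templates
# until the next cycle.

#' Spontaneous-assembly propensity
#'
#' Second-order channel `k_s * A * B`, gated to zero when the site cannot
#' supply a full-length polymer (fewer than `L/2` monomers of either species).
#'
#' @param A,B Free monomer counts on the site.
#' @param params A [usr_params()] object.
#' @return Non-negative propensity.
#' @examples
#' assembly_propensity(60, 60, usr_params(k_s = 0.001))  # 3.6
#' @export
assembly_propensity <- function(A, B, params) {
  L2 <- params$polymer_length / 2
  if (A < L2 || B < L2) return(0)
  params$k_s * A * B
}

#' Replication propensity
#'
#' Third-order channel `k_r * A * B * templates` (templates = copies of the
#' lineage still available this dry phase), with the same resource gate as
#' assembly. The `A * B` nucleation term makes replication rate depend on
#' local resource availability, not just template abundance.
#'
#' @param A,B Free monomer counts on the site.
#' @param templates Available template count for one lineage.
#' @param params A [usr_params()] object.
#' @return Non-negative propensity.
#' @export
replication_propensity <- function(A, B, templates, params) {
  L2 <- params$polymer_length / 2
  if (A < L2 || B < L2 || templates <= 0) return(0)
  params$k_r * A * B * templates
}

#' Apply a spontaneous-assembly event
#'
#' Consumes `L/2` monomers of each species at the site, registers a fresh
#' lineage (every spontaneously assembled sequence is assumed novel) and
#' places one copy there. The new polymer is not an eligible template in the
#' current dry phase.
#'
#' @param state A `usr_state` (modified in place).
#' @param site Site index.
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @param cycle Current cycle (birth cycle of the lineage).
#' @param functional Functional flag for the new lineage (inoculation uses
#'   `"A"`/`"B"`; spontaneous assembly is `"none"`).
#' @return The new lineage ID.
#' @export
apply_assembly <- function(state, site, params, tracker, cycle,
                           functional = "none") {
  L2 <- params$polymer_length / 2
  if (state$A[site] < L2 || state$B[site] < L2)
    stop("internal inconsistency: assembly applied on a resource-gated site")
  id <- register_lineage(tracker, cycle, functional)
  state$A[site] <- state$A[site] - L2
  state$B[site] <- state$B[site] - L2
  v <- state$pol[[site]]
  if (is.null(v)) v <- numeric(0)
  v[as.character(id)] <- 1
  state$pol[[site]] <- v
  state$site_pol[site] <- state$site_pol[site] + 1
  tracker$count[id] <- 1
  if (functional == "A") state$enzA[site] <- state$enzA[site] + 1
  if (functional == "B") state$enzB[site] <- state$enzB[site] + 1
  id
}

#' Apply a template-directed replication event
#'
#' Consumes `L/2` monomers of each species, adds one copy of the lineage at
#' the site, and sequesters the used template: the lineage's available
#' template count drops by one, and the new copy is not itself available
#' until the next dry phase.
#'
#' @inheritParams apply_assembly
#' @param lineage_id Lineage being copied.
#' @return Invisibly, the state.
#' @export
apply_replication <- function(state, site, params, tracker, lineage_id) {
  L2 <- params$polymer_length / 2
  if (state$A[site] < L2 || state$B[site] < L2)
    stop("internal inconsistency: replication applied on a resource-gated site")
  nm <- as.character(lineage_id)
  av <- state$avail[[site]]
  if (is.null(av) || is.na(av[nm]) || av[nm] < 1)
    stop("internal inconsistency: replication without an available template")
  av[nm] <- av[nm] - 1
  state$avail[[site]] <- av
  state$A[site] <- state$A[site] - L2
  state$B[site] <- state$B[site] - L2
  v <- state$pol[[site]]
  v[nm] <- if (is.na(v[nm])) 1 else v[nm] + 1
  state$pol[[site]] <- v
  state$site_pol[site] <- state$site_pol[site] + 1
  tracker$count[lineage_id] <- tracker$count[lineage_id] + 1
  fl <- tracker$func[lineage_id]
  if (fl == "A") state$enzA[site] <- state$enzA[site] + 1
  if (fl == "B") state$enzB[site] <- state$enzB[site] + 1
  invisible(state)
}

#' Run one dehydrated phase
#'
#' Simulates every lattice site independently with the standard Gillespie
#' algorithm over the dry-phase duration. Available templates are snapshotted
#' from the polymer holdings at phase start. Each site consumes its own RNG
#' substream (seeded from the master stream before the sweep), so per-site
#' outcomes do not depend on site processing order.
#'
#' @param state A `usr_state` (modified in place).
#' @param params A `usr_params`.
#' @param tracker The run's `species_tracker`.
#' @param log Optional event log environment.
#' @return Invisibly, the state.
#' @export
run_dry_phase <- function(state, params, tracker, log = NULL) {
  n <- state$n
  N <- n * n
  L2 <- params$polymer_length / 2
  dur <- params$dry_duration
  k_s <- params$k_s; k_r <- params$k_r
  # template snapshot: everything standing at phase start is available
  state$avail <- lapply(state$pol, identity)
  if (k_s <= 0 && (k_r <= 0 || sum(state$site_pol) == 0)) {
    state$avail <- NULL
    return(invisible(state))
  }
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  site_seeds <- sample.int(.Machine$integer.max - 1L, N)
  master <- get(".Random.seed", envir = globalenv())
  cyc <- state$cycle
  for (s in seq_len(N)) {
    A <- state$A[s]; B <- state$B[s]
    if (A < L2 || B < L2) next
    av <- state$avail[[s]]
    Ttot <- if (length(av)) sum(av) else 0
    if (k_s <= 0 && (k_r <= 0 || Ttot <= 0)) next
    set.seed(site_seeds[s])
    t <- 0
    repeat {
      A <- state$A[s]; B <- state$B[s]
      if (A < L2 || B < L2) break
      av <- state$avail[[s]]
      Ttot <- if (length(av)) sum(av) else 0
      a_s <- k_s * A * B
      a_r <- if (Ttot > 0) k_r * A * B * Ttot else 0
      a_tot <- a_s + a_r
      if (a_tot <= 0) break
      t <- t + stats::rexp(1, a_tot)
      if (t > dur) break
      if (stats::runif(1) * a_tot < a_s) {
        id <- apply_assembly(state, s, params, tracker, cyc)
        if (!is.null(log)) log_event(log, cyc, t, s, "assembly", id)
      } else {
        k <- if (length(av) == 1L) 1L else wsample(av)
        id <- as.integer(names(av)[k])
        apply_replication(state, s, params, tracker, id)
        if (!is.null(log)) log_event(log, cyc, t, s, "replication", id)
      }
    }
  }
  assign(".Random.seed", master, envir = globalenv())
  state$avail <- NULL
  invisible(state)
}
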