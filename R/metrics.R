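# The six system metrics and spatial observables.
#
# Per-cycle metrics (sampled at end of wet phase): total population, extant
# species, exploration (new lineages that cycle), average species population
# (total/extant) and average local Shannon diversity. Window metrics:
# species lifetime statistics from the lineage registry, and quasi-steady
# state time averages.

#' Local Shannon diversity of one site
#'
#' `H = -sum p_i log(p_i)` over the lineage counts present on a site
#' (natural log, unnormalized); an empty site has `H = 0`.
#'
#' @param site_counts Named or unnamed vector of per-lineage counts.
#' @return Non-negative entropy (nats).
#' @examples
#' local_shannon_diversity(c(3, 1))  # 0.5623...
#' @export
local_shannon_diversity <- function(site_counts) {
  v <- site_counts[site_counts > 0]
  if (length(v) <= 1L) return(0)
  p <- v / sum(v)
  -sum(p * log(p))
}

#' Average local diversity of a state
#'
#' Mean of [local_shannon_diversity()] over all lattice sites; empty sites
#' contribute 0.
#'
#' @param state A `usr_state`.
#' @return Mean per-site Shannon entropy.
#' @export
average_local_diversity <- function(state) {
  H <- vapply(state$pol, function(v) {
    if (is.null(v) || length(v) == 0L) 0 else local_shannon_diversity(v)
  }, numeric(1))
  mean(H)
}

#' Species lifetime statistics over a cycle window
#'
#' A species' lifetime is the number of contiguous cycles in which at least
#' one copy existed (`extinction - birth`, with extinction recorded as the
#' first cycle without a copy). Lineages whose extinction falls inside
#' `window` enter the statistics; still-extant (censored) lineages born by the
#' window's end are excluded from the mean but counted.
#'
#' @param tracker A `species_tracker`, or the data frame from [lineages_df()].
#' @param window Numeric `c(c0, c1)` with `c1 > c0`.
#' @return List with `mean`, `sd`, `n` (closed lifetimes used) and
#'   `censored` (open lineages excluded). With `n = 0` the mean/sd are `NA`
#'   and `undefined` is `TRUE` (no exception is raised).
#' @export
species_lifetime_stats <- function(tracker, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  lin <- if (inherits(tracker, "species_tracker")) lineages_df(tracker)
         else tracker
  closed <- !is.na(lin$extinction) &
    lin$extinction >= window[1] & lin$extinction <= window[2]
  life <- lin$extinction[closed] - lin$birth[closed]
  censored <- sum(is.na(lin$extinction) & lin$birth <= window[2])
  list(mean = if (length(life)) mean(life) else NA_real_,
       sd = if (length(life) > 1L) stats::sd(life) else NA_real_,
       n = length(life), censored = censored,
       undefined = length(life) == 0L)
}

#' Quasi-steady-state summary of a run
#'
#' Time averages of the per-cycle metrics from cycle `t0` onward, plus the
#' species lifetime statistics over the same window when a lineage registry
#' is available.
#'
#' @param history Per-cycle metrics data frame (from [usr_simulate()]), or a
#'   `usr_sim` object (its lineage registry is then used for lifetimes).
#' @param t0 First cycle of the averaging window.
#' @return One-row data frame with the window means `total_population`,
#'   `extant_species`, `avg_species_population`, `exploration`,
#'   `avg_local_diversity`, and (if available) `lifetime_mean`, `lifetime_n`,
#'   `lifetime_censored`.
#' @export
quasi_steady_state_summary <- function(history, t0) {
  lin <- NULL
  if (inherits(history, "usr_sim")) {
    lin <- history$lineages
    history <- history$history
  }
  if (!nrow(history) || t0 > max(history$cycle))
    stop("t0 lies beyond the end of the recorded history")
  h <- history[history$cycle >= t0, , drop = FALSE]
  out <- data.frame(
    t0 = t0, cycles = nrow(h),
    total_population = mean(h$total_population),
    extant_species = mean(h$extant_species),
    avg_species_population = mean(h$avg_species_population),
    exploration = mean(h$exploration),
    avg_local_diversity = mean(h$avg_local_diversity)
  )
  if (!is.null(lin)) {
    ls <- species_lifetime_stats(lin, c(t0, max(history$cycle) + 1))
    out$lifetime_mean <- ls$mean
    out$lifetime_sd <- ls$sd
    out$lifetime_n <- ls$n
    out$lifetime_censored <- ls$censored
  }
  out
}

#' Label polymer clusters on a density grid
#'
#' 4-connected components of sites with density strictly above `threshold`,
#' with periodic wraparound.
#'
#' @param grid Numeric matrix of per-site polymer density.
#' @param threshold Density cut (default 0: any occupied site).
#' @return List with `labels` (integer matrix, 0 = below threshold) and
#'   `sizes` (component sizes, sorted decreasing).
#' @export
cluster_map <- function(grid, threshold = 0) {
  stopifnot(threshold >= 0, is.matrix(grid), nrow(grid) == ncol(grid))
  n <- nrow(grid)
  nbr <- make_neighbors(n)
  occupied <- as.vector(grid) > threshold
  labels <- integer(n * n)
  sizes <- integer(0)
  lab <- 0L
  for (s0 in which(occupied)) {
    if (labels[s0] > 0L) next
    lab <- lab + 1L
    queue <- s0
    labels[s0] <- lab
    size <- 0L
    while (length(queue)) {
      s <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (d in nbr[s, ]) {
        if (occupied[d] && labels[d] == 0L) {
          labels[d] <- lab
          queue <- c(queue, d)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = matrix(labels, n, n), sizes = sort(sizes, decreasing = TRUE))
}
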