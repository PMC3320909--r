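# Lattice state, lineage tracking, mass accounting, event logging, checkpoints.
#
# The state is a mutable environment so that the phase engines can update it
# in place. Monomer fields are n x n numeric matrices in column-major linear
# site indexing (site s <-> matrix element [s]); per-site polymer holdings are
# named numeric vectors (names = lineage IDs) kept strictly positive -- a
# lineage absent from the vector has zero copies on the site.

#' Initialize a simulation state
#'
#' Every lattice site receives the configured monomer and proto-monomer
#' counts; no polymers are present and the cycle clock is 0.
#'
#' @param params A [usr_params()] object.
#' @return A mutable state environment of class `usr_state`.
#' @examples
#' st <- init_state(usr_params(lattice_side = 4))
#' sum(st$A)  # 16 sites x 60 A monomers
#' @export
init_state <- function(params) {
  validate_params(params)
  n <- params$lattice_side
  N <- n * n
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$cycle <- 0L
  st$A <- matrix(params$init_A, n, n)
  st$B <- matrix(params$init_B, n, n)
  st$pA <- matrix(params$init_pA, n, n)
  st$pB <- matrix(params$init_pB, n, n)
  st$pol <- vector("list", N)          # per-site named count vectors
  st$site_pol <- numeric(N)            # cached per-site polymer totals
  st$enzA <- numeric(N)                # per-site A-synthetase copies
  st$enzB <- numeric(N)                # per-site B-synthetase copies
  st$avail <- NULL                     # templates; only set inside dry phase
  st$nbr <- make_neighbors(n)
  class(st) <- "usr_state"
  st
}

# 4-neighbour table with periodic wrap; N x 4 integer matrix of site indices.
make_neighbors <- function(n) {
  N <- n * n
  s <- seq_len(N)
  r <- (s - 1L) %% n
  c <- (s - 1L) %/% n
  up    <- ((r - 1L) %% n) + c * n + 1L
  down  <- ((r + 1L) %% n) + c * n + 1L
  left  <- r + ((c - 1L) %% n) * n + 1L
  right <- r + ((c + 1L) %% n) * n + 1L
  cbind(up, down, left, right)
}

#' @export
print.usr_state <- function(x, ...) {
  cat(sprintf("lattice state: %d x %d, cycle %d, %g polymers, %g free A, %g free B\n",
              x$n, x$n, x$cycle, sum(x$site_pol), sum(x$A), sum(x$B)))
  invisible(x)
}

# Deep copy (environments are reference objects).
clone_state <- function(st) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(st)) assign(nm, get(nm, envir = st), envir = out)
  out$pol <- lapply(st$pol, identity)
  class(out) <- "usr_state"
  out
}

## ---------------------------------------------------------------- lineage IDs

#' Create a species (lineage) tracker
#'
#' Lineage IDs are assigned in order of first appearance. The tracker records
#' each lineage's birth cycle, extinction cycle (the first cycle in which no
#' copy exists; NA while extant), functional flag, and current global copy
#' number.
#'
#' @return A mutable tracker environment of class `species_tracker`.
#' @export
new_species_tracker <- function() {
  tr <- new.env(parent = emptyenv())
  tr$n <- 0L
  tr$birth <- integer(0)
  tr$extinct <- integer(0)
  tr$func <- character(0)
  tr$count <- numeric(0)
  tr$series <- list()    # per-cycle counts, flagged lineages only
  class(tr) <- "species_tracker"
  tr
}

#' Register a new lineage
#'
#' @param tracker A [new_species_tracker()] object.
#' @param cycle Birth cycle.
#' @param functional `"none"`, `"A"` (A-synthetase) or `"B"` (B-synthetase).
#' @return The new lineage ID (integer, strictly increasing from 1).
#' @export
register_lineage <- function(tracker, cycle, functional = "none") {
  id <- tracker$n + 1L
  if (id > length(tracker$birth)) {
    grow <- max(256L, length(tracker$birth))
    length(tracker$birth) <- length(tracker$birth) + grow
    length(tracker$extinct) <- length(tracker$birth)
    length(tracker$func) <- length(tracker$birth)
    length(tracker$count) <- length(tracker$birth)
  }
  tracker$n <- id
  tracker$birth[id] <- as.integer(cycle)
  tracker$extinct[id] <- NA_integer_
  tracker$func[id] <- functional
  tracker$count[id] <- 0
  id
}

clone_tracker <- function(tr) {
  out <- new_species_tracker()
  for (nm in c("n", "birth", "extinct", "func", "count"))
    assign(nm, get(nm, envir = tr), envir = out)
  out$series <- lapply(tr$series, identity)
  out
}

#' Lineage registry as a data frame
#'
#' @param tracker A `species_tracker`.
#' @return Data frame with one row per lineage: `id`, `birth`, `extinction`
#'   (NA while extant), `functional`, `count` (current global copies).
#' @export
lineages_df <- function(tracker) {
  n <- tracker$n
  if (n == 0L)
    return(data.frame(id = integer(0), birth = integer(0),
                      extinction = integer(0), functional = character(0),
                      count = numeric(0)))
  data.frame(
    id = seq_len(n),
    birth = tracker$birth[seq_len(n)],
    extinction = tracker$extinct[seq_len(n)],
    functional = tracker$func[seq_len(n)],
    count = tracker$count[seq_len(n)]
  )
}

## ----------------------------------------------------------------- event log

new_event_log <- function() {
  lg <- new.env(parent = emptyenv())
  lg$n <- 0L
  lg$cycle <- integer(0); lg$time <- numeric(0); lg$site <- integer(0)
  lg$site2 <- integer(0); lg$kind <- character(0); lg$lineage <- integer(0)
  class(lg) <- "event_log"
  lg
}

log_event <- function(lg, cycle, time, site, kind, lineage = NA_integer_,
                      site2 = NA_integer_) {
  i <- lg$n + 1L
  if (i > length(lg$cycle)) {
    grow <- max(1024L, length(lg$cycle))
    length(lg$cycle) <- length(lg$cycle) + grow
    length(lg$time) <- length(lg$cycle); length(lg$site) <- length(lg$cycle)
    length(lg$site2) <- length(lg$cycle); length(lg$kind) <- length(lg$cycle)
    length(lg$lineage) <- length(lg$cycle)
  }
  lg$n <- i
  lg$cycle[i] <- cycle; lg$time[i] <- time; lg$site[i] <- site
  lg$site2[i] <- site2; lg$kind[i] <- kind; lg$lineage[i] <- lineage
  invisible(lg)
}

#' Event log as a data frame
#'
#' @param lg An event log produced by running a simulation with
#'   `log_events = TRUE`.
#' @return Data frame with columns `cycle`, `time` (within-phase), `site`,
#'   `site2` (hop destination, else NA), `kind`
#'   (assembly/replication/hydrolysis/hop/catalysis/inoculation), `lineage`.
#' @export
events_df <- function(lg) {
  if (is.null(lg) || lg$n == 0L)
    return(data.frame(cycle = integer(0), time = numeric(0), site = integer(0),
                      site2 = integer(0), kind = character(0),
                      lineage = integer(0)))
  i <- seq_len(lg$n)
  data.frame(cycle = lg$cycle[i], time = lg$time[i], site = lg$site[i],
             site2 = lg$site2[i], kind = lg$kind[i], lineage = lg$lineage[i])
}

## ------------------------------------------------------------- mass ledger

#' Element conservation ledger
#'
#' Sums each monomer element over its three possible states: free monomer,
#' bound as polymer residue (each polymer carries `L/2` residues of each
#' element), and proto-monomer. The totals `total_A` and `total_B` are
#' invariant over a run: hydration-dehydration cycling only moves mass
#' between the three pools.
#'
#' @param state A `usr_state`.
#' @param params The matching `usr_params`.
#' @return Object of class `mass_ledger`: free, bound and proto sums per
#'   element plus element totals.
#' @examples
#' p <- usr_params(lattice_side = 4)
#' conserved_totals(init_state(p), p)$total_A  # 16 * 60
#' @export
conserved_totals <- function(state, params) {
  L2 <- params$polymer_length / 2
  npol <- sum(state$site_pol)
  out <- list(
    free_A = sum(state$A), free_B = sum(state$B),
    bound_A = L2 * npol, bound_B = L2 * npol,
    proto_A = sum(state$pA), proto_B = sum(state$pB)
  )
  out$total_A <- out$free_A + out$bound_A + out$proto_A
  out$total_B <- out$free_B + out$bound_B + out$proto_B
  class(out) <- "mass_ledger"
  out
}

#' @export
print.mass_ledger <- function(x, ...) {
  cat(sprintf("A: free %.6g + bound %.6g + proto %.6g = %.6g\n",
              x$free_A, x$bound_A, x$proto_A, x$total_A))
  cat(sprintf("B: free %.6g + bound %.6g + proto %.6g = %.6g\n",
              x$free_B, x$bound_B, x$proto_B, x$total_B))
  invisible(x)
}

## ------------------------------------------------------------- checkpoints

#' Write a checkpoint
#'
#' Serializes parameters, the cycle clock, the four monomer grids, the
#' (site, lineage, count) polymer table and the lineage registry into a
#' directory of plain-text files (JSON + CSV). Round-trips are lossless for
#' integer-valued fields and accurate to 17 significant digits for real
#' fields.
#'
#' @param state A `usr_state`.
#' @param params The matching `usr_params`.
#' @param tracker The matching `species_tracker`.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(state, params, tracker, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(cycle = state$cycle, n = state$n),
                       file.path(dir, "state.json"), auto_unbox = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  fields <- data.frame(site = seq_len(state$n^2),
                       A = fmt(as.vector(state$A)), B = fmt(as.vector(state$B)),
                       pA = fmt(as.vector(state$pA)),
                       pB = fmt(as.vector(state$pB)))
  utils::write.csv(fields, file.path(dir, "fields.csv"), row.names = FALSE,
                   quote = FALSE)
  tab <- polymer_table(state)
  utils::write.csv(tab, file.path(dir, "polymers.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(lineages_df(tracker), file.path(dir, "lineages.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Polymer holdings as a (site, lineage, count) table
#'
#' @param state A `usr_state`.
#' @return Data frame with one row per occupied (site, lineage) pair.
#' @export
polymer_table <- function(state) {
  sites <- which(vapply(state$pol, function(v) length(v) > 0, logical(1)))
  if (!length(sites))
    return(data.frame(site = integer(0), lineage = integer(0),
                      count = numeric(0)))
  do.call(rbind, lapply(sites, function(s) {
    v <- state$pol[[s]]
    data.frame(site = s, lineage = as.integer(names(v)), count = unname(v))
  }))
}

#' Read a checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return List with elements `state` (`usr_state`), `params` (`usr_params`)
#'   and `tracker` (`species_tracker`).
#' @export
load_checkpoint <- function(dir) {
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- do.call(usr_params, pj)
  meta <- jsonlite::read_json(file.path(dir, "state.json"), simplifyVector = TRUE)
  st <- init_state(params)
  st$cycle <- as.integer(meta$cycle)
  fields <- utils::read.csv(file.path(dir, "fields.csv"))
  n <- params$lattice_side
  st$A <- matrix(as.numeric(fields$A), n, n)
  st$B <- matrix(as.numeric(fields$B), n, n)
  st$pA <- matrix(as.numeric(fields$pA), n, n)
  st$pB <- matrix(as.numeric(fields$pB), n, n)
  tracker <- new_species_tracker()
  lin <- utils::read.csv(file.path(dir, "lineages.csv"),
                         colClasses = c(functional = "character"))
  if (nrow(lin)) {
    for (i in seq_len(nrow(lin)))
      register_lineage(tracker, lin$birth[i], lin$functional[i])
    tracker$extinct[lin$id] <- ifelse(is.na(lin$extinction), NA_integer_,
                                      as.integer(lin$extinction))
    tracker$count[lin$id] <- lin$count
  }
  tab <- utils::read.csv(file.path(dir, "polymers.csv"))
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      s <- tab$site[i]; id <- as.character(tab$lineage[i])
      v <- st$pol[[s]]; if (is.null(v)) v <- numeric(0)
      v[id] <- tab$count[i]
      st$pol[[s]] <- v
    }
    st$site_pol <- vapply(st$pol, function(v) if (length(v)) sum(v) else 0,
                          numeric(1))
    refresh_enzymes(st, tracker)
  }
  list(state = st, params = params, tracker = tracker)
}

# Recompute per-site synthetase counts from the polymer table.
refresh_enzymes <- function(st, tracker) {
  N <- st$n^2
  st$enzA <- numeric(N); st$enzB <- numeric(N)
  ids_A <- which(tracker$func[seq_len(tracker$n)] == "A")
  ids_B <- which(tracker$func[seq_len(tracker$n)] == "B")
  if (!length(ids_A) && !length(ids_B)) return(invisible(st))
  for (s in seq_len(N)) {
    v <- st$pol[[s]]
    if (!length(v)) next
    ids <- as.integer(names(v))
    st$enzA[s] <- sum(v[ids %in% ids_A])
    st$enzB[s] <- sum(v[ids %in% ids_B])
  }
  invisible(st)
}

# Weighted single draw; w a non-negative vector with positive sum.
wsample <- function(w) {
  tot <- sum(w)
  u <- stats::runif(1) * tot
  cs <- cumsum(w)
  which.max(cs >= u)
}
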