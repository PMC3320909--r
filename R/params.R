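#' Simulation parameters
#'
#' Construct and validate the full parameter set for a wet-dry cycling
#' simulation. All rate constants are dimensionless, quoted per unit phase
#' time (one phase has duration 1 by default, so rates are effectively "per
#' cycle"); diffusivities are total escape rates in sites/cycle.
#'
#' @param lattice_side Sites per edge of the periodic square lattice.
#' @param polymer_length Residues per polymer; must be even (each polymer
#'   holds `polymer_length/2` A-residues and as many B-residues).
#' @param k_s Spontaneous-assembly rate constant (second order, per A.B).
#' @param k_r Replication rate constant (third order, per A.B.template).
#' @param k_h Hydrolysis rate constant (first order, per polymer).
#' @param k_cat Catalysis rate constant (second order, per proto-monomer and
#'   synthetase copy). The default is saturating: a single synthetase converts
#'   essentially all proto-monomer on its site within one wet phase.
#' @param d_m Monomer hopping rate (sites/cycle); must satisfy `d_p <= d_m`.
#' @param d_p Polymer hopping rate (sites/cycle).
#' @param init_A,init_B Monomers of each species initially on every site.
#' @param init_pA,init_pB Proto-monomers initially on every site (used by
#'   functional-selection experiments; ordinary runs leave them 0).
#' @param n_cycles Number of hydration-dehydration cycles to simulate.
#' @param dry_duration,wet_duration Phase durations (cycle fractions).
#' @param seed Integer seed for the run's random number streams.
#' @param wet_substep Propensity-refresh interval (cycles) of the hybrid
#'   wet-phase engine; only consulted while a catalysis channel is active,
#'   since no other rare-event propensity drifts between events.
#'
#' @return An object of class `usr_params` (a validated named list).
#' @examples
#' p <- usr_params(lattice_side = 4, n_cycles = 10)
#' p$k_s
#' @export
usr_params <- function(lattice_side = 16L,
                       polymer_length = 20L,
                       k_s = 1e-4,
                       k_r = 5e-4,
                       k_h = 0.1,
                       k_cat = 10,
                       d_m = 1,
                       d_p = 0.01,
                       init_A = 60,
                       init_B = 60,
                       init_pA = 0,
                       init_pB = 0,
                       n_cycles = 1000L,
                       dry_duration = 1,
                       wet_duration = 1,
                       seed = 1L,
                       wet_substep = 0.01) {
  p <- list(
    lattice_side = as.integer(lattice_side),
    polymer_length = as.integer(polymer_length),
    k_s = as.numeric(k_s), k_r = as.numeric(k_r),
    k_h = as.numeric(k_h), k_cat = as.numeric(k_cat),
    d_m = as.numeric(d_m), d_p = as.numeric(d_p),
    init_A = as.numeric(init_A), init_B = as.numeric(init_B),
    init_pA = as.numeric(init_pA), init_pB = as.numeric(init_pB),
    n_cycles = as.integer(n_cycles),
    dry_duration = as.numeric(dry_duration),
    wet_duration = as.numeric(wet_duration),
    seed = as.integer(seed),
    wet_substep = as.numeric(wet_substep)
  )
  class(p) <- "usr_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  bad <- function(msg) stop("invalid parameters: ", msg, call. = FALSE)
  if (is.na(p$lattice_side) || p$lattice_side < 1L)
    bad("lattice_side must be a positive integer")
  if (is.na(p$polymer_length) || p$polymer_length < 2L ||
      p$polymer_length %% 2L != 0L)
    bad("polymer_length must be an even integer >= 2")
  for (nm in c("k_s", "k_r", "k_h", "k_cat", "d_m", "d_p",
               "init_A", "init_B", "init_pA", "init_pB")) {
    v <- p[[nm]]
    if (!is.finite(v) || v < 0) bad(paste(nm, "must be a non-negative number"))
  }
  if (p$d_p > p$d_m)
    bad("d_p must not exceed d_m (polymers cannot out-diffuse monomers)")
  if (is.na(p$n_cycles) || p$n_cycles < 0L)
    bad("n_cycles must be a non-negative integer")
  if (!is.finite(p$dry_duration) || p$dry_duration <= 0)
    bad("dry_duration must be positive")
  if (!is.finite(p$wet_duration) || p$wet_duration <= 0)
    bad("wet_duration must be positive")
  if (is.na(p$seed)) bad("seed must be an integer")
  if (!is.finite(p$wet_substep) || p$wet_substep <= 0)
    bad("wet_substep must be positive")
  invisible(p)
}

#' @export
print.usr_params <- function(x, ...) {
  cat("Wet-dry cycle simulation parameters\n")
  cat(sprintf("  lattice: %d x %d (periodic), polymer length %d\n",
              x$lattice_side, x$lattice_side, x$polymer_length))
  cat(sprintf("  kinetics: k_s=%g  k_r=%g  k_h=%g  k_cat=%g\n",
              x$k_s, x$k_r, x$k_h, x$k_cat))
  cat(sprintf("  diffusion: d_m=%g  d_p=%g sites/cycle\n", x$d_m, x$d_p))
  cat(sprintf("  initial per site: A=%g B=%g pA=%g pB=%g\n",
              x$init_A, x$init_B, x$init_pA, x$init_pB))
  cat(sprintf("  %d cycles (dry %g + wet %g), seed %d\n",
              x$n_cycles, x$dry_duration, x$wet_duration, x$seed))
  invisible(x)
}

# Update selected fields of a parameter object, re-validating.
#' Modify simulation parameters
#'
#' @param params A `usr_params` object.
#' @param ... Named fields to replace.
#' @return A new validated `usr_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "usr_params"))
  mods <- list(...)
  unknown <- setdiff(names(mods), names(params))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(usr_params, utils::modifyList(unclass(params), mods))
}
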