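# Shared fixtures: small parameter sets used across the suite.

tiny_params <- function(...) {
  usr_params(lattice_side = 4, n_cycles = 20, seed = 42, ...)
}

# A state with a hand-placed polymer table (no engine involvement).
seed_polymers <- function(state, tracker, placements, cycle = 0L,
                          functional = "none") {
  # placements: data.frame(site, count); each row one lineage
  for (i in seq_len(nrow(placements))) {
    id <- register_lineage(tracker, cycle, functional)
    s <- placements$site[i]
    v <- state$pol[[s]]
    if (is.null(v)) v <- numeric(0)
    v[as.character(id)] <- placements$count[i]
    state$pol[[s]] <- v
    state$site_pol[s] <- state$site_pol[s] + placements$count[i]
    tracker$count[id] <- placements$count[i]
    if (functional == "A") state$enzA[s] <- state$enzA[s] + placements$count[i]
    if (functional == "B") state$enzB[s] <- state$enzB[s] + placements$count[i]
  }
  invisible(state)
}

# Relative difference helper.
rel_err <- function(a, b) abs(a - b) / max(1e-12, abs(b))
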