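# Independent event-log audits. These replay a typed event log from an empty
# lattice, reconstructing the polymer table without consulting the engine's
# own state, so they provide a second bookkeeping path.

#' Audit the once-per-cycle replication cap
#'
#' Template sequestration implies that a lineage can be copied at most as
#' many times per dry phase, per site, as it had standing copies at the
#' start of that phase. This audit replays the event log (assembly,
#' replication, hydrolysis, hop, inoculation events) from scratch and checks
#' that bound for every (cycle, site, lineage).
#'
#' @param events Event data frame from a run with `log_events = TRUE`.
#' @return List with `ok` (logical) and `violations` (data frame of
#'   offending `(cycle, site, lineage, replications, available)` rows).
#' @export
audit_replication_cap <- function(events) {
  counts <- new.env(parent = emptyenv())  # "site:lineage" -> copies
  bump <- function(s, id, d) {
    key <- paste0(s, ":", id)
    v <- counts[[key]]
    counts[[key]] <- (if (is.null(v)) 0 else v) + d
  }
  viol <- list()
  for (cyc in sort(unique(events$cycle))) {
    ev <- events[events$cycle == cyc, , drop = FALSE]
    dry <- ev[ev$kind %in% c("assembly", "replication"), , drop = FALSE]
    if (nrow(dry)) {
      repl <- dry[dry$kind == "replication", , drop = FALSE]
      if (nrow(repl)) {
        key <- paste(repl$site, repl$lineage)
        nrep <- table(key)
        for (k in names(nrep)) {
          parts <- as.integer(strsplit(k, " ")[[1]])
          avail <- counts[[paste0(parts[1], ":", parts[2])]]
          if (is.null(avail)) avail <- 0
          if (nrep[[k]] > avail)
            viol[[length(viol) + 1L]] <-
              data.frame(cycle = cyc, site = parts[1], lineage = parts[2],
                         replications = as.integer(nrep[[k]]),
                         available = avail)
        }
      }
      for (i in seq_len(nrow(dry)))
        bump(dry$site[i], dry$lineage[i], 1)
    }
    wet <- ev[ev$kind %in% c("hydrolysis", "hop", "inoculation"), ,
              drop = FALSE]
    for (i in seq_len(nrow(wet))) {
      k <- wet$kind[i]
      if (k == "hydrolysis") bump(wet$site[i], wet$lineage[i], -1)
      else if (k == "inoculation") bump(wet$site[i], wet$lineage[i], 1)
      else {
        bump(wet$site[i], wet$lineage[i], -1)
        bump(wet$site2[i], wet$lineage[i], 1)
      }
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol)
          else data.frame(cycle = integer(0), site = integer(0),
                          lineage = integer(0), replications = integer(0),
                          available = numeric(0))
  list(ok = nrow(viol) == 0L, violations = viol)
}
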