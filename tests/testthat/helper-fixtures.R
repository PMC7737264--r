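# Shared fixtures and independent oracles. Oracles deliberately use naive,
# quadratic formulations so they share no code path with the implementation.

# 13-concept biological-process excerpt: five areas
# {} (3), {Location} (3), {Part of Process} (2),
# {Location, Part of Process} (3), {Initiator BP, Location, Part of
# Process} (2), with monotone inheritance throughout.
fig2_hierarchy <- function() {
  trip <- function(src, type, tgt) {
    data.frame(source = src, type = type, target = tgt,
               stringsAsFactors = FALSE)
  }
  loc <- function(src) trip(src, "Location", "Cell")
  pop <- function(src) trip(src, "Part of Process", "Biochemical Process")
  ibp <- function(src) trip(src, "Initiator BP", "Signaling Process")
  lateral <- rbind(
    loc("Cellular Process"), loc("Cell Growth"), loc("Cell Death"),
    pop("Cancer Cell Growth Regulation"), pop("Morphogenesis"),
    loc("Cell Aging"), pop("Cell Aging"),
    loc("Replicative Senescence"), pop("Replicative Senescence"),
    loc("Cell Cycle Arrest"), pop("Cell Cycle Arrest"),
    loc("Protein Expression"), pop("Protein Expression"),
    ibp("Protein Expression"),
    loc("Protein Secretion"), pop("Protein Secretion"),
    ibp("Protein Secretion")
  )
  ids <- c("Biological Process", "Pathologic Process", "Reproductive Process",
           "Cellular Process", "Cell Growth", "Cell Death",
           "Cancer Cell Growth Regulation", "Morphogenesis",
           "Cell Aging", "Replicative Senescence", "Cell Cycle Arrest",
           "Protein Expression", "Protein Secretion")
  isa <- data.frame(
    child = c("Pathologic Process", "Reproductive Process",
              "Cellular Process", "Cell Growth", "Cell Death",
              "Cancer Cell Growth Regulation", "Morphogenesis",
              "Cell Aging", "Replicative Senescence", "Cell Cycle Arrest",
              "Protein Expression", "Protein Secretion"),
    parent = c("Biological Process", "Biological Process",
               "Biological Process", "Cellular Process", "Cellular Process",
               "Pathologic Process", "Reproductive Process",
               "Cellular Process", "Cell Aging", "Cell Aging",
               "Cell Growth", "Protein Expression"),
    stringsAsFactors = FALSE
  )
  hierarchy(data.frame(id = ids, name = ids, hierarchy = "Biological Process",
                       stringsAsFactors = FALSE),
            isa, lateral, root = "Biological Process")
}

# A single top-area IS-A chain of 7 links below the root, with two named
# waypoints at levels 5 and 7; no lateral relationships.
fig5_chain <- function() {
  ids <- c("Biological Process", "Physiological Process", "Molecular Function",
           "Binding", "Macromolecule Binding", "DNA Binding",
           "DNA Groove Binding", "DNA Major Groove Binding")
  isa <- data.frame(child = ids[-1], parent = ids[-length(ids)],
                    stringsAsFactors = FALSE)
  hierarchy(data.frame(id = ids, name = ids, hierarchy = NA),
            isa, NULL, root = ids[1L])
}

# Relationship-free hierarchy whose top area has the given number of
# concepts at levels 0, 1, 2, ...; every concept at level l hangs under the
# first concept of level l - 1.
leveled_hierarchy <- function(level_counts) {
  stopifnot(level_counts[1L] == 1L)
  ids <- unlist(lapply(seq_along(level_counts), function(l) {
    sprintf("L%02d_%03d", l - 1L, seq_len(level_counts[l]))
  }))
  level_of <- rep(seq_along(level_counts) - 1L, level_counts)
  isa <- do.call(rbind, lapply(which(level_of > 0L), function(i) {
    data.frame(child = ids[i],
               parent = sprintf("L%02d_%03d", level_of[i] - 1L, 1L),
               stringsAsFactors = FALSE)
  }))
  hierarchy(data.frame(id = ids, name = ids, hierarchy = NA),
            isa, NULL, root = ids[1L])
}

# Small random DAG hierarchy (not via the synthetic module): parent of
# concept i is uniform among earlier concepts, occasionally a second one;
# each concept gets a random subset of types (not necessarily monotone
# unless monotone = TRUE, in which case parent triples are copied down).
random_hierarchy <- function(n, types = c("Location", "Part of Process",
                                          "Initiator BP"),
                             p_type = 0.3, p_second = 0.2,
                             monotone = FALSE) {
  ids <- sprintf("N%03d", seq_len(n))
  child <- parent <- character(0)
  for (i in seq_len(n)[-1]) {
    p1 <- sample.int(i - 1L, 1L)
    child <- c(child, ids[i]); parent <- c(parent, ids[p1])
    if (i > 2L && stats::runif(1) < p_second) {
      p2 <- sample(setdiff(seq_len(i - 1L), p1), 1L)
      child <- c(child, ids[i]); parent <- c(parent, ids[p2])
    }
  }
  lateral <- data.frame(source = character(), type = character(),
                        target = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tt <- types[stats::runif(length(types)) < p_type]
    if (length(tt)) {
      lateral <- rbind(lateral, data.frame(
        source = ids[i], type = tt,
        target = paste0("T_", gsub(" ", "", tt)), stringsAsFactors = FALSE))
    }
  }
  h <- hierarchy(data.frame(id = ids, name = ids, hierarchy = NA),
                 data.frame(child = child, parent = parent,
                            stringsAsFactors = FALSE),
                 lateral, root = ids[1L])
  if (monotone) {
    # push every triple down to all descendants
    lat <- h$lateral
    for (i in seq_len(n)) {
      desc <- concept_descendants(h, ids[i])
      own <- lat[lat$source == ids[i], , drop = FALSE]
      if (length(desc) && nrow(own)) {
        for (d in desc) {
          add <- own; add$source <- d
          lat <- rbind(lat, add)
        }
      }
    }
    h <- hierarchy(h$concepts, h$isa, unique(lat), root = h$root)
  }
  h
}

# --- oracles ------------------------------------------------------------

# Concept -> sorted type-set string, one concept at a time.
oracle_area_key <- function(h, ids) {
  vapply(ids, function(cid) {
    paste(sort(unique(h$lateral$type[h$lateral$source == cid])),
          collapse = "|")
  }, character(1L))
}

# Longest path length from `id` to any of `roots` following child -> parent
# edges restricted to `members`, by exhaustive path enumeration.
oracle_longest_level <- function(id, roots, members, isa) {
  if (id %in% roots) return(0L)
  parents <- isa$parent[isa$child == id & isa$parent %in% members]
  if (!length(parents)) return(NA_integer_)
  best <- -1L
  for (p in parents) {
    sub <- oracle_longest_level(p, roots, members, isa)
    if (!is.na(sub)) best <- max(best, sub + 1L)
  }
  if (best < 0L) NA_integer_ else best
}

# Two-sided Fisher p by full enumeration of tables with the observed
# margins, point-probability rule with relative tolerance 1e-7.
oracle_fisher <- function(ct) {
  a <- ct[1, 1]; b <- ct[1, 2]; c <- ct[2, 1]; d <- ct[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
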