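#' Specification for the synthetic hierarchy generator
#'
#' The generator grows a rooted IS-A DAG by depth-penalized random
#' attachment (each new concept picks one parent among earlier concepts
#' with spare child capacity, shallow parents preferred, plus occasionally
#' a second parent), and materializes monotone relationship inheritance:
#' every concept
#' carries all of its ancestors' lateral triples and may introduce new ones
#' of its own. The defaults emulate the shape of the studied hierarchies:
#' thousands of concepts, seven relationship types, roughly 10-12 occupied
#' top-area levels, and a top area holding roughly 20-45% of the concepts.
#'
#' @param n_concepts number of hierarchy concepts (root included).
#' @param max_children maximum IS-A children per concept.
#' @param multi_parent_prob probability a concept gets a second parent.
#' @param depth_penalty attachment weight multiplier per level of parent
#'   depth (in (0, 1]); values below 1 keep the hierarchy bushy near the
#'   root. The default targets the 10-12 occupied levels observed in real
#'   hierarchies of a few thousand concepts.
#' @param type_pool relationship-type names; defaults to the seven
#'   abbreviated role names of a biological-process hierarchy.
#' @param intro_prob probability, per concept and per type, of introducing
#'   a new relationship of that type at the concept.
#' @param n_targets_per_type size of the external target pool per type.
#' @param seed optional integer seed; when set, [generate_truth()] is
#'   deterministic for the spec.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_concepts = 8000, max_children = 6,
                           multi_parent_prob = 0.15, depth_penalty = 0.65,
                           type_pool = c("Location",
                                         "Initiator Chemical or Drug",
                                         "Initiator BP",
                                         "Resulting Anatomy",
                                         "Resulting BP",
                                         "Resulting Chemical or Drug",
                                         "Part of Process"),
                           intro_prob = 0.03, n_targets_per_type = 4,
                           seed = NULL) {
  if (n_concepts < 1L) {
    stop_areatax("n_concepts must be >= 1", class = "areatax_parameter_error")
  }
  if (!length(type_pool)) {
    stop_areatax("type_pool must be non-empty",
                 class = "areatax_parameter_error")
  }
  probs <- c(multi_parent_prob, intro_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_areatax("probabilities must lie in [0, 1]",
                 class = "areatax_parameter_error")
  }
  if (max_children < 1L) {
    stop_areatax("max_children must be >= 1",
                 class = "areatax_parameter_error")
  }
  if (depth_penalty <= 0 || depth_penalty > 1) {
    stop_areatax("depth_penalty must lie in (0, 1]",
                 class = "areatax_parameter_error")
  }
  structure(
    list(n_concepts = as.integer(n_concepts),
         max_children = as.integer(max_children),
         multi_parent_prob = multi_parent_prob,
         depth_penalty = depth_penalty,
         type_pool = type_pool,
         intro_prob = intro_prob,
         n_targets_per_type = as.integer(n_targets_per_type),
         seed = seed),
    class = "generator_spec"
  )
}

#' Generate a ground-truth hierarchy
#'
#' Produces a valid, monotone-inheritance [hierarchy()] according to a
#' [generator_spec()]: relationship-type sets only grow down the IS-A
#' hierarchy ([check_monotone_inheritance()] is empty by construction).
#' Triple targets are drawn from a per-type external pool and listed in the
#' concept table as external references.
#'
#' @param spec a [generator_spec()].
#' @return a [hierarchy()].
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_concepts
  ids <- sprintf("C%05d", seq_len(n))
  n_types <- length(spec$type_pool)
  n_tgt <- spec$n_targets_per_type

  # --- IS-A structure: depth-penalized random attachment ---------------
  # A new concept picks a parent among concepts with spare child capacity,
  # with probability proportional to depth_penalty^depth. The penalty
  # keeps hierarchies bushy near the root, reproducing the ~10-12 occupied
  # levels seen in real hierarchies of this size instead of the long thin
  # chains plain uniform attachment produces. Open concepts are bucketed
  # by depth so each draw costs O(max depth).
  child1 <- integer(0)
  parent1 <- integer(0)
  if (n > 1L) {
    child_cnt <- integer(n)
    depth <- integer(n)
    buckets <- list(1L)  # buckets[[d + 1]] = open concepts at depth d
    p1 <- integer(n)
    p2 <- integer(n)
    second <- stats::runif(n) < spec$multi_parent_prob
    w <- spec$depth_penalty
    draw_parent <- function(exclude = 0L) {
      sizes <- lengths(buckets)
      if (exclude > 0L && exclude %in% buckets[[depth[exclude] + 1L]]) {
        sizes[depth[exclude] + 1L] <- sizes[depth[exclude] + 1L] - 1L
      } else {
        exclude <- 0L
      }
      wt <- sizes * w^(seq_along(sizes) - 1L)
      if (all(wt == 0)) return(0L)
      d <- sample.int(length(wt), 1L, prob = wt)
      b <- buckets[[d]]
      if (exclude > 0L) b <- b[b != exclude]
      b[sample.int(length(b), 1L)]
    }
    take_slot <- function(pick) {
      child_cnt[pick] <<- child_cnt[pick] + 1L
      if (child_cnt[pick] >= spec$max_children) {
        d <- depth[pick] + 1L
        buckets[[d]] <<- buckets[[d]][buckets[[d]] != pick]
      }
    }
    for (i in 2:n) {
      pick <- draw_parent()
      p1[i] <- pick
      take_slot(pick)
      if (second[i]) {
        pick2 <- draw_parent(exclude = pick)
        if (pick2 > 0L) {
          p2[i] <- pick2
          take_slot(pick2)
        }
      }
      depth[i] <- max(depth[p1[i]], if (p2[i] > 0L) depth[p2[i]] else 0L) + 1L
      d <- depth[i] + 1L
      if (d > length(buckets)) buckets[[d]] <- integer(0)
      buckets[[d]] <- c(buckets[[d]], i)
    }
    child1 <- c(2:n, which(p2 > 0L))
    parent1 <- c(p1[2:n], p2[p2 > 0L])
  }

  # --- introduced relationships; pair = (type, target) encoded as int --
  intro <- matrix(stats::runif(n * n_types) < spec$intro_prob, n, n_types)
  intro[1L, ] <- FALSE  # the root carries the baseline (empty) set
  tgt_idx <- matrix(sample.int(n_tgt, n * n_types, replace = TRUE),
                    n, n_types)
  pair_code <- function(type_i, tgt_i) (type_i - 1L) * n_tgt + tgt_i

  # elements start as integer(0), not NULL: `[[<-` with NULL would shrink
  # the list
  intro_pairs <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    tt <- which(intro[i, ])
    if (length(tt)) intro_pairs[[i]] <- pair_code(tt, tgt_idx[i, tt])
  }

  # --- materialize inheritance (generation order is topological) -------
  parents_of <- rep(list(integer(0)), n)
  if (length(child1)) {
    sp <- split(parent1, child1)
    parents_of[as.integer(names(sp))] <- unname(sp)
  }
  full <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    inh <- unlist(full[parents_of[[i]]], use.names = FALSE)
    own <- setdiff(intro_pairs[[i]], inh)
    intro_pairs[[i]] <- own
    full[[i]] <- unique(c(inh, own))
  }

  counts <- lengths(full)
  pairs <- unlist(full, use.names = FALSE)
  type_i <- (pairs - 1L) %/% n_tgt + 1L
  tgt_i <- (pairs - 1L) %% n_tgt + 1L
  target_ids <- target_pool_ids(spec)
  lateral <- data.frame(
    source = rep(ids, counts),
    type = spec$type_pool[type_i],
    target = target_ids[pair_code(type_i, tgt_i)],
    stringsAsFactors = FALSE
  )
  ext <- sort_c(unique(lateral$target))
  concepts <- data.frame(
    id = c(ids, ext),
    name = c(paste("Synthetic concept", seq_len(n)), ext),
    hierarchy = c(rep("Synthetic Process", n),
                  rep("External", length(ext))),
    stringsAsFactors = FALSE
  )
  isa <- data.frame(child = ids[child1], parent = ids[parent1],
                    stringsAsFactors = FALSE)
  hierarchy(concepts, isa, lateral, root = ids[1L])
}

target_pool_ids <- function(spec) {
  abbrev <- gsub("[^A-Za-z]", "", spec$type_pool)
  as.vector(t(outer(abbrev, seq_len(spec$n_targets_per_type),
                    function(a, k) paste0("T_", a, "_", k))))
}

#' Level-dependent removal-probability models
#'
#' An error model gives, for each hierarchy level ℓ (longest-path IS-A
#' distance from the hierarchy root), the probability p(ℓ) that a lateral
#' relationship introduced (authored) at a level-ℓ concept is omitted.
#' `constant_error_model()` is level-independent; `logistic_error_model()`
#' rises smoothly from `floor` to `ceiling` with depth, the
#' operationalization of "deeper concepts are more complex and more likely
#' to be under-modeled".
#'
#' @param rates either a function of the level or a numeric vector indexed
#'   by level + 1 (the last value is carried on to deeper levels).
#' @param seed optional integer seed applied when planting.
#' @return object of class `error_model` with field `p(level)`.
#' @export
error_model <- function(rates, seed = NULL) {
  p <- if (is.function(rates)) {
    rates
  } else {
    rates <- as.numeric(rates)
    function(level) rates[pmin(level + 1L, length(rates))]
  }
  probe <- p(0:20)
  if (any(probe < 0 | probe > 1)) {
    stop_areatax("removal probabilities must lie in [0, 1]",
                 class = "areatax_parameter_error")
  }
  structure(list(p = p, seed = seed), class = "error_model")
}

#' @rdname error_model
#' @param prob single removal probability used at every level.
#' @export
constant_error_model <- function(prob = 0.3, seed = NULL) {
  error_model(function(level) rep(prob, length(level)), seed = seed)
}

#' @rdname error_model
#' @param floor,ceiling removal probabilities approached at the root and at
#'   depth, respectively.
#' @param midpoint level at which the curve is halfway between the two; the
#'   default sits at the lower/higher-half boundary of the 10-12-level
#'   hierarchies [generator_spec()] produces, so the rise spans the
#'   occupied levels.
#' @param slope logistic steepness per level.
#' @export
logistic_error_model <- function(floor = 0.1, ceiling = 0.7, midpoint = 5,
                                 slope = 1, seed = NULL) {
  error_model(function(level) {
    floor + (ceiling - floor) / (1 + exp(-slope * (level - midpoint)))
  }, seed = seed)
}

# Longest-path level of every hierarchy member from the root.
hierarchy_depths <- function(h) {
  members <- hierarchy_members(h)
  lev <- integer(length(members))
  names(lev) <- members
  if (!nrow(h$isa)) return(lev)
  ord <- topo_order_parents_first(members, h$isa$child, h$isa$parent)
  idx <- seq_along(members)
  names(idx) <- members
  parents_of <- parent_index(idx, h$isa)
  for (ii in unname(idx[ord])) {
    p <- parents_of[[ii]]
    if (length(p)) lev[ii] <- max(lev[p]) + 1L
  }
  lev
}

# Integer-indexed adjacency: parent positions per member position.
parent_index <- function(idx, isa) {
  out <- rep(list(integer(0)), length(idx))
  if (nrow(isa)) {
    sp <- split(unname(idx[isa$parent]), unname(idx[isa$child]))
    out[as.integer(names(sp))] <- unname(sp)
  }
  out
}

#' Plant missing-relationship errors into a ground-truth hierarchy
#'
#' Walks the hierarchy in authoring (topological) order. Each triple
#' introduced at a concept -- i.e., not inherited from any parent -- is
#' independently omitted with probability p(ℓ) of the concept's level ℓ
#' (longest IS-A path from the hierarchy root). Inheritance is then
#' re-materialized from the surviving introductions, so the inherited
#' copies of an omitted assertion vanish from all descendants, exactly as
#' when an editor fails to author a definitional relationship.
#'
#' @param truth a monotone [hierarchy()], e.g. from [generate_truth()].
#' @param em an [error_model()].
#' @return object of class `planted_truth`: `truth`, `observed` (the
#'   damaged [hierarchy()]; identical IS-A structure), `planted`
#'   (data.frame of authoring-time omissions: `concept`, `type`, `target`,
#'   `level`) and `errors` (the full `truth` minus `observed` triple
#'   difference, which additionally contains the implicitly vanished
#'   inherited copies).
#' @export
plant_errors <- function(truth, em) {
  stopifnot(inherits(em, "error_model"))
  if (!is.null(em$seed)) set.seed(em$seed)
  members <- hierarchy_members(truth)
  depth <- hierarchy_depths(truth)
  ord <- if (nrow(truth$isa)) {
    topo_order_parents_first(members, truth$isa$child, truth$isa$parent)
  } else {
    members
  }
  # Encode each distinct (type, target) pair as an integer so the per-
  # concept set algebra below runs on integer vectors.
  idx <- seq_along(members)
  names(idx) <- members
  lat <- truth$lateral[truth$lateral$source %in% members, , drop = FALSE]
  pair_key <- paste(lat$type, lat$target, sep = "\x1f")
  pair_levels <- unique(pair_key)
  pid <- match(pair_key, pair_levels)
  full <- rep(list(integer(0)), length(members))
  sp <- split(pid, unname(idx[lat$source]))
  full[as.integer(names(sp))] <- unname(sp)
  parents_of <- parent_index(idx, truth$isa)

  observed <- rep(list(integer(0)), length(members))
  planted_concept <- integer(0)
  planted_pair <- integer(0)
  for (id in ord) {
    ii <- idx[[id]]
    pa <- parents_of[[ii]]
    inherited_truth <- unique(unlist(full[pa], use.names = FALSE))
    introduced <- setdiff(full[[ii]], inherited_truth)
    kept <- introduced
    if (length(introduced)) {
      drop <- stats::runif(length(introduced)) < em$p(depth[[ii]])
      kept <- introduced[!drop]
      if (any(drop)) {
        planted_concept <- c(planted_concept,
                             rep(ii, sum(drop)))
        planted_pair <- c(planted_pair, introduced[drop])
      }
    }
    observed[[ii]] <- unique(c(
      unlist(observed[pa], use.names = FALSE), kept))
  }

  pair_type <- sub("\x1f.*$", "", pair_levels)
  pair_target <- sub("^.*\x1f", "", pair_levels)
  counts <- lengths(observed)
  obs_pid <- unlist(observed, use.names = FALSE)
  obs_lateral <- data.frame(source = rep(members, counts),
                            type = pair_type[obs_pid],
                            target = pair_target[obs_pid],
                            stringsAsFactors = FALSE)
  observed_h <- hierarchy(truth$concepts, truth$isa, obs_lateral,
                          root = truth$root)

  planted_df <- data.frame(concept = members[planted_concept],
                           type = pair_type[planted_pair],
                           target = pair_target[planted_pair],
                           level = unname(depth[planted_concept]),
                           stringsAsFactors = FALSE)

  errors <- triple_difference(truth$lateral, observed_h$lateral)
  structure(
    list(truth = truth, observed = observed_h, planted = planted_df,
         errors = errors),
    class = "planted_truth"
  )
}

# Rows of a present in neither order in b.
triple_difference <- function(a, b) {
  ka <- paste(a$source, a$type, a$target, sep = "\x1f")
  kb <- paste(b$source, b$type, b$target, sep = "\x1f")
  out <- a[!ka %in% kb, , drop = FALSE]
  out <- out[order(out$source, out$type, out$target, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>", nrow(x$planted), "authoring-time omissions at",
      length(unique(x$planted$concept)), "concepts;",
      nrow(x$errors), "missing triples overall\n")
  invisible(x)
}

#' Simulated audit study: recovery of planted omission patterns
#'
#' Repeatedly generates a ground-truth hierarchy, plants omission errors,
#' derives the area taxonomy of the damaged (observed) hierarchy, and
#' evaluates both study hypotheses with the ground truth standing in for
#' the human reviewer: a concept is deemed erroneous when one of its own
#' authored assertions was omitted (the planted set). The top-area
#' comparison (`p_h1`) tests the full top area against a random control
#' sample of non-top concepts; the depth comparison (`p_h2`) tests the
#' higher- against the lower-indexed-half levels within the top area. Each comparison uses the
#' two-tailed Fisher's exact test.
#'
#' @param spec a [generator_spec()]; its `seed` is ignored here so that
#'   runs differ, all randomness flowing from `seed`.
#' @param em an [error_model()]; its `seed` is likewise ignored.
#' @param n_runs number of simulated studies.
#' @param alpha significance level for the rejection rates.
#' @param n_control control-sample size for the top-area comparison.
#' @param seed integer seed for the whole experiment.
#' @return object of class `recovery_summary`: per-run data.frame `runs`
#'   (`p_h1`, `p_h2`, `top_size`, `top_fraction`, `n_levels`,
#'   `n_erroneous_top`) and rejection rates `reject_h1`, `reject_h2`.
#' @export
recovery_experiment <- function(spec, em, n_runs, alpha = 0.05,
                                n_control = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec$seed <- NULL
  em$seed <- NULL
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    truth <- generate_truth(spec)
    pt <- plant_errors(truth, em)
    stopifnot(identical(
      triple_difference(pt$truth$lateral, pt$observed$lateral),
      pt$errors
    ))
    t <- derive_taxonomy(pt$observed)
    lm <- compute_levels(t, pt$observed)
    err_ids <- unique(pt$planted$concept)

    top <- t$areas[[t$top_area]]$members
    non_top <- setdiff(hierarchy_members(pt$observed), top)
    ctrl <- sample(non_top, min(n_control, length(non_top)))
    ct_h1 <- build_contingency(ctrl %in% err_ids, top %in% err_ids,
                               labels = c("non_top", "top"))
    p_h1 <- suppressWarnings(fisher_two_tailed(ct_h1))

    is_err <- top %in% err_ids
    first_type <- pt$planted$type[match(top, pt$planted$concept)]
    audits <- audit_records(
      concept_id = top,
      verdict = ifelse(is_err, "erroneous", "clean"),
      missing_type = ifelse(is_err, first_type, NA),
      reviewer = "ground_truth"
    )
    ct_h2 <- build_half_contingency(audits, lm)
    p_h2 <- suppressWarnings(fisher_two_tailed(ct_h2))

    runs[[r]] <- data.frame(
      run = r, p_h1 = p_h1, p_h2 = p_h2,
      top_size = length(top),
      top_fraction = length(top) / length(hierarchy_members(pt$observed)),
      n_levels = lm$n_levels,
      n_erroneous_top = sum(is_err)
    )
  }
  runs <- do.call(rbind, runs)
  structure(
    list(runs = runs, alpha = alpha,
         reject_h1 = mean(runs$p_h1 < alpha),
         reject_h2 = mean(runs$p_h2 < alpha)),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d runs, alpha = %.2f\n",
              nrow(x$runs), x$alpha))
  cat(sprintf("  H1 (top vs non-top) rejection rate: %.2f\n", x$reject_h1))
  cat(sprintf("  H2 (higher vs lower half) rejection rate: %.2f\n",
              x$reject_h2))
  cat(sprintf("  median top area: %.0f concepts (%.0f%%), %.0f levels\n",
              stats::median(x$runs$top_size),
              100 * stats::median(x$runs$top_fraction),
              stats::median(x$runs$n_levels)))
  invisible(x)
}
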