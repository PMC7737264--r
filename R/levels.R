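#' Longest-path levels of top-area concepts
#'
#' The level of a top-area concept is the number of IS-A links on its
#' longest path to the top-area root; the root sits at level 0 and a
#' multi-parent concept takes the longest of its paths. Levels are computed
#' in one pass over a topological order of the IS-A subgraph induced by the
#' top-area members; IS-A parents outside the top area are ignored for
#' leveling (under monotone inheritance there are none). Every area root of
#' the top area is assigned level 0, so a disconnected top area (possible
#' only for non-monotone input) still levels from all of its roots.
#'
#' @param t an [derive_taxonomy()] result.
#' @param h the [hierarchy()] the taxonomy was derived from.
#' @return object of class `level_map`: `levels` (named integer vector over
#'   top-area members), `n_levels` (count of occupied levels, including
#'   level 0), and `outside_parents` (ids of top-area members that also
#'   have an IS-A parent outside the top area, flagged because those paths
#'   are not counted).
#' @export
compute_levels <- function(t, h) {
  top <- t$areas[[t$top_area]]
  members <- top$members
  idx <- seq_along(members)
  names(idx) <- members

  inside <- h$isa$child %in% members & h$isa$parent %in% members
  edges <- h$isa[inside, , drop = FALSE]
  has_outside <- unique(h$isa$child[h$isa$child %in% members & !inside])

  lev <- integer(length(members))
  lev[] <- NA_integer_
  lev[idx[top$roots]] <- 0L
  if (nrow(edges)) {
    ord <- topo_order_parents_first(members, edges$child, edges$parent)
    parents_of <- split(idx[edges$parent], edges$child)
    for (id in ord) {
      p <- parents_of[[id]]
      if (!is.null(p)) lev[idx[id]] <- max(lev[p]) + 1L
    }
  }
  names(lev) <- members
  structure(
    list(levels = lev, n_levels = max(lev) + 1L,
         outside_parents = sort_c(has_outside)),
    class = "level_map"
  )
}

#' @export
print.level_map <- function(x, ...) {
  cat("<level_map>", length(x$levels), "top-area concepts over",
      x$n_levels, "levels\n")
  print(table(level = x$levels))
  invisible(x)
}

#' Split top-area levels into lower- and higher-indexed halves
#'
#' With n occupied levels (level 0 of the root included), the
#' higher-indexed half starts at level floor((n + 1) / 2) and runs to the
#' deepest level; the lower-indexed half is levels 0 to
#' floor((n + 1) / 2) - 1. Concepts in the higher-indexed half are farther
#' from the root, more complex, and expected to be more prone to missing
#' relationships. E.g., 10 levels split into {0..4} and {5..9}; 11 levels
#' into {0..5} and {6..10}.
#'
#' @param lm a [compute_levels()] result, or a single integer level count.
#' @return object of class `half_split`: `n_levels`, `split_start`,
#'   `lower`, `higher` (integer level vectors).
#' @export
half_split <- function(lm) {
  n <- if (inherits(lm, "level_map")) lm$n_levels else as.integer(lm)
  if (is.na(n) || n < 1L) {
    stop_areatax("need at least one level", class = "areatax_parameter_error")
  }
  split_start <- (n + 1L) %/% 2L
  structure(
    list(n_levels = n, split_start = split_start,
         lower = seq.int(0L, split_start - 1L),
         higher = if (split_start <= n - 1L) seq.int(split_start, n - 1L)
                  else integer()),
    class = "half_split"
  )
}

#' @export
print.half_split <- function(x, ...) {
  fmt <- function(v) if (!length(v)) "(none)" else
    paste0(v[1L], "..", v[length(v)])
  cat(sprintf("<half_split> n = %d: lower %s | higher %s\n",
              x$n_levels, fmt(x$lower), fmt(x$higher)))
  invisible(x)
}

#' Prioritized QA candidate list for the top area
#'
#' Orders top-area concepts for manual review: deepest level first (most
#' complex, most likely under-modeled), ties broken by concept id so review
#' batches are reproducible. With `scope = "higher"` only concepts in the
#' higher-indexed-half levels are listed.
#'
#' @param t an [derive_taxonomy()] result.
#' @param lm a [compute_levels()] result for `t`.
#' @param h optional [hierarchy()] used to attach concept names.
#' @param scope `"higher"` (default) or `"all"`.
#' @param max_candidates truncate the list to this many rows.
#' @return data.frame with columns `rank`, `id`, `name`, `level`, `half`.
#' @export
prioritize_candidates <- function(t, lm, h = NULL,
                                  scope = c("higher", "all"),
                                  max_candidates = Inf) {
  scope <- match.arg(scope)
  hs <- half_split(lm)
  lev <- lm$levels
  if (scope == "higher") lev <- lev[lev >= hs$split_start]
  ids <- names(lev)[order(-lev, names(lev), method = "radix")]
  lev <- unname(lm$levels[ids])
  nm <- rep(NA_character_, length(ids))
  if (!is.null(h)) {
    nm <- h$concepts$name[match(ids, h$concepts$id)]
  }
  out <- data.frame(
    rank = seq_along(ids), id = ids, name = nm, level = lev,
    half = ifelse(lev >= hs$split_start, "higher", "lower"),
    stringsAsFactors = FALSE
  )
  utils::head(out, n = max_candidates)
}
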