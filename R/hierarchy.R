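#' Construct an ontology hierarchy
#'
#' A hierarchy is a rooted IS-A DAG over concepts, plus the lateral
#' (non-hierarchical) relationship triples sourced at those concepts.
#' Concepts listed in `concepts` that take part in no IS-A edge and are not
#' the root are treated as external references (e.g., anatomy targets that
#' live in another hierarchy of the same ontology); they may appear as
#' triple targets but belong to no area.
#'
#' @param concepts data.frame with columns `id`, `name`, `hierarchy`
#'   (character; `name`/`hierarchy` may be `NA`).
#' @param isa data.frame with columns `child`, `parent`: one row per IS-A
#'   edge, child IS-A parent.
#' @param lateral data.frame with columns `source`, `type`, `target`: one
#'   row per lateral relationship triple.
#' @param root concept id of the unique hierarchy root.
#' @param strict if `TRUE`, reject triples whose target id is not a listed
#'   concept; the default keeps them as external references.
#' @return An object of class `hierarchy`.
#' @examples
#' h <- hierarchy(
#'   concepts = data.frame(id = c("R", "A", "X"), name = NA, hierarchy = NA),
#'   isa      = data.frame(child = "A", parent = "R"),
#'   lateral  = data.frame(source = "A", type = "Location", target = "X"),
#'   root     = "R"
#' )
#' hierarchy_members(h)
#' @export
hierarchy <- function(concepts, isa, lateral = NULL, root, strict = FALSE) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (!all(c("id") %in% names(concepts))) {
    stop_areatax("concepts must have an 'id' column", class = "areatax_format_error")
  }
  if (is.null(concepts$name)) concepts$name <- NA_character_
  if (is.null(concepts$hierarchy)) concepts$hierarchy <- NA_character_
  concepts <- concepts[, c("id", "name", "hierarchy")]
  concepts$id <- as.character(concepts$id)
  concepts$name <- as.character(concepts$name)
  concepts$hierarchy <- as.character(concepts$hierarchy)

  if (is.null(isa) || nrow(as.data.frame(isa)) == 0L) {
    isa <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  } else {
    isa <- as.data.frame(isa, stringsAsFactors = FALSE)
    isa <- data.frame(child = as.character(isa$child),
                      parent = as.character(isa$parent),
                      stringsAsFactors = FALSE)
  }
  if (is.null(lateral) || nrow(as.data.frame(lateral)) == 0L) {
    lateral <- data.frame(source = character(), type = character(),
                          target = character(), stringsAsFactors = FALSE)
  } else {
    lateral <- as.data.frame(lateral, stringsAsFactors = FALSE)
    lateral <- data.frame(source = as.character(lateral$source),
                          type = as.character(lateral$type),
                          target = as.character(lateral$target),
                          stringsAsFactors = FALSE)
  }
  lateral <- unique(lateral)
  isa <- unique(isa)
  rownames(concepts) <- NULL
  rownames(isa) <- NULL
  rownames(lateral) <- NULL

  h <- structure(
    list(concepts = concepts, isa = isa, lateral = lateral,
         root = as.character(root)),
    class = "hierarchy"
  )
  validate_hierarchy(h, strict = strict)
}

#' @export
print.hierarchy <- function(x, ...) {
  m <- hierarchy_members(x)
  cat("<hierarchy> root:", x$root, "\n")
  cat("  concepts:", nrow(x$concepts),
      sprintf("(%d in hierarchy, %d external refs)",
              length(m), nrow(x$concepts) - length(m)), "\n")
  cat("  IS-A edges:", nrow(x$isa), " lateral triples:", nrow(x$lateral), "\n")
  invisible(x)
}

#' Validate a hierarchy
#'
#' Checks id uniqueness, referential integrity of IS-A edges and triples,
#' acyclicity, and that the root is the unique top from which every
#' in-hierarchy concept is reachable.
#'
#' @param h a [hierarchy()].
#' @param strict reject triples with unlisted target ids.
#' @return `h`, invisibly usable, after passing all checks.
#' @export
validate_hierarchy <- function(h, strict = FALSE) {
  ids <- h$concepts$id
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop_areatax("concept ids must be non-empty", class = "areatax_format_error")
  }
  if (anyDuplicated(ids)) {
    stop_areatax("duplicate concept id: ", ids[duplicated(ids)][1L],
                 class = "areatax_format_error")
  }
  if (!h$root %in% ids) {
    stop_areatax("root id '", h$root, "' is not a listed concept",
                 class = "areatax_lookup_error")
  }
  bad <- setdiff(c(h$isa$child, h$isa$parent), ids)
  if (length(bad)) {
    stop_areatax("IS-A edge references unknown concept id: ", bad[1L],
                 class = "areatax_load_error")
  }
  bad <- setdiff(h$lateral$source, ids)
  if (length(bad)) {
    stop_areatax("lateral triple sourced at unknown concept id: ", bad[1L],
                 class = "areatax_load_error")
  }
  if (strict) {
    bad <- setdiff(h$lateral$target, ids)
    if (length(bad)) {
      stop_areatax("lateral triple targets unknown concept id: ", bad[1L],
                   class = "areatax_load_error")
    }
  }
  if (h$root %in% h$isa$child) {
    stop_areatax("root '", h$root, "' has an IS-A parent",
                 class = "areatax_structural_error")
  }
  if (nrow(h$isa)) {
    g <- isa_graph(h)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      member <- igraph::ends(g, cyc[1L])[1L]
      stop_areatax("IS-A cycle detected involving concept '", member, "'",
                   class = "areatax_structural_error")
    }
    members <- hierarchy_members(h)
    involved <- unique(c(h$isa$child, h$isa$parent, h$root))
    unreachable <- setdiff(involved, members)
    if (length(unreachable)) {
      stop_areatax("concept '", unreachable[1L],
                   "' is not reachable from root '", h$root, "'",
                   class = "areatax_structural_error")
    }
  }
  h
}

# igraph over IS-A edges, directed child -> parent.
isa_graph <- function(h) {
  verts <- unique(c(h$root, h$isa$child, h$isa$parent))
  igraph::graph_from_data_frame(
    data.frame(from = h$isa$child, to = h$isa$parent, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
}

#' Concepts belonging to the hierarchy proper
#'
#' Returns the root and all concepts reachable from it by following IS-A
#' edges downwards, i.e., every concept that participates in the hierarchy
#' (as opposed to external reference targets).
#'
#' @param h a [hierarchy()].
#' @return character vector of concept ids.
#' @export
hierarchy_members <- function(h) {
  if (!nrow(h$isa)) return(h$root)
  g <- isa_graph(h)
  as.character(igraph::subcomponent(g, h$root, mode = "in")$name)
}

#' IS-A descendants of a concept
#'
#' @param h a [hierarchy()].
#' @param id concept id.
#' @param include_self include `id` itself in the result.
#' @return character vector of descendant concept ids.
#' @export
concept_descendants <- function(h, id, include_self = FALSE) {
  if (!id %in% h$concepts$id) {
    stop_areatax("unknown concept id: ", id, class = "areatax_lookup_error")
  }
  if (!nrow(h$isa) || !id %in% c(h$isa$child, h$isa$parent, h$root)) {
    return(if (include_self) id else character())
  }
  g <- isa_graph(h)
  d <- as.character(igraph::subcomponent(g, id, mode = "in")$name)
  if (include_self) d else setdiff(d, id)
}

#' Lateral relationship type set of each concept
#'
#' A concept's type set is the set of relationship-type names over the
#' triples sourced at it (targets and multiplicity ignored). Concepts with
#' no triples have the empty set.
#'
#' @param h a [hierarchy()].
#' @param ids concept ids to report (default: all hierarchy members).
#' @return named list of character vectors (sorted, unique type names).
#' @export
rel_type_sets <- function(h, ids = hierarchy_members(h)) {
  lat <- h$lateral[h$lateral$source %in% ids, c("source", "type")]
  sets <- lapply(split(lat$type, factor(lat$source, levels = ids)),
                 function(tt) sort_c(unique(tt)))
  names(sets) <- ids
  sets
}

# Canonical area name for a type set: "{}" or "{t1, t2, ...}" with types in
# byte order, matching how areas are labeled in taxonomy diagrams.
type_set_name <- function(types) {
  paste0("{", paste(sort_c(unique(types)), collapse = ", "), "}")
}

#' Extract the subhierarchy rooted at a concept
#'
#' Keeps `root_id` and all of its IS-A descendants; IS-A edges are restricted
#' to retained concepts and lateral triples are retained when their source is
#' retained. External reference concepts that remain triple targets are kept
#' in the concept table.
#'
#' @param h a [hierarchy()].
#' @param root_id concept id of the new root.
#' @return a [hierarchy()] rooted at `root_id`.
#' @export
extract_subhierarchy <- function(h, root_id) {
  keep <- concept_descendants(h, root_id, include_self = TRUE)
  isa <- h$isa[h$isa$child %in% keep & h$isa$parent %in% keep, , drop = FALSE]
  lateral <- h$lateral[h$lateral$source %in% keep, , drop = FALSE]
  ext <- setdiff(intersect(lateral$target, h$concepts$id), keep)
  concepts <- h$concepts[h$concepts$id %in% c(keep, ext), , drop = FALSE]
  hierarchy(concepts, isa, lateral, root = root_id)
}

#' Check that lateral relationship types are inherited monotonically
#'
#' Under faithful modeling, a concept carries at least the relationship
#' types of each of its IS-A parents (descendants only add types). This
#' check reports every IS-A edge violating that assumption; an empty result
#' means taxonomy levels and top-area connectivity behave as expected (the
#' top area is ancestor-closed, has a single root, and child-of links point
#' from larger to smaller type sets).
#'
#' @param h a [hierarchy()].
#' @return data.frame with columns `child`, `parent`, `missing_types`
#'   (comma-separated parent types absent from the child); zero rows when
#'   inheritance is monotone.
#' @export
check_monotone_inheritance <- function(h) {
  members <- hierarchy_members(h)
  sets <- rel_type_sets(h, members)
  isa <- h$isa[h$isa$child %in% members & h$isa$parent %in% members, , drop = FALSE]
  if (!nrow(isa)) {
    return(data.frame(child = character(), parent = character(),
                      missing_types = character(), stringsAsFactors = FALSE))
  }
  missing <- mapply(function(ch, pa) {
    m <- setdiff(sets[[pa]], sets[[ch]])
    if (length(m)) paste(m, collapse = ", ") else NA_character_
  }, isa$child, isa$parent)
  bad <- !is.na(missing)
  data.frame(child = isa$child[bad], parent = isa$parent[bad],
             missing_types = unname(missing[bad]), stringsAsFactors = FALSE)
}
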