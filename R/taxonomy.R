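#' Derive the areas of a hierarchy
#'
#' An area is the non-empty set of all hierarchy concepts having exactly
#' the same set of lateral-relationship types. Areas partition the
#' hierarchy's concepts; external reference concepts (triple targets from
#' other hierarchies) belong to no area. Each area is named canonically as
#' `"{t1, t2, ...}"` with the types in byte order.
#'
#' @param h a [hierarchy()].
#' @return named list of `area` objects, each with fields `name`, `types`
#'   (character vector), `members` and (once computed) `roots`.
#' @export
derive_areas <- function(h) {
  members <- hierarchy_members(h)
  key <- type_set_keys(h, members)
  groups <- split(members, key)
  areas <- lapply(names(groups), function(nm) {
    structure(
      list(name = nm,
           types = parse_type_set_name(nm),
           members = sort_c(groups[[nm]]),
           roots = NULL),
      class = "area"
    )
  })
  names(areas) <- names(groups)
  areas[sort_c(names(areas))]
}

# Canonical area name per concept, vectorized.
type_set_keys <- function(h, members) {
  lat <- unique(h$lateral[h$lateral$source %in% members,
                          c("source", "type"), drop = FALSE])
  key <- rep("{}", length(members))
  names(key) <- members
  if (nrow(lat)) {
    lat <- lat[order(lat$source, lat$type, method = "radix"), , drop = FALSE]
    nm <- vapply(split(lat$type, lat$source),
                 function(tt) paste0("{", paste(tt, collapse = ", "), "}"),
                 character(1L))
    key[names(nm)] <- nm
  }
  key
}

parse_type_set_name <- function(nm) {
  inner <- sub("^\\{", "", sub("\\}$", "", nm))
  if (!nzchar(inner)) character() else strsplit(inner, ", ", fixed = TRUE)[[1L]]
}

#' Roots of an area
#'
#' A root of an area is a member concept having no IS-A parent inside the
#' same area.
#'
#' @param area an `area` from [derive_areas()].
#' @param h the [hierarchy()] the area was derived from.
#' @return character vector of concept ids.
#' @export
compute_area_roots <- function(area, h) {
  inside <- h$isa$child %in% area$members & h$isa$parent %in% area$members
  sort_c(setdiff(area$members, h$isa$child[inside]))
}

#' Derive child-of links between areas
#'
#' An area A is child-of an area B when some root of A has an IS-A parent
#' in B. Links may skip display levels (a child area can add several
#' relationship types at once).
#'
#' @param areas named list of areas with roots computed.
#' @param h the [hierarchy()].
#' @return data.frame with columns `child`, `parent` (canonical area names).
#' @export
derive_child_of <- function(areas, h) {
  area_of <- rep(names(areas), lengths(lapply(areas, `[[`, "members")))
  names(area_of) <- unlist(lapply(areas, `[[`, "members"), use.names = FALSE)
  links <- lapply(areas, function(a) {
    parents <- h$isa$parent[h$isa$child %in% a$roots]
    parents <- unique(area_of[parents])
    if (!length(parents)) return(NULL)
    data.frame(child = a$name, parent = unname(parents),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, c(links, list(
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)))))
  out <- out[order(out$child, out$parent, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive the area taxonomy of a hierarchy
#'
#' Composes area derivation, area-root computation and child-of derivation
#' into the full abstraction network. The display level of an area is the
#' size of its type set. The top area is the area whose type set equals the
#' hierarchy root's own type set: the empty set for a full hierarchy
#' (`mode = "full"`), the subhierarchy root's inherited set for a
#' subtaxonomy (`mode = "sub"`); both are instances of the one rule
#' "baseline = root's type set".
#'
#' @param h a [hierarchy()] (for `mode = "sub"`, typically the result of
#'   [extract_subhierarchy()]).
#' @param mode `"full"` or `"sub"`; recorded on the result and reflected in
#'   printing, the derivation itself is identical.
#' @return an object of class `area_taxonomy`: fields `areas`, `child_of`,
#'   `display_level`, `top_area` (canonical name), `root`, `mode`.
#' @examples
#' h <- hierarchy(
#'   concepts = data.frame(id = c("R", "A", "B", "X")),
#'   isa = data.frame(child = c("A", "B"), parent = c("R", "A")),
#'   lateral = data.frame(source = c("A", "B"), type = "Location",
#'                        target = "X"),
#'   root = "R"
#' )
#' t <- derive_taxonomy(h)
#' area_table(t)
#' @export
derive_taxonomy <- function(h, mode = c("full", "sub")) {
  mode <- match.arg(mode)
  areas <- derive_areas(h)
  for (nm in names(areas)) {
    areas[[nm]]$roots <- compute_area_roots(areas[[nm]], h)
  }
  child_of <- derive_child_of(areas, h)
  display_level <- vapply(areas, function(a) length(a$types), integer(1L))
  baseline <- type_set_name(rel_type_sets(h, h$root)[[h$root]])
  if (is.null(areas[[baseline]])) {
    stop_areatax("baseline area ", baseline, " (the root's type set) ",
                 "is not present; cannot identify a top area",
                 class = "areatax_derivation_error")
  }
  structure(
    list(areas = areas, child_of = child_of, display_level = display_level,
         top_area = baseline, root = h$root, mode = mode),
    class = "area_taxonomy"
  )
}

#' @export
print.area_taxonomy <- function(x, ...) {
  n <- sum(lengths(lapply(x$areas, `[[`, "members")))
  top <- x$areas[[x$top_area]]
  cat(sprintf("<area %s> %d areas over %d concepts (root: %s)\n",
              if (x$mode == "sub") "subtaxonomy" else "taxonomy",
              length(x$areas), n, x$root))
  cat(sprintf("  top area %s: %d concepts (%.1f%%)\n", x$top_area,
              length(top$members), 100 * length(top$members) / n))
  cat("  child-of links:", nrow(x$child_of), "\n")
  invisible(x)
}

#' Area membership lookup
#'
#' @param t an [derive_taxonomy()] result.
#' @return named character vector mapping concept id to canonical area name.
#' @export
area_of_concept <- function(t) {
  out <- rep(names(t$areas), lengths(lapply(t$areas, `[[`, "members")))
  names(out) <- unlist(lapply(t$areas, `[[`, "members"), use.names = FALSE)
  out
}

#' Top-area size metrics and anomaly flag
#'
#' A disproportionately large top area signals widespread under-modeling:
#' many concepts carrying none of the relationships expected for the
#' hierarchy. Hierarchies whose top area exceeds the upper band limit are
#' intentionally left almost entirely primitive by their curators, and the
#' flag is not raised for them.
#'
#' @param t an [derive_taxonomy()] result.
#' @param band numeric length-2, lower and upper top-area fraction limits
#'   within which the top area is deemed anomalous. The defaults (0.04,
#'   0.90) reflect that published taxonomies with 1-2% top areas are
#'   unremarkable while ~4.4% and up were judged disproportionate, and
#'   hierarchies above ~90% are deliberately primitive.
#' @return object of class `top_area_report`: `top_size`, `hierarchy_size`,
#'   `fraction`, `anomalous`, `band`.
#' @export
top_area_metrics <- function(t, band = c(0.04, 0.90)) {
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop_areatax("band must be c(low, high) with low < high",
                 class = "areatax_parameter_error")
  }
  top_size <- length(t$areas[[t$top_area]]$members)
  n <- sum(lengths(lapply(t$areas, `[[`, "members")))
  fraction <- top_size / n
  structure(
    list(top_size = top_size, hierarchy_size = n, fraction = fraction,
         anomalous = fraction >= band[1L] && fraction <= band[2L],
         band = band),
    class = "top_area_report"
  )
}

#' @export
print.top_area_report <- function(x, ...) {
  cat(sprintf("top area: %d of %d concepts (%.1f%%) - %s [band %.0f%%-%.0f%%]\n",
              x$top_size, x$hierarchy_size, 100 * x$fraction,
              if (x$anomalous) "ANOMALOUS" else "not anomalous",
              100 * x$band[1L], 100 * x$band[2L]))
  invisible(x)
}

#' Tabular area report
#'
#' One row per area: canonical name, display level, member count, root
#' count; ordered by display level then name. Suitable for writing as TSV.
#'
#' @param t an [derive_taxonomy()] result.
#' @return data.frame.
#' @export
area_table <- function(t) {
  out <- data.frame(
    area = names(t$areas),
    display_level = unname(t$display_level[names(t$areas)]),
    n_concepts = vapply(t$areas, function(a) length(a$members), integer(1L)),
    n_roots = vapply(t$areas, function(a) length(a$roots), integer(1L)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$display_level, out$area, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
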