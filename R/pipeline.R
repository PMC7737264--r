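#' Export an area taxonomy as Graphviz DOT
#'
#' One node per area labeled `"{types} (count)"`, colored and ranked by
#' display level (number of relationship types), and one directed edge per
#' child-of link, drawn from child to parent as in the usual taxonomy
#' diagrams.
#'
#' @param t an [derive_taxonomy()] result.
#' @return a single character string of DOT source.
#' @export
export_dot <- function(t) {
  palette <- c("#cfe8ff", "#c9f2c9", "#fff2b3", "#ffd9b3", "#f2c9f2",
               "#d9d9f2", "#f2d9c9")
  node_id <- function(nm) paste0("a", match(nm, names(t$areas)))
  nodes <- vapply(names(t$areas), function(nm) {
    a <- t$areas[[nm]]
    lvl <- t$display_level[[nm]]
    sprintf("  %s [label=\"%s (%d)\", shape=box, style=filled, fillcolor=\"%s\"];",
            node_id(nm), gsub("\"", "\\\\\"", nm), length(a$members),
            palette[lvl %% length(palette) + 1L])
  }, character(1L))
  ranks <- vapply(sort(unique(t$display_level)), function(lvl) {
    same <- names(t$display_level)[t$display_level == lvl]
    sprintf("  { rank=same; %s }", paste(node_id(same), collapse = "; "))
  }, character(1L))
  edges <- if (nrow(t$child_of)) {
    sprintf("  %s -> %s;", node_id(t$child_of$child),
            node_id(t$child_of$parent))
  } else {
    character()
  }
  paste(c("digraph area_taxonomy {",
          "  rankdir=BT;",
          nodes, ranks, edges, "}"), collapse = "\n")
}

#' Run the QA derivation pipeline end to end
#'
#' Loads a hierarchy, optionally extracts a subhierarchy, derives the area
#' taxonomy, computes the top-area metrics, levels and half split, and
#' writes the full set of artifacts into the output directory:
#' `areas.tsv`, `child_of.tsv`, `taxonomy.dot`, `top_area.tsv`,
#' `levels.tsv` and `candidates.tsv`. Headline metrics (top-area fraction,
#' level count, half-split start) are logged so a run is self-documenting.
#'
#' @param config a list (e.g. read from YAML) with elements:
#'   `input` (path: native-format directory, or RF2 snapshot directory),
#'   `format` (`"native"` or `"rf2"`), `out_dir`;
#'   optional: `root` (native root override / RF2 root, required for rf2),
#'   `sub_root` (derive the subtaxonomy of this subhierarchy),
#'   `band` (length-2 anomaly band), `scope` (`"higher"`/`"all"`),
#'   `max_candidates`, `isa_type_id`, `quiet`.
#' @return invisibly, a list with the derived objects (`hierarchy`,
#'   `taxonomy`, `top_report`, `level_map`, `half`, `candidates`) and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  need <- setdiff(c("input", "format", "out_dir"), names(config))
  if (length(need)) {
    stop_areatax("config is missing field(s): ", paste(need, collapse = ", "),
                 class = "areatax_usage_error")
  }
  say <- function(...) if (!isTRUE(config$quiet)) message(...)

  h <- switch(config$format,
    native = read_native_hierarchy(config$input, root = config$root %||% NULL),
    rf2 = {
      if (is.null(config$root)) {
        stop_areatax("rf2 input requires config$root",
                     class = "areatax_usage_error")
      }
      read_rf2_hierarchy(config$input, config$root,
                         isa_type_id = config$isa_type_id %||% "116680003")
    },
    stop_areatax("unknown input format: ", config$format,
                 class = "areatax_usage_error")
  )
  say("loaded hierarchy: ", length(hierarchy_members(h)), " concepts, ",
      nrow(h$isa), " IS-A edges, ", nrow(h$lateral), " triples")

  mode <- "full"
  if (!is.null(config$sub_root)) {
    h <- extract_subhierarchy(h, config$sub_root)
    mode <- "sub"
    say("extracted subhierarchy at ", config$sub_root, ": ",
        length(hierarchy_members(h)), " concepts")
  }

  viol <- check_monotone_inheritance(h)
  if (nrow(viol)) {
    say("note: ", nrow(viol), " IS-A edge(s) violate monotone inheritance")
  }

  t <- derive_taxonomy(h, mode = mode)
  band <- config$band %||% c(0.04, 0.90)
  report <- top_area_metrics(t, band = band)
  lm <- compute_levels(t, h)
  hs <- half_split(lm)
  cand <- prioritize_candidates(t, lm, h,
                                scope = config$scope %||% "higher",
                                max_candidates = config$max_candidates %||% Inf)
  say(sprintf("top area %s: %d/%d concepts (%.1f%%), anomalous: %s",
              t$top_area, report$top_size, report$hierarchy_size,
              100 * report$fraction, report$anomalous))
  say(sprintf("levels: n = %d, higher-indexed half starts at level %d",
              lm$n_levels, hs$split_start))
  say(nrow(cand), " review candidates (scope: ",
      config$scope %||% "higher", ")")

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- c(
    areas = file.path(out, "areas.tsv"),
    child_of = file.path(out, "child_of.tsv"),
    dot = file.path(out, "taxonomy.dot"),
    top_area = file.path(out, "top_area.tsv"),
    levels = file.path(out, "levels.tsv"),
    candidates = file.path(out, "candidates.tsv")
  )
  write_tsv_plain(area_table(t), paths[["areas"]])
  write_tsv_plain(t$child_of, paths[["child_of"]])
  writeLines(export_dot(t), paths[["dot"]])
  write_tsv_plain(data.frame(
    top_area = t$top_area, top_size = report$top_size,
    hierarchy_size = report$hierarchy_size,
    fraction = sprintf("%.6f", report$fraction),
    anomalous = report$anomalous,
    band_low = band[1L], band_high = band[2L],
    n_levels = lm$n_levels, split_start = hs$split_start,
    stringsAsFactors = FALSE
  ), paths[["top_area"]])
  lev_df <- data.frame(id = names(lm$levels), level = unname(lm$levels),
                       stringsAsFactors = FALSE)
  lev_df <- lev_df[order(lev_df$id, method = "radix"), , drop = FALSE]
  write_tsv_plain(lev_df, paths[["levels"]])
  write_tsv_plain(cand, paths[["candidates"]])

  invisible(list(hierarchy = h, taxonomy = t, top_report = report,
                 level_map = lm, half = hs, candidates = cand,
                 paths = paths))
}
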