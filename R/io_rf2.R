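#' Read a hierarchy from SNOMED CT RF2 snapshot files
#'
#' Reads the standard tab-delimited `sct2_Concept_Snapshot*` and
#' `sct2_Relationship_Snapshot*` files of an RF2 release. Only rows with
#' `active == "1"` are used. Relationship rows whose `typeId` equals the
#' "Is a" type identifier become IS-A edges; all other active relationship
#' rows become lateral triples (role groups are flattened: only `typeId`
#' and `destinationId` are kept). The result is restricted to `root_id`
#' and its IS-A descendants, the usual way a single hierarchy or
#' subhierarchy is carved out of a release.
#'
#' @param snapshot_dir directory containing the two snapshot files (any
#'   file matching `sct2_Concept_Snapshot*` / `sct2_Relationship_Snapshot*`).
#' @param root_id SCTID of the hierarchy (or subhierarchy) root.
#' @param isa_type_id relationship type identifier denoting IS-A;
#'   SNOMED CT's |Is a| concept `116680003` by default.
#' @param strict reject lateral triples whose target is outside the
#'   extracted hierarchy and not otherwise listed.
#' @return a [hierarchy()].
#' @export
read_rf2_hierarchy <- function(snapshot_dir, root_id,
                               isa_type_id = "116680003", strict = FALSE) {
  concept_file <- find_rf2_file(snapshot_dir, "sct2_Concept_Snapshot")
  rel_file <- find_rf2_file(snapshot_dir, "sct2_Relationship_Snapshot")

  con <- read_rf2_table(concept_file, c("id", "active"))
  rel <- read_rf2_table(rel_file, c("id", "active", "sourceId",
                                    "destinationId", "typeId"))
  con <- con[con$active == "1", , drop = FALSE]
  rel <- rel[rel$active == "1", , drop = FALSE]

  if (!root_id %in% con$id) {
    stop_areatax("root_id '", root_id, "' is not an active concept in ",
                 concept_file, class = "areatax_lookup_error")
  }

  is_isa <- rel$typeId == isa_type_id
  isa <- data.frame(child = rel$sourceId[is_isa],
                    parent = rel$destinationId[is_isa],
                    stringsAsFactors = FALSE)
  lat <- data.frame(source = rel$sourceId[!is_isa],
                    type = rel$typeId[!is_isa],
                    target = rel$destinationId[!is_isa],
                    stringsAsFactors = FALSE)

  keep <- descend_ids(root_id, isa)
  isa <- isa[isa$child %in% keep & isa$parent %in% keep, , drop = FALSE]
  lat <- lat[lat$source %in% keep, , drop = FALSE]

  ids <- unique(c(keep, intersect(lat$target, con$id)))
  concepts <- data.frame(id = ids, name = NA_character_,
                         hierarchy = NA_character_, stringsAsFactors = FALSE)
  hierarchy(concepts, isa, lat, root = root_id, strict = strict)
}

find_rf2_file <- function(dir, prefix) {
  hits <- list.files(dir, pattern = paste0("^", prefix), full.names = TRUE)
  if (!length(hits)) {
    stop_areatax("no ", prefix, "* file found in ", dir,
                 class = "areatax_load_error")
  }
  hits[1L]
}

read_rf2_table <- function(path, required_cols) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                         quote = "", comment.char = "", na.strings = NULL,
                         fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(x))
  if (length(missing)) {
    stop_areatax("RF2 file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "areatax_format_error")
  }
  x
}

# Reachability closure over child -> parent edges without needing a valid
# hierarchy object yet (used while carving the RF2 subset).
descend_ids <- function(root_id, isa) {
  kids <- split(isa$child, isa$parent)
  seen <- root_id
  frontier <- root_id
  while (length(frontier)) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}
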