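#' Read a hierarchy from the native tab-separated format
#'
#' The native format is three UTF-8, tab-separated files with header rows:
#' `concepts.tsv` (`id`, `name`, `hierarchy`), `isa.tsv` (`child_id`,
#' `parent_id`) and `rels.tsv` (`source_id`, `type`, `target_id`).
#'
#' @param concepts_path,isa_path,rels_path file paths; alternatively pass a
#'   single directory as `concepts_path` containing the three standard file
#'   names.
#' @param root root concept id; defaults to the unique concept without an
#'   IS-A parent.
#' @param strict reject triples whose target is not a listed concept.
#' @return a [hierarchy()].
#' @export
read_native_hierarchy <- function(concepts_path, isa_path = NULL,
                                  rels_path = NULL, root = NULL,
                                  strict = FALSE) {
  if (is.null(isa_path) && dir.exists(concepts_path)) {
    dir <- concepts_path
    concepts_path <- file.path(dir, "concepts.tsv")
    isa_path <- file.path(dir, "isa.tsv")
    rels_path <- file.path(dir, "rels.tsv")
  }
  concepts <- read_tsv_checked(concepts_path, c("id", "name", "hierarchy"))
  isa <- read_tsv_checked(isa_path, c("child_id", "parent_id"))
  rels <- read_tsv_checked(rels_path, c("source_id", "type", "target_id"))

  check_known_ids(isa$child_id, concepts$id, isa_path, "child_id")
  check_known_ids(isa$parent_id, concepts$id, isa_path, "parent_id")
  check_known_ids(rels$source_id, concepts$id, rels_path, "source_id")

  if (is.null(root)) {
    tops <- setdiff(unique(c(isa$parent_id, concepts$id)), isa$child_id)
    ext <- setdiff(concepts$id, c(isa$child_id, isa$parent_id))
    tops <- if (nrow(isa)) setdiff(tops, ext) else tops
    if (length(tops) != 1L) {
      stop_areatax("cannot infer a unique root (candidates: ",
                   paste(utils::head(sort_c(tops), 5L), collapse = ", "),
                   "); pass `root`", class = "areatax_structural_error")
    }
    root <- tops
  }
  hierarchy(
    concepts,
    data.frame(child = isa$child_id, parent = isa$parent_id,
               stringsAsFactors = FALSE),
    data.frame(source = rels$source_id, type = rels$type,
               target = rels$target_id, stringsAsFactors = FALSE),
    root = root, strict = strict
  )
}

#' Write a hierarchy in the native tab-separated format
#'
#' Rows are written in a canonical (byte-sorted) order so that writing the
#' same hierarchy twice produces byte-identical files.
#'
#' @param h a [hierarchy()].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths written.
#' @export
write_native_hierarchy <- function(h, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- h$concepts[order(h$concepts$id, method = "radix"), , drop = FALSE]
  names(con) <- c("id", "name", "hierarchy")
  isa <- h$isa[order(h$isa$child, h$isa$parent, method = "radix"), , drop = FALSE]
  names(isa) <- c("child_id", "parent_id")
  rel <- h$lateral[order(h$lateral$source, h$lateral$type, h$lateral$target,
                         method = "radix"), , drop = FALSE]
  names(rel) <- c("source_id", "type", "target_id")
  paths <- file.path(dir, c("concepts.tsv", "isa.tsv", "rels.tsv"))
  write_tsv_plain(con, paths[1L])
  write_tsv_plain(isa, paths[2L])
  write_tsv_plain(rel, paths[3L])
  invisible(paths)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop_areatax("file not found: ", path, class = "areatax_load_error")
  }
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                         quote = "", comment.char = "", na.strings = NULL,
                         fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(x))
  if (length(missing)) {
    stop_areatax("file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "areatax_format_error")
  }
  x[x == ""] <- NA_character_
  x
}

write_tsv_plain <- function(df, path) {
  df[] <- lapply(df, function(col) ifelse(is.na(col), "", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

# Loader-level referential check with a 1-based data row number (header is
# line 1 of the file, so file line = row + 1).
check_known_ids <- function(ids, known, path, col) {
  bad <- which(!ids %in% known)
  if (length(bad)) {
    stop_areatax("unknown concept id '", ids[bad[1L]], "' in ", path,
                 " column ", col, " (data row ", bad[1L], ", file line ",
                 bad[1L] + 1L, ")", class = "areatax_load_error")
  }
}
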