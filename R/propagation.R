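#' Repair proposal tables
#'
#' A repair proposal records that a concept is missing a relationship of a
#' given type pointing at a given target, together with its curation
#' status. Proposals are plain data.frames with columns `concept_id`,
#' `rel_type`, `target_id`, `status` (`proposed`, `confirmed` or
#' `rejected`).
#'
#' @param concept_id,rel_type,target_id,status vectors, recycled.
#' @return validated proposal data.frame.
#' @export
repair_proposals <- function(concept_id, rel_type, target_id,
                             status = "proposed") {
  out <- data.frame(
    concept_id = as.character(concept_id),
    rel_type = as.character(rel_type),
    target_id = as.character(target_id),
    status = as.character(status),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(out$status), c("proposed", "confirmed", "rejected"))
  if (length(bad)) {
    stop_areatax("unknown proposal status: ", bad[1L],
                 class = "areatax_format_error")
  }
  out
}

#' @rdname repair_proposals
#' @param path TSV file with the proposal columns.
#' @export
read_proposals <- function(path) {
  x <- read_tsv_checked(path, c("concept_id", "rel_type", "target_id",
                                "status"))
  repair_proposals(x$concept_id, x$rel_type, x$target_id, x$status)
}

# IS-A ancestors of a concept (excluding itself).
concept_ancestors <- function(h, id) {
  if (!nrow(h$isa) || !id %in% c(h$isa$child, h$isa$parent, h$root)) {
    return(character())
  }
  g <- isa_graph(h)
  setdiff(as.character(igraph::subcomponent(g, id, mode = "out")$name), id)
}

#' Classify the descendants of a concept with a confirmed missing relationship
#'
#' When a concept C is missing a relationship R pointing at target D, every
#' IS-A descendant of C should also carry R, pointing either at D itself or
#' at a descendant of D. Each descendant d of C is classified as:
#' `missing_same` (d has no R triple at all), `already_correct` (d has R
#' with target D or an IS-A descendant of D), or `incorrect_target` (d has
#' R but its target is neither D nor more specific than D). When the target
#' D is an external reference whose own hierarchy is not loaded, only exact
#' target equality counts as correct and the result is flagged accordingly.
#'
#' @param h a [hierarchy()].
#' @param concept_id the concept C carrying the confirmed proposal.
#' @param rel_type the missing relationship type R.
#' @param target_id the proposed target D.
#' @return data.frame with columns `descendant`, `class`,
#'   `observed_target`; attribute `external_target` is `TRUE` when D's
#'   descendants could not be resolved.
#' @export
classify_descendants <- function(h, concept_id, rel_type, target_id) {
  desc <- concept_descendants(h, concept_id)
  target_known <- target_id %in% h$concepts$id
  ok_targets <- if (target_known) {
    concept_descendants(h, target_id, include_self = TRUE)
  } else {
    target_id
  }
  lat <- h$lateral[h$lateral$source %in% desc & h$lateral$type == rel_type,
                   c("source", "target"), drop = FALSE]
  targets_of <- split(lat$target, lat$source)
  cls <- character(length(desc))
  obs <- rep(NA_character_, length(desc))
  for (i in seq_along(desc)) {
    tt <- targets_of[[desc[i]]]
    if (is.null(tt)) {
      cls[i] <- "missing_same"
    } else {
      hit <- intersect(tt, ok_targets)
      if (length(hit)) {
        cls[i] <- "already_correct"
        obs[i] <- sort_c(hit)[1L]
      } else {
        cls[i] <- "incorrect_target"
        obs[i] <- sort_c(tt)[1L]
      }
    }
  }
  out <- data.frame(descendant = desc, class = cls, observed_target = obs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$descendant, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "external_target") <- !target_known
  out
}

#' Impact report for confirmed repairs
#'
#' For every non-leaf concept with a confirmed missing-relationship
#' proposal, categorizes where its IS-A descendants fall (all outside the
#' top area, some in the top area, all in the top area) and counts the
#' affected descendants outside the top area: those missing the same
#' relationship as their repaired ancestor plus those carrying it with an
#' incorrect target. Leaf proposal concepts are excluded -- they cannot
#' propagate missing relationships downward. A descendant is counted once
#' per repaired ancestor concept.
#'
#' @param h a [hierarchy()].
#' @param t the [derive_taxonomy()] of `h`.
#' @param proposals proposal data.frame; only `confirmed` rows are used.
#' @return object of class `impact_report`: `concepts` (per-concept rows:
#'   `concept`, `category`, `n_descendants_outside_top`, `n_affected`) and
#'   `summary` (per-category counts plus a `total` row).
#' @export
impact_report <- function(h, t, proposals) {
  proposals <- proposals[proposals$status == "confirmed", , drop = FALSE]
  top_members <- t$areas[[t$top_area]]$members
  ids <- sort_c(unique(proposals$concept_id))
  rows <- lapply(ids, function(cid) {
    desc <- concept_descendants(h, cid)
    if (!length(desc)) return(NULL)  # leaves propagate nothing
    in_top <- desc %in% top_members
    outside <- desc[!in_top]
    category <- if (all(in_top)) "all_descendants_top"
                else if (!any(in_top)) "all_descendants_non_top"
                else "mixed"
    prop_c <- proposals[proposals$concept_id == cid, , drop = FALSE]
    affected <- character()
    for (j in seq_len(nrow(prop_c))) {
      cl <- classify_descendants(h, cid, prop_c$rel_type[j],
                                 prop_c$target_id[j])
      affected <- union(affected,
                        cl$descendant[cl$class != "already_correct"])
    }
    data.frame(concept = cid, category = category,
               n_descendants_outside_top = length(outside),
               n_affected = length(intersect(affected, outside)),
               stringsAsFactors = FALSE)
  })
  concepts <- do.call(rbind, c(rows, list(
    data.frame(concept = character(), category = character(),
               n_descendants_outside_top = integer(),
               n_affected = integer(), stringsAsFactors = FALSE))))
  cats <- c("all_descendants_non_top", "mixed", "all_descendants_top")
  fcat <- factor(concepts$category, levels = cats)
  summary <- data.frame(
    category = c(cats, "total"),
    n_concepts = c(as.integer(table(fcat)), nrow(concepts)),
    n_descendants_outside_top = c(
      as.integer(tapply(concepts$n_descendants_outside_top, fcat, sum,
                        default = 0L)),
      sum(concepts$n_descendants_outside_top)),
    n_affected = c(
      as.integer(tapply(concepts$n_affected, fcat, sum, default = 0L)),
      sum(concepts$n_affected)),
    stringsAsFactors = FALSE
  )
  structure(list(concepts = concepts, summary = summary),
            class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report>", nrow(x$concepts), "non-leaf repaired concepts\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Shared-error report: errors repeated from erroneous ancestors
#'
#' For each concept found erroneous in an audit, checks its erroneous IS-A
#' ancestors: `same_error` when it misses a (type, target) pair an ancestor
#' also misses; `more_specific_target` when it misses the same relationship
#' type as an ancestor but with a target that is a strict IS-A descendant
#' of the ancestor's target; `ancestor_error_disjoint` when it has
#' erroneous ancestors but no overlapping finding; `no_erroneous_ancestor`
#' otherwise. Classes are assigned with that priority.
#'
#' @param h a [hierarchy()].
#' @param audits audit data.frame.
#' @return object of class `shared_error_report`: `per_concept`
#'   (`concept`, `class`) and `counts` (named integer vector).
#' @export
shared_error_report <- function(h, audits) {
  audits <- validate_audits(audits)
  err <- audits[audits$verdict == "erroneous", , drop = FALSE]
  findings_of <- split(err[, c("missing_type", "proposed_target_id")],
                       err$concept_id)
  err_ids <- sort_c(unique(err$concept_id))
  classes <- vapply(err_ids, function(cid) {
    anc <- intersect(concept_ancestors(h, cid), err_ids)
    if (!length(anc)) return("no_erroneous_ancestor")
    own <- findings_of[[cid]]
    for (a in anc) {
      fa <- findings_of[[a]]
      shared <- merge(own, fa, by = c("missing_type", "proposed_target_id"))
      if (nrow(shared)) return("same_error")
    }
    for (a in anc) {
      fa <- findings_of[[a]]
      for (j in seq_len(nrow(fa))) {
        tgt_desc <- if (fa$proposed_target_id[j] %in% h$concepts$id) {
          concept_descendants(h, fa$proposed_target_id[j])
        } else character()
        hit <- own$missing_type == fa$missing_type[j] &
          own$proposed_target_id %in% tgt_desc
        if (any(hit)) return("more_specific_target")
      }
    }
    "ancestor_error_disjoint"
  }, character(1L))
  counts <- table(factor(classes, levels = c(
    "same_error", "more_specific_target", "ancestor_error_disjoint",
    "no_erroneous_ancestor")))
  structure(
    list(per_concept = data.frame(concept = err_ids, class = unname(classes),
                                  stringsAsFactors = FALSE),
         counts = c(counts)),
    class = "shared_error_report"
  )
}

#' @export
print.shared_error_report <- function(x, ...) {
  cat("<shared_error_report>", nrow(x$per_concept), "erroneous concepts\n")
  print(x$counts)
  invisible(x)
}

#' Apply confirmed repairs to a hierarchy
#'
#' Adds the missing triple (C, R, D) for each confirmed proposal. With
#' `inherit = TRUE`, also adds (d, R, D) for every descendant of C
#' classified `missing_same` -- the automatic error correction by
#' inheritance. Descendants with an `incorrect_target` are reported by
#' [classify_descendants()] but never modified automatically (changing an
#' existing assertion is curator work). The input hierarchy is unchanged;
#' duplicate triples are silently collapsed, so re-applying the same
#' proposals is a no-op.
#'
#' @param h a [hierarchy()].
#' @param proposals proposal data.frame; all rows must be `confirmed`
#'   (passing a rejected proposal is an error).
#' @param inherit propagate the added relationship to `missing_same`
#'   descendants.
#' @return a new, revised [hierarchy()].
#' @export
apply_repairs <- function(h, proposals, inherit = TRUE) {
  if (nrow(proposals) == 0L) return(h)
  if (any(proposals$status != "confirmed")) {
    stop_areatax("apply_repairs accepts only confirmed proposals (got: ",
                 paste(setdiff(unique(proposals$status), "confirmed"),
                       collapse = ", "), ")",
                 class = "areatax_input_error")
  }
  unknown <- setdiff(proposals$concept_id, h$concepts$id)
  if (length(unknown)) {
    stop_areatax("proposal for unknown concept: ", unknown[1L],
                 class = "areatax_lookup_error")
  }
  add <- data.frame(source = proposals$concept_id,
                    type = proposals$rel_type,
                    target = proposals$target_id, stringsAsFactors = FALSE)
  if (inherit) {
    for (j in seq_len(nrow(proposals))) {
      cl <- classify_descendants(h, proposals$concept_id[j],
                                 proposals$rel_type[j],
                                 proposals$target_id[j])
      miss <- cl$descendant[cl$class == "missing_same"]
      if (length(miss)) {
        add <- rbind(add, data.frame(source = miss,
                                     type = proposals$rel_type[j],
                                     target = proposals$target_id[j],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  hierarchy(h$concepts, h$isa, rbind(h$lateral, add), root = h$root)
}
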