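# Hierarchy used throughout: C has descendants d1..d4; the proposed target
# D has descendant D2; T is unrelated.
propagation_fixture <- function() {
  ids <- c("root", "C", "d1", "d2", "d3", "d4", "D", "D2", "T")
  isa <- data.frame(
    child = c("C", "d1", "d2", "d3", "d4", "D", "D2", "T"),
    parent = c("root", "C", "C", "d1", "d2", "root", "D", "root"))
  lateral <- data.frame(
    source = c("d2", "d3", "d4"),
    type = c("Location", "Location", "Location"),
    target = c("D2", "T", "D"))
  hierarchy(data.frame(id = ids, name = NA, hierarchy = NA),
            isa, lateral, "root")
}

test_that("descendant classification follows the target-specialization rule", {
  h <- propagation_fixture()
  cl <- classify_descendants(h, "C", "Location", "D")
  got <- stats::setNames(cl$class, cl$descendant)
  expect_equal(unname(got["d1"]), "missing_same")       # no triple at all
  expect_equal(unname(got["d2"]), "already_correct")    # target below D
  expect_equal(unname(got["d3"]), "incorrect_target")   # unrelated target
  expect_equal(unname(got["d4"]), "already_correct")    # exact target
  expect_setequal(cl$descendant, c("d1", "d2", "d3", "d4"))
  expect_false(attr(cl, "external_target"))
  expect_error(classify_descendants(h, "nope", "Location", "D"),
               class = "areatax_lookup_error")
})

test_that("an external target only matches by exact equality", {
  h <- propagation_fixture()
  cl <- classify_descendants(h, "C", "Location", "X_external")
  expect_true(attr(cl, "external_target"))
  got <- stats::setNames(cl$class, cl$descendant)
  expect_equal(unname(got["d2"]), "incorrect_target")
  expect_equal(unname(got["d1"]), "missing_same")
})

test_that("classification partitions the descendant set on random data", {
  set.seed(606)
  for (k in 1:5) {
    h <- random_hierarchy(50, p_type = 0.4)
    cid <- sample(hierarchy_members(h), 1L)
    cl <- classify_descendants(h, cid, "Location", "T_Location")
    expect_setequal(cl$descendant, concept_descendants(h, cid))
    expect_true(all(cl$class %in%
                      c("missing_same", "already_correct",
                        "incorrect_target")))
    # recount oracle for missing_same
    want_missing <- Filter(function(d) {
      !any(h$lateral$source == d & h$lateral$type == "Location")
    }, concept_descendants(h, cid))
    expect_setequal(cl$descendant[cl$class == "missing_same"], want_missing)
  }
})

test_that("impact report categorizes by top-area membership and skips leaves", {
  h <- propagation_fixture()
  t <- derive_taxonomy(h)
  # C's descendants: d1 (top area, no laterals), d2/d3/d4 ({Location})
  props <- repair_proposals(c("C", "d3"), "Location", "D", "confirmed")
  rep <- impact_report(h, t, props)
  expect_equal(nrow(rep$concepts), 1L)  # d3 is a leaf: excluded
  row <- rep$concepts[rep$concepts$concept == "C", ]
  expect_equal(row$category, "mixed")
  expect_equal(row$n_descendants_outside_top, 3L)
  expect_equal(row$n_affected, 1L)  # only d3 (incorrect target) outside top
  tot <- rep$summary[rep$summary$category == "total", ]
  expect_equal(tot$n_concepts, 1L)
  expect_equal(tot$n_affected, 1L)
})

test_that("impact totals equal a brute-force recount on synthetic data", {
  set.seed(607)
  h <- random_hierarchy(60, p_type = 0.35)
  t <- derive_taxonomy(h)
  nonleaf <- unique(h$isa$parent)
  ids <- sample(nonleaf, 5L)
  props <- repair_proposals(ids, "Location", "T_Location", "confirmed")
  rep <- impact_report(h, t, props)
  top_members <- t$areas[[t$top_area]]$members
  for (i in seq_len(nrow(rep$concepts))) {
    cid <- rep$concepts$concept[i]
    desc <- concept_descendants(h, cid)
    outside <- setdiff(desc, top_members)
    affected <- Filter(function(d) {
      tri <- h$lateral[h$lateral$source == d &
                         h$lateral$type == "Location", ]
      nrow(tri) == 0L || !"T_Location" %in% tri$target
    }, outside)
    expect_equal(rep$concepts$n_descendants_outside_top[i], length(outside))
    expect_equal(rep$concepts$n_affected[i], length(affected))
  }
  expect_equal(rep$summary$n_affected[rep$summary$category == "total"],
               sum(rep$concepts$n_affected))
})

test_that("shared-error report distinguishes repeat and refined errors", {
  h <- propagation_fixture()
  aud <- rbind(
    audit_records("C", "erroneous", "Location", "D"),
    audit_records("d1", "erroneous", "Location", "D"),    # same error
    audit_records("d2", "erroneous", "Location", "D2"),   # more specific
    audit_records("d3", "erroneous", "Part of Process", "T"),  # disjoint
    audit_records("T", "erroneous", "Location", "D"))     # no err ancestor
  rep <- shared_error_report(h, aud)
  got <- stats::setNames(rep$per_concept$class, rep$per_concept$concept)
  expect_equal(unname(got["d1"]), "same_error")
  expect_equal(unname(got["d2"]), "more_specific_target")
  expect_equal(unname(got["d3"]), "ancestor_error_disjoint")
  expect_equal(unname(got["T"]), "no_erroneous_ancestor")
  expect_equal(unname(rep$counts["same_error"]), 1L)
  expect_equal(sum(rep$counts), 5L)
})

test_that("apply_repairs adds triples, inherits, and is idempotent", {
  h <- propagation_fixture()
  expect_equal(apply_repairs(h, repair_proposals(character(), character(),
                                                 character(), character())),
               h)
  props <- repair_proposals("C", "Location", "D", "confirmed")
  h2 <- apply_repairs(h, props, inherit = TRUE)
  # input unchanged
  expect_equal(nrow(h$lateral), 3L)
  # C and its missing_same descendant d1 both gained (Location, D)
  expect_true(any(h2$lateral$source == "C" & h2$lateral$target == "D"))
  expect_true(any(h2$lateral$source == "d1" & h2$lateral$target == "D"))
  # incorrect target at d3 untouched
  expect_true(any(h2$lateral$source == "d3" & h2$lateral$target == "T"))
  expect_false(any(h2$lateral$source == "d3" & h2$lateral$target == "D"))
  # no missing_same left; idempotent under re-application
  cl <- classify_descendants(h2, "C", "Location", "D")
  expect_false(any(cl$class == "missing_same"))
  expect_equal(apply_repairs(h2, props, inherit = TRUE), h2)
  expect_error(
    apply_repairs(h, repair_proposals("C", "Location", "D", "rejected")),
    class = "areatax_input_error")
})

test_that("repairing a top-area concept moves it out on re-derivation", {
  h <- fig2_hierarchy()
  t <- derive_taxonomy(h)
  before <- length(t$areas[["{}"]]$members)
  props <- repair_proposals("Reproductive Process", "Location", "Cell",
                            "confirmed")
  h2 <- apply_repairs(h, props)
  t2 <- derive_taxonomy(h2)
  expect_equal(length(t2$areas[["{}"]]$members), before - 1L)
  expect_true("Reproductive Process" %in% t2$areas[["{Location}"]]$members)

  # a repair introducing an unseen type set creates a new area
  props2 <- repair_proposals("Pathologic Process", "Resulting Anatomy",
                             "Fibrin", "confirmed")
  t3 <- derive_taxonomy(apply_repairs(h, props2))
  expect_true("{Resulting Anatomy}" %in% names(t3$areas))
  expect_false("{Resulting Anatomy}" %in% names(t$areas))
})

test_that("repairs with inheritance preserve monotone inheritance", {
  set.seed(608)
  h <- random_hierarchy(50, p_type = 0.3, monotone = TRUE)
  expect_equal(nrow(check_monotone_inheritance(h)), 0L)
  nonleaf <- unique(h$isa$parent)
  props <- repair_proposals(sample(nonleaf, 3L), "Initiator BP",
                            "T_InitiatorBP", "confirmed")
  h2 <- apply_repairs(h, props, inherit = TRUE)
  expect_equal(nrow(check_monotone_inheritance(h2)), 0L)
})

test_that("proposal TSVs round-trip", {
  props <- repair_proposals(c("C", "d1"), c("Location", "Part of Process"),
                            c("D", "T"), c("confirmed", "proposed"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(props, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_proposals(path), props, ignore_attr = TRUE)
  expect_error(repair_proposals("C", "Location", "D", "unknown"),
               class = "areatax_format_error")
})
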