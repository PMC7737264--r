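test_that("native loader round-trips and resolves ids", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\thierarchy",
               "R\tRoot\tBP", "A\tAlpha\tBP", "B\tBeta\tBP",
               "X\tSite\tAnatomy"),
             file.path(dir, "concepts.tsv"))
  writeLines(c("child_id\tparent_id", "A\tR", "B\tR"),
             file.path(dir, "isa.tsv"))
  writeLines(c("source_id\ttype\ttarget_id", "A\tLocation\tX"),
             file.path(dir, "rels.tsv"))
  h <- read_native_hierarchy(dir)
  expect_equal(h$root, "R")
  expect_equal(nrow(h$concepts), 4L)  # X kept as an external reference
  expect_equal(nrow(h$lateral), 1L)
  expect_setequal(hierarchy_members(h), c("R", "A", "B"))

  out <- withr::local_tempdir()
  write_native_hierarchy(h, out)
  h2 <- read_native_hierarchy(out)
  canon <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(canon(h2$concepts), canon(h$concepts))
  expect_equal(canon(h2$isa), canon(h$isa))
  expect_equal(canon(h2$lateral), canon(h$lateral))
  expect_equal(h2$root, h$root)
})

test_that("writing is idempotent byte for byte and round-trips random data", {
  set.seed(101)
  h <- random_hierarchy(60, p_type = 0.4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_native_hierarchy(h, d1)
  h2 <- read_native_hierarchy(d1)
  write_native_hierarchy(h2, d2)
  for (f in c("concepts.tsv", "isa.tsv", "rels.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_setequal(hierarchy_members(h2), hierarchy_members(h))
  expect_equal(nrow(h2$lateral), nrow(h$lateral))
})

test_that("loader rejects cycles and dangling ids with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\thierarchy", "R\t\t", "A\t\t", "B\t\t"),
             file.path(dir, "concepts.tsv"))
  writeLines(c("child_id\tparent_id", "A\tB", "B\tA"),
             file.path(dir, "isa.tsv"))
  writeLines("source_id\ttype\ttarget_id", file.path(dir, "rels.tsv"))
  expect_error(read_native_hierarchy(dir, root = "R"),
               class = "areatax_structural_error")

  writeLines(c("child_id\tparent_id", "A\tR", "ZZZ\tR"),
             file.path(dir, "isa.tsv"))
  err <- tryCatch(read_native_hierarchy(dir, root = "R"),
                  error = function(e) e)
  expect_s3_class(err, "areatax_load_error")
  expect_match(conditionMessage(err), "ZZZ")
  expect_match(conditionMessage(err), "line 3")
})

test_that("hierarchy validation enforces rooting and uniqueness", {
  con <- data.frame(id = c("R", "A"), name = NA, hierarchy = NA)
  expect_error(
    hierarchy(rbind(con, con[2, ]), data.frame(child = "A", parent = "R"),
              NULL, "R"),
    class = "areatax_format_error")
  # a second top not reachable from the declared root
  con3 <- data.frame(id = c("R", "A", "S", "B"), name = NA, hierarchy = NA)
  expect_error(
    hierarchy(con3, data.frame(child = c("A", "B"), parent = c("R", "S")),
              NULL, "R"),
    class = "areatax_structural_error")
  # strict mode rejects external targets
  expect_error(
    hierarchy(con, data.frame(child = "A", parent = "R"),
              data.frame(source = "A", type = "Location", target = "X"),
              "R", strict = TRUE),
    class = "areatax_load_error")
})

test_that("RF2 loader filters inactive rows and splits IS-A from lateral", {
  dir <- withr::local_tempdir()
  cols <- c("id", "effectiveTime", "active", "moduleId", "definitionStatusId")
  rcols <- c("id", "effectiveTime", "active", "moduleId", "sourceId",
             "destinationId", "relationshipGroup", "typeId",
             "characteristicTypeId", "modifierId")
  write_rows <- function(path, header, rows) {
    writeLines(c(paste(header, collapse = "\t"),
                 vapply(rows, paste, character(1L), collapse = "\t")), path)
  }
  write_rows(file.path(dir, "sct2_Concept_Snapshot_INT.txt"), cols, list(
    c("100", "20180131", "1", "m", "p"),
    c("200", "20180131", "1", "m", "p"),
    c("300", "20180131", "1", "m", "p"),
    c("400", "20180131", "0", "m", "p"),   # inactive concept
    c("900", "20180131", "1", "m", "p")))  # lateral target
  write_rows(file.path(dir, "sct2_Relationship_Snapshot_INT.txt"), rcols, list(
    c("1", "t", "1", "m", "200", "100", "0", "116680003", "c", "m"),
    c("2", "t", "0", "m", "300", "100", "0", "116680003", "c", "m"),  # inactive
    c("3", "t", "1", "m", "300", "200", "0", "116680003", "c", "m"),
    c("4", "t", "1", "m", "200", "900", "0", "363698007", "c", "m"),
    c("5", "t", "1", "m", "300", "900", "1", "363698007", "c", "m"),
    c("6", "t", "1", "m", "300", "900", "0", "116676008", "c", "m")))
  h <- read_rf2_hierarchy(dir, "100")
  expect_equal(nrow(h$isa), 2L)  # inactive IS-A row dropped
  expect_equal(nrow(h$lateral), 3L)
  expect_setequal(hierarchy_members(h), c("100", "200", "300"))
  expect_error(read_rf2_hierarchy(dir, "999"),
               class = "areatax_lookup_error")
})

test_that("RF2 and native loaders agree on an equivalent fixture", {
  set.seed(77)
  h <- random_hierarchy(50, p_type = 0.35)
  # re-encode as RF2: numeric ids, types as typeId strings
  idmap <- stats::setNames(as.character(1000 + seq_len(nrow(h$concepts))),
                           h$concepts$id)
  typemap <- c(Location = "363698007", `Part of Process` = "123005000",
               `Initiator BP` = "260686004")
  dir <- withr::local_tempdir()
  con_rows <- paste(idmap[h$concepts$id], "t", "1", "m", "p", sep = "\t")
  writeLines(c("id\teffectiveTime\tactive\tmoduleId\tdefinitionStatusId",
               con_rows),
             file.path(dir, "sct2_Concept_Snapshot_INT.txt"))
  isa_rows <- paste(seq_len(nrow(h$isa)), "t", "1", "m",
                    idmap[h$isa$child], idmap[h$isa$parent], "0",
                    "116680003", "c", "m", sep = "\t")
  lat_rows <- paste(nrow(h$isa) + seq_len(nrow(h$lateral)), "t", "1", "m",
                    idmap[h$lateral$source], idmap[h$lateral$target], "0",
                    typemap[h$lateral$type], "c", "m", sep = "\t")
  writeLines(c(paste("id", "effectiveTime", "active", "moduleId", "sourceId",
                     "destinationId", "relationshipGroup", "typeId",
                     "characteristicTypeId", "modifierId", sep = "\t"),
               isa_rows, lat_rows),
             file.path(dir, "sct2_Relationship_Snapshot_INT.txt"))
  h_rf2 <- read_rf2_hierarchy(dir, idmap[[h$root]])
  expect_setequal(hierarchy_members(h_rf2),
                  unname(idmap[hierarchy_members(h)]))
  expect_equal(nrow(h_rf2$isa), nrow(h$isa))
  expect_equal(nrow(h_rf2$lateral), nrow(h$lateral))
  # areas must coincide under the id/type renaming
  t1 <- derive_taxonomy(h)
  t2 <- derive_taxonomy(h_rf2)
  m1 <- sort(table(area_of_concept(t1)))
  m2 <- sort(table(area_of_concept(t2)))
  expect_equal(unname(as.integer(m1)), unname(as.integer(m2)))
})

test_that("subhierarchy extraction equals brute-force reachability", {
  expect_equal(extract_subhierarchy(fig2_hierarchy(), "Biological Process"),
               fig2_hierarchy())
  h <- hierarchy(data.frame(id = c("R", "A", "B"), name = NA, hierarchy = NA),
                 data.frame(child = c("A", "B"), parent = c("R", "A")),
                 NULL, "R")
  expect_setequal(hierarchy_members(extract_subhierarchy(h, "A")),
                  c("A", "B"))
  expect_error(extract_subhierarchy(h, "nope"),
               class = "areatax_lookup_error")

  set.seed(202)
  for (k in 1:5) {
    h <- random_hierarchy(100, p_type = 0.25)
    root <- sample(hierarchy_members(h), 1L)
    sub <- extract_subhierarchy(h, root)
    # oracle: BFS closure over child edges
    frontier <- root; seen <- root
    repeat {
      nxt <- setdiff(h$isa$child[h$isa$parent %in% frontier], seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(hierarchy_members(sub), seen)
    expect_true(all(sub$lateral$source %in% seen))
  }
})

test_that("monotone-inheritance check flags exactly the violating edges", {
  expect_equal(nrow(check_monotone_inheritance(fig2_hierarchy())), 0L)
  h <- hierarchy(data.frame(id = c("R", "P", "C"), name = NA, hierarchy = NA),
                 data.frame(child = c("P", "C"), parent = c("R", "P")),
                 data.frame(source = "P", type = "Location", target = "X"),
                 "R")
  v <- check_monotone_inheritance(h)
  expect_equal(nrow(v), 1L)
  expect_equal(v$child, "C")
  expect_equal(v$missing_types, "Location")
})
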