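#' Audit record tables
#'
#' Audit findings are kept in a plain data.frame with one row per finding:
#' columns `concept_id`, `verdict` (`"erroneous"` or `"clean"`),
#' `missing_type`, `proposed_target_id`, `stage` (`"primary"` or
#' `"confirmed"`) and `reviewer`. A clean concept has a single row with
#' empty finding columns. Keeping the review stage on each row lets the
#' primary-review and confirmed-review analyses be re-run from one file.
#'
#' @param concept_id,verdict,missing_type,proposed_target_id,stage,reviewer
#'   vectors, recycled to a common length.
#' @return validated audit data.frame.
#' @export
audit_records <- function(concept_id, verdict, missing_type = NA,
                          proposed_target_id = NA, stage = "primary",
                          reviewer = NA) {
  out <- data.frame(
    concept_id = as.character(concept_id),
    verdict = as.character(verdict),
    missing_type = as.character(missing_type),
    proposed_target_id = as.character(proposed_target_id),
    stage = as.character(stage),
    reviewer = as.character(reviewer),
    stringsAsFactors = FALSE
  )
  validate_audits(out)
}

validate_audits <- function(audits) {
  bad <- setdiff(unique(audits$verdict), c("erroneous", "clean"))
  if (length(bad)) {
    stop_areatax("unknown verdict: ", bad[1L], class = "areatax_format_error")
  }
  finding <- !is.na(audits$missing_type)
  if (any(audits$verdict == "clean" & finding)) {
    stop_areatax("clean records must not carry findings",
                 class = "areatax_format_error")
  }
  if (any(audits$verdict == "erroneous" & !finding)) {
    stop_areatax("erroneous records must name the missing relationship type",
                 class = "areatax_format_error")
  }
  audits
}

#' Read / write audit TSV files
#'
#' @param path TSV file with the [audit_records()] columns.
#' @return data.frame of audit records.
#' @export
read_audits <- function(path) {
  x <- read_tsv_checked(path, c("concept_id", "verdict", "missing_type",
                                "proposed_target_id", "stage", "reviewer"))
  validate_audits(x)
}

#' @rdname read_audits
#' @param audits audit data.frame.
#' @export
write_audits <- function(audits, path) {
  write_tsv_plain(validate_audits(audits), path)
  invisible(path)
}

#' Per-concept verdicts
#'
#' @param audits audit data.frame.
#' @param stage restrict to one review stage (default: all rows).
#' @return named logical vector, `TRUE` for erroneous concepts.
#' @export
audit_verdicts <- function(audits, stage = NULL) {
  if (!is.null(stage)) audits <- audits[audits$stage %in% stage, , drop = FALSE]
  tab <- tapply(audits$verdict == "erroneous", audits$concept_id, any)
  out <- as.logical(tab)
  names(out) <- names(tab)
  out
}

#' Build a 2x2 audit contingency table
#'
#' Counts erroneous vs clean concepts in two audit groups (e.g., top area
#' vs other areas, or higher- vs lower-indexed-half levels), laid out as
#' rows = groups, columns = (erroneous, clean).
#'
#' @param group1,group2 audit data.frames, or logical verdict vectors as
#'   returned by [audit_verdicts()].
#' @param labels length-2 character row labels.
#' @return 2x2 integer matrix.
#' @export
build_contingency <- function(group1, group2,
                              labels = c("group1", "group2")) {
  as_verdicts <- function(g) {
    if (is.data.frame(g)) audit_verdicts(g) else as.logical(g)
  }
  v1 <- as_verdicts(group1)
  v2 <- as_verdicts(group2)
  if (!length(v1) || !length(v2)) {
    stop_areatax("both audit groups must be non-empty",
                 class = "areatax_input_error")
  }
  m <- matrix(c(sum(v1), sum(!v1), sum(v2), sum(!v2)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(labels, c("erroneous", "clean")))
  storage.mode(m) <- "integer"
  m
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' with both margins fixed, over all tables whose point probability does
#' not exceed that of the observed table (compared with relative tolerance
#' 1e-7) -- the point-probability method implemented by
#' [stats::fisher.test()], which this wraps. A table with a zero margin
#' leaves nothing to condition on; it returns 1 with a warning.
#'
#' @param ct 2x2 matrix of non-negative counts.
#' @return the p-value in (0, 1].
#' @export
fisher_two_tailed <- function(ct) {
  ct <- as.matrix(ct)
  if (!all(dim(ct) == c(2L, 2L)) || any(ct < 0)) {
    stop_areatax("ct must be a 2x2 matrix of non-negative counts",
                 class = "areatax_input_error")
  }
  if (any(rowSums(ct) == 0) || any(colSums(ct) == 0)) {
    warning("degenerate contingency table (zero margin); p = 1")
    return(1)
  }
  stats::fisher.test(ct, alternative = "two.sided")$p.value
}

#' Percentage with half-up rounding
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param decimals digits after the decimal point (reports in the field mix
#'   1- and 2-decimal conventions).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    stop_areatax("denominator must be > 0", class = "areatax_arithmetic_error")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    stop_areatax("need 0 <= numerator <= denominator",
                 class = "areatax_arithmetic_error")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Per-level error distribution table
#'
#' One row per occupied top-area level plus a totals row: number of
#' concepts at the level, number audited, % audited, number found
#' erroneous, % erroneous (of the audited). Mirrors the per-level QA
#' summary tables used when a top area is reviewed level by level.
#'
#' @param audits audit data.frame; audited concepts must be top-area
#'   members.
#' @param lm a [compute_levels()] result for the taxonomy under audit.
#' @param decimals digits for the percentage columns.
#' @return data.frame of class `level_error_table` with columns `level`,
#'   `n_concepts`, `n_audited`, `pct_audited`, `n_erroneous`,
#'   `pct_erroneous`; the final row (`level == NA`) holds column totals.
#' @export
level_error_table <- function(audits, lm, decimals = 1) {
  verdicts <- audit_verdicts(audits)
  outside <- setdiff(names(verdicts), names(lm$levels))
  if (length(outside)) {
    stop_areatax("audited concept(s) outside the top area: ",
                 paste(utils::head(sort_c(outside), 5L), collapse = ", "),
                 class = "areatax_input_error")
  }
  lev_all <- lm$levels
  lev_aud <- lev_all[names(verdicts)]
  levels_seq <- seq.int(0L, lm$n_levels - 1L)
  n_concepts <- as.integer(table(factor(lev_all, levels = levels_seq)))
  n_audited <- as.integer(table(factor(lev_aud, levels = levels_seq)))
  n_err <- as.integer(table(factor(lev_aud[verdicts], levels = levels_seq)))
  pct <- function(num, den) ifelse(den > 0, percent(num, pmax(den, 1L),
                                                    decimals), 0)
  out <- data.frame(
    level = levels_seq,
    n_concepts = n_concepts,
    n_audited = n_audited,
    pct_audited = pct(n_audited, n_concepts),
    n_erroneous = n_err,
    pct_erroneous = pct(n_err, n_audited),
    stringsAsFactors = FALSE
  )
  totals <- data.frame(
    level = NA_integer_,
    n_concepts = sum(n_concepts),
    n_audited = sum(n_audited),
    pct_audited = pct(sum(n_audited), sum(n_concepts)),
    n_erroneous = sum(n_err),
    pct_erroneous = pct(sum(n_err), sum(n_audited)),
    stringsAsFactors = FALSE
  )
  structure(rbind(out, totals),
            class = c("level_error_table", "data.frame"))
}

#' Contingency table of audit outcomes grouped by level half
#'
#' Groups the audited top-area concepts into the lower- and
#' higher-indexed-half levels and cross-tabulates erroneous vs clean;
#' the table feeding the depth hypothesis test.
#'
#' @param audits audit data.frame over top-area concepts.
#' @param lm a [compute_levels()] result.
#' @return 2x2 integer matrix, rows `lower`, `higher`.
#' @export
build_half_contingency <- function(audits, lm) {
  verdicts <- audit_verdicts(audits)
  outside <- setdiff(names(verdicts), names(lm$levels))
  if (length(outside)) {
    stop_areatax("audited concept(s) outside the top area: ",
                 paste(utils::head(sort_c(outside), 5L), collapse = ", "),
                 class = "areatax_input_error")
  }
  hs <- half_split(lm)
  lev <- lm$levels[names(verdicts)]
  in_higher <- lev >= hs$split_start
  build_contingency(verdicts[!in_higher], verdicts[in_higher],
                    labels = c("lower", "higher"))
}
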