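#' Load a species detection table
#'
#' Reads the per-species counts of transects with at least one detection
#' under each of the seven survey protocols. With `source = NULL` the
#' packaged case-study table is loaded: ten squamate species surveyed on ten
#' transects with camera traps, artificial refuges and pitfall traps.
#'
#' The expected CSV header is
#' `species,common_name,size_class,All-74,CT-74,All-16,CT-16,LI,AR,PF`,
#' one row per species, counts in `0..n_transects`. The table is validated on
#' load (see [validate_detection_table()]); an invalid table is an error.
#'
#' @param source Path to a CSV file, or `NULL` for the packaged fixture.
#' @param n_transects Number of transects surveyed (default 10).
#' @return A tibble with one row per species, the three descriptor columns
#'   and seven integer protocol-count columns.
#' @export
#' @examples
#' load_detection_table()
load_detection_table <- function(source = NULL, n_transects = 10) {
  if (is.null(source)) source <- trapcost_example("detection_table.csv")
  tbl <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  required <- c("species", "common_name", "size_class", protocol_levels())
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("detection table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl[required])
  for (p in protocol_levels()) {
    v <- tbl[[p]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      stop("column '", p, "' must contain integer counts", call. = FALSE)
    }
    tbl[[p]] <- as.integer(v)
  }
  validate_detection_table(tbl, n_transects = n_transects)
  tbl
}

#' Validate a species detection table
#'
#' Checks that every protocol count lies in `0..n_transects` and that the
#' per-species counts are jointly feasible under the protocol nesting
#' (`LI = AR | PF`, `All-16 = CT-16 | LI`, `All-74 = CT-74 | LI`,
#' `CT-16` nested in `CT-74`): unions are at least as large as their largest
#' part and no larger than the sum of their parts (capped at `n_transects`),
#' and the implied method overlaps with the labour-intensive transect set are
#' consistent with the camera nesting
#' (`CT-16 - All-16 <= CT-74 - All-74`). Violations raise an error naming the
#' species and the constraint.
#'
#' @param table A detection-table tibble as returned by
#'   [load_detection_table()].
#' @param n_transects Number of transects surveyed.
#' @return The table, invisibly, if valid.
#' @export
validate_detection_table <- function(table, n_transects = 10) {
  fail <- function(species, constraint) {
    stop("invalid detection table: species '", species, "' violates ",
         constraint, call. = FALSE)
  }
  for (k in seq_len(nrow(table))) {
    row <- table[k, ]
    sp <- row$species
    cnt <- vapply(protocol_levels(), function(p) row[[p]], integer(1))
    if (any(cnt < 0 | cnt > n_transects)) {
      fail(sp, paste0("count range [0, ", n_transects, "]"))
    }
    ct74 <- cnt[["CT-74"]]; ct16 <- cnt[["CT-16"]]
    ar <- cnt[["AR"]]; pf <- cnt[["PF"]]; li <- cnt[["LI"]]
    a16 <- cnt[["All-16"]]; a74 <- cnt[["All-74"]]
    if (ct16 > ct74) fail(sp, "CT-16 <= CT-74 (16-day cameras nest in 74-day)")
    if (a16 > a74) fail(sp, "All-16 <= All-74")
    if (li < max(ar, pf) || li > min(n_transects, ar + pf)) {
      fail(sp, "max(AR, PF) <= LI <= min(n_transects, AR + PF) (LI = AR union PF)")
    }
    if (a16 < max(ct16, li) || a16 > min(n_transects, ct16 + li)) {
      fail(sp, "max(CT-16, LI) <= All-16 <= min(n_transects, CT-16 + LI)")
    }
    if (a74 < max(ct74, li) || a74 > min(n_transects, ct74 + li)) {
      fail(sp, "max(CT-74, LI) <= All-74 <= min(n_transects, CT-74 + LI)")
    }
    # overlap sizes |CT-x ∩ LI| = CT-x + LI - All-x must respect CT-16 ⊆ CT-74
    if (ct16 - a16 > ct74 - a74) {
      fail(sp, "CT-16 - All-16 <= CT-74 - All-74 (camera/LI overlap feasibility)")
    }
  }
  invisible(table)
}

#' Write a species detection table to CSV
#'
#' Round-trips with [load_detection_table()]: writing and reloading
#' reproduces the table field for field.
#'
#' @param table A validated detection-table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
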