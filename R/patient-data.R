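#' Canonical columns of a patient hemodynamics table
#'
#' Column order and types expected by [load_patient_table()]. All flows are
#' BSA-indexed (L/min/m^2), resistances BSA-indexed (WU.m^2), pressures mmHg.
#'
#' @keywords internal
patient_columns <- function() {
  c(
    pid = "c", sex = "c", bsa = "d", age = "d",
    q_svc = "d", q_lpa = "d", q_rpa = "d",
    pvr_cath = "d", qp_cath = "d",
    p_svc = "d", p_lpa = "d", p_rpa = "d", p_la = "d", p_ra = "d"
  )
}

#' Path to the bundled 16-patient Glenn reference cohort
#'
#' A table of demographic and hemodynamic data for 16 children with Glenn
#' physiology: sex, body surface area (BSA, m^2), age, BSA-indexed CMR flows
#' in the superior vena cava and the two pulmonary arteries (L/min/m^2),
#' catheterization-derived total pulmonary vascular resistance (WU.m^2) and
#' Fick pulmonary flow (L/min/m^2), and mean catheterization pressures at the
#' SVC, LPA, RPA, left atrium and right atrium (mmHg).
#'
#' @return Path to the bundled CSV file.
#' @seealso [load_patient_table()]
#' @export
#' @examples
#' cohort <- load_patient_table(glenn_cohort_path())
#' nrow(cohort)
glenn_cohort_path <- function() {
  system.file("extdata", "table1.csv", package = "glennpvr", mustWork = TRUE)
}

#' Load a patient hemodynamics table
#'
#' Reads a CSV of per-patient hemodynamics (one row per patient) and validates
#' it against the canonical schema. Row order is preserved.
#'
#' @param source Path to a CSV file, or `"bundled"` for the reference cohort
#'   shipped with the package.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the headers actually present in the file, e.g.
#'   `c(q_svc = "Q_SVC", p_la = "P_LA")`. Unmapped canonical names are looked
#'   up directly (case-insensitively).
#' @return A tibble with columns `pid`, `sex`, `bsa`, `age`, `q_svc`, `q_lpa`,
#'   `q_rpa`, `pvr_cath`, `qp_cath`, `p_svc`, `p_lpa`, `p_rpa`, `p_la`, `p_ra`.
#' @details Validation enforces `bsa > 0`, non-negative flows and finite
#'   pressures for every row. A missing column raises an error naming the
#'   column; a non-numeric cell raises an error naming the row and column.
#' @export
#' @examples
#' cohort <- load_patient_table("bundled")
#' dplyr::glimpse(cohort)
load_patient_table <- function(source = "bundled", col_map = NULL) {
  path <- if (identical(source, "bundled")) glenn_cohort_path() else source
  if (!file.exists(path)) {
    stop("patient table not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    strip.white = TRUE),
    error = function(e) {
      stop("patient table schema error: cannot read '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (nrow(raw) == 0L || ncol(raw) <= 1L) {
    stop("patient table schema error: file '", path,
         "' has no data rows with the expected header", call. = FALSE)
  }

  spec <- patient_columns()
  canonical <- names(spec)
  lookup <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) {
      stop("unknown canonical column(s) in col_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lookup[names(col_map)] <- unname(col_map)
  }

  header_lc <- tolower(trimws(names(raw)))
  idx <- vapply(canonical, function(cn) {
    hit <- which(header_lc == tolower(lookup[[cn]]))
    if (length(hit) == 0L) NA_integer_ else hit[[1L]]
  }, integer(1))
  if (anyNA(idx)) {
    stop("patient table schema error: missing column(s): ",
         paste(canonical[is.na(idx)], collapse = ", "), call. = FALSE)
  }

  out <- tibble::as_tibble(stats::setNames(raw[idx], canonical))
  for (cn in canonical[spec == "d"]) {
    val <- suppressWarnings(as.numeric(out[[cn]]))
    bad <- which(is.na(val) & !is.na(out[[cn]]) & !(out[[cn]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf(
        "patient table parse error: non-numeric value '%s' in column '%s', row %d",
        out[[cn]][bad[1L]], cn, bad[1L]), call. = FALSE)
    }
    out[[cn]] <- val
  }
  validate_patient_records(out)
  out
}

validate_patient_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!is.finite(records$bsa)) || any(records$bsa <= 0)) {
    stop("invalid patient record: bsa must be finite and > 0", call. = FALSE)
  }
  flows <- c("q_svc", "q_lpa", "q_rpa", "qp_cath")
  for (cn in flows) {
    if (any(!is.finite(records[[cn]])) || any(records[[cn]] < 0)) {
      stop("invalid patient record: ", cn, " must be finite and >= 0",
           call. = FALSE)
    }
  }
  for (cn in c("p_svc", "p_lpa", "p_rpa", "p_la", "p_ra")) {
    if (any(!is.finite(records[[cn]]))) {
      stop("invalid patient record: ", cn, " must be finite", call. = FALSE)
    }
  }
  invisible(records)
}

#' Write a patient table back to CSV
#'
#' Inverse of [load_patient_table()]; loading the written file reproduces all
#' numeric fields exactly at the printed precision.
#'
#' @param records Patient table (tibble from [load_patient_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path) {
  validate_patient_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort summary: per-column mean and sample SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of every
#' numeric column, as printed in the summary row of cohort tables.
#'
#' @param records Patient table with at least 2 rows.
#' @return A tibble with columns `column`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' summarize_cohort(load_patient_table("bundled"))
summarize_cohort <- function(records) {
  if (nrow(records) < 2L) {
    stop("insufficient data: cohort summary requires n >= 2 records",
         call. = FALSE)
  }
  num <- records[vapply(records, is.numeric, logical(1))]
  tibble::tibble(
    column = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    n = nrow(num)
  )
}

#' Convert between absolute and BSA-indexed flow
#'
#' Indexing divides an absolute flow (L/min) by body surface area (m^2) so
#' that patients of different sizes are comparable; `deindex_flow()` is the
#' exact inverse. The indexed-resistance convention follows: an indexed
#' resistance (WU.m^2) times an indexed flow (L/min/m^2) is a pressure (mmHg).
#'
#' @param q_abs Absolute flow, L/min.
#' @param q_indexed Indexed flow, L/min/m^2.
#' @param bsa Body surface area, m^2 (> 0).
#' @return Flow in the other convention.
#' @export
#' @examples
#' index_flow(2.0, 1.0)
#' deindex_flow(index_flow(1.3, 0.64), 0.64)
index_flow <- function(q_abs, bsa) {
  check_bsa(bsa)
  q_abs / bsa
}

#' @rdname index_flow
#' @export
deindex_flow <- function(q_indexed, bsa) {
  check_bsa(bsa)
  q_indexed * bsa
}

check_bsa <- function(bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("bsa must be finite and > 0", call. = FALSE)
  }
  invisible(bsa)
}
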