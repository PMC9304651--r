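#' Training-set expression ranges of the 15 genes
#'
#' Per-gene minimum and maximum raw microarray expression values over the
#' 239-record training set, used as the fixed normalization ranges so that
#' trained networks behave identically regardless of which subset of data is
#' loaded. Columns: `gene` (index), `name`, `min`, `max`.
#'
#' @format A tibble with 15 rows.
#' @export
gene_ranges <- tibble::tribble(
  ~gene, ~name,     ~min,     ~max,
  1L,  "SERP1",    315.8,   1879.8,
  2L,  "NPM1",    1556.8,   9849.1,
  3L,  "PIK3R1",    59.8,    437.1,
  4L,  "APEX1",    200.7,   1741.2,
  5L,  "DAPP1",     69.9,    564.5,
  6L,  "NRAS",      38.8,    679.2,
  7L,  "RRAGC",    148.9,    679.2,
  8L,  "CFLAR",    135.7,   2000.7,
  9L,  "CXCL5",      1.09,    58.8,
  10L, "IL15",      13.3,    562.05,
  11L, "NFKB2",     54.7,   2848.01,
  12L, "COX7C",    559.5,   5476.9,
  13L, "RPS7",    1142.48, 12167.3,
  14L, "RPS13",   2079.7,  23208.7,
  15L, "UQCRH",    370.82,  5554.15
)

gene_cols <- function() sprintf("gene_%02d", 1:15)

gene_column <- function(data, gene) {
  col <- sprintf("gene_%02d", gene)
  if (!col %in% names(data))
    abort(sprintf("column `%s` not found in the patient table", col))
  data[[col]]
}

#' Normalize raw expression values to the per-gene training range
#'
#' Affine min-max normalization, `p = (e - Min) / (Max - Min)`, using the
#' per-gene range in `stats`. Values outside the range map outside `[0, 1]`
#' and are accepted: they still encode a meaningful illumination switch
#' time.
#'
#' @param e Raw expression value(s).
#' @param gene Gene index (1..15 for the published ranges).
#' @param stats Range table with columns `gene`, `min`, `max`; defaults to
#'   the published training ranges [gene_ranges].
#' @return Normalized value(s) `p`.
#' @examples
#' normalize_expression(12167.3, gene = 13)  # top of the range -> 1
#' normalize_expression(0, gene = 13)        # below the range -> negative
#' @export
normalize_expression <- function(e, gene, stats = concilium::gene_ranges) {
  row <- stats[stats$gene == gene, ]
  if (nrow(row) != 1L)
    abort(sprintf("no normalization range for gene %d", gene))
  if (row$max <= row$min)
    abort(sprintf("degenerate range for gene %d: max <= min", gene))
  (e - row$min) / (row$max - row$min)
}

#' Inverse of the min-max normalization
#'
#' @inheritParams normalize_expression
#' @param p Normalized value(s).
#' @return Raw expression value(s).
#' @export
denormalize_expression <- function(p, gene, stats = concilium::gene_ranges) {
  row <- stats[stats$gene == gene, ]
  row$min + p * (row$max - row$min)
}

#' Add normalized-expression columns to a patient table
#'
#' @param data A patient tibble with `gene_01`..`gene_15` columns.
#' @param stats Range table (see [normalize_expression()]).
#' @return `data` with added columns `p_01`..`p_15`.
#' @export
normalize_table <- function(data, stats = concilium::gene_ranges) {
  for (g in stats$gene) {
    data[[sprintf("p_%02d", g)]] <-
      normalize_expression(gene_column(data, g), g, stats)
  }
  data
}

#' Per-gene min/max computed from a loaded table
#'
#' @param data A patient tibble.
#' @return A tibble shaped like [gene_ranges] (without `name`).
#' @export
gene_stats <- function(data) {
  tibble(
    gene = 1:15,
    min = map_dbl(1:15, function(g) min(gene_column(data, g))),
    max = map_dbl(1:15, function(g) max(gene_column(data, g)))
  )
}

#' Read a patient table
#'
#' Two dialects are supported. The canonical CSV has columns
#' `gene_01`..`gene_15` (ordered as in [gene_ranges]), `outcome` (0 =
#' nonresponsive, 1 = responsive), `drug` (`PS341` for bortezomib, `DEX` for
#' dexamethasone) and `patient_id`. The spreadsheet dialect is the
#' supplementary clinical-database layout: expression in columns A-O,
#' outcome in Q, drug in S and the GSM identifier in U (requires the
#' `readxl` package).
#'
#' @param path File path.
#' @param dialect `"csv"` (canonical) or `"xlsx"` (supplementary layout);
#'   guessed from the file extension by default.
#' @return A validated patient tibble; a per-drug/outcome record summary is
#'   printed via `message()`.
#' @export
read_patient_table <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  data <- if (dialect == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      abort("the spreadsheet dialect requires the `readxl` package")
    raw <- readxl::read_excel(path, col_names = FALSE)
    supplementary_layout_to_canonical(raw)
  }
  validate_patient_table(data)
}

# Map the supplementary spreadsheet layout (expression in columns A-O,
# outcome in Q, drug in S, GSM id in U) onto the canonical column names.
# A leading header row is dropped if its first expression cell is not
# numeric.
supplementary_layout_to_canonical <- function(raw) {
  if (ncol(raw) < 21)
    abort("supplementary layout needs at least 21 columns (A through U)")
  if (is.na(suppressWarnings(as.numeric(raw[[1]][1]))))
    raw <- raw[-1, ]
  out <- setNames(as_tibble(lapply(raw[1:15], as.numeric)), gene_cols())
  out$outcome <- as.integer(as.numeric(raw[[17]]))
  out$drug <- as.character(raw[[19]])
  out$patient_id <- as.character(raw[[21]])
  out
}

validate_patient_table <- function(data) {
  missing <- setdiff(c(gene_cols(), "outcome"), names(data))
  if (length(missing))
    abort(c("patient table is missing required columns",
            paste(missing, collapse = ", ")))
  for (col in gene_cols())
    if (!is.numeric(data[[col]]))
      abort(sprintf("expression column `%s` is not numeric", col))
  if (!all(data$outcome %in% 0:1))
    abort("`outcome` must be binary: 0 (nonresponsive) or 1 (responsive)")
  data <- as_tibble(data)
  if ("drug" %in% names(data)) {
    summ <- data |>
      count(.data$drug, .data$outcome) |>
      summarise(txt = paste(sprintf("%d %s", .data$n,
                                    ifelse(.data$outcome == 1, "R", "N")),
                            collapse = " / "),
                .by = "drug")
    message(sprintf("%d records: %s", nrow(data),
                    paste(summ$drug, summ$txt, sep = " ", collapse = "; ")))
  }
  data
}

#' Write a patient table as canonical CSV
#'
#' @param data A patient tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
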