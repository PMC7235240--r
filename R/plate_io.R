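cq_columns <- c("rna", "kit", "rt_input_ng", "qpcr_dilution_level",
                "amplicon", "replicate", "cq", "role")
cq_key_columns <- c("rna", "kit", "rt_input_ng", "qpcr_dilution_level",
                    "amplicon", "replicate")
group_key_columns <- c("rna", "kit", "rt_input_ng", "qpcr_dilution_level",
                       "amplicon")

#' Validate a long-format Cq table
#'
#' Checks the canonical schema: one row per well, columns `rna`, `kit`,
#' `rt_input_ng`, `qpcr_dilution_level`, `amplicon`, `replicate`, `cq`,
#' `role`. `cq` is `NA` for wells that never crossed the detection
#' threshold within the 40-cycle run ("Undetermined"); finite values must
#' lie in (0, 40]. Well keys must be unique.
#'
#' @param table A data frame.
#' @return The table as a tibble, invisibly usable downstream.
#' @export
validate_cq_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(cq_columns, names(table))
  if (length(missing) > 0) {
    stop("Cq table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  table$rt_input_ng <- as.numeric(table$rt_input_ng)
  table$qpcr_dilution_level <- as.numeric(table$qpcr_dilution_level)
  table$replicate <- as.integer(table$replicate)
  bad_role <- !table$role %in% c("sample", "RT0", "RTminus", "gDNA")
  if (any(bad_role)) {
    stop("invalid role value(s): ",
         paste(unique(table$role[bad_role]), collapse = ", "), call. = FALSE)
  }
  finite <- is.finite(table$cq)
  if (any(finite & (table$cq <= 0 | table$cq > 40))) {
    n <- sum(finite & (table$cq <= 0 | table$cq > 40))
    stop("Cq values outside (0, 40] in ", n, " row(s); a 40-cycle run ",
         "cannot produce them (use Undetermined/NA for no amplification)",
         call. = FALSE)
  }
  key <- do.call(paste, c(table[cq_key_columns], list(table$role, sep = "\r")))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate well key(s): ",
         paste(utils::head(gsub("\r", "/", dups), 5), collapse = "; "),
         if (length(dups) > 5) " ..." else "", call. = FALSE)
  }
  table[, cq_columns]
}

#' Read a long-format qPCR result table
#'
#' Reads the canonical long CSV dialect: one well per row, UTF-8, "."
#' decimal separator, header with the canonical column names. The literal
#' cell values `Undetermined`, `NA` or an empty cell in the `cq` column map
#' to an undetermined Cq (`NA`); they are preserved, never coerced to 40.
#' A `col_map` can rename non-canonical headers (e.g. from a supplementary
#' spreadsheet export saved as CSV) before validation.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(cq = "Cq.Value")`.
#' @return A validated tibble (see [validate_cq_table()]).
#' @export
read_cq_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      if (!col_map[[canonical]] %in% names(raw)) {
        stop("col_map refers to absent column: ", col_map[[canonical]],
             call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[canonical]]] <- canonical
    }
  }
  missing <- setdiff(cq_columns, names(raw))
  if (length(missing) > 0) {
    stop("Cq table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cq_chr <- trimws(raw$cq)
  undet <- is.na(cq_chr) | cq_chr == "" | toupper(cq_chr) %in% c("UNDETERMINED", "NA")
  cq <- suppressWarnings(as.numeric(cq_chr))
  if (any(!undet & is.na(cq))) {
    stop("non-numeric cq value(s): ",
         paste(unique(cq_chr[!undet & is.na(cq)]), collapse = ", "),
         call. = FALSE)
  }
  cq[undet] <- NA_real_
  out <- tibble::tibble(
    rna = raw$rna,
    kit = raw$kit,
    rt_input_ng = suppressWarnings(as.numeric(raw$rt_input_ng)),
    qpcr_dilution_level = suppressWarnings(as.numeric(raw$qpcr_dilution_level)),
    amplicon = raw$amplicon,
    replicate = as.integer(raw$replicate),
    cq = cq,
    role = raw$role
  )
  validate_cq_table(out)
}

#' Write a Cq table in the canonical long CSV dialect
#'
#' Undetermined Cq values are written as the literal `Undetermined`.
#' Writing then re-reading a table reproduces it exactly, and re-writing a
#' freshly read canonical file is byte-identical.
#'
#' @param table A validated Cq table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path) {
  table <- validate_cq_table(table)
  out <- table
  out$cq <- ifelse(is.na(table$cq), "Undetermined", sprintf("%.15g", table$cq))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Check a Cq table for completeness against a design
#'
#' Compares the well groups present in a table with those a design
#' enumerates. A group is a (rna, kit, RT input, qPCR dilution, amplicon)
#' combination; replicate rows within a group are counted. The table
#' passes when every designed group is present with at least two
#' replicates (the minimum for best-duplicate condensation) and carries no
#' unexpected groups.
#'
#' @param table A validated Cq table.
#' @param design A [design_grid()].
#' @return A list with elements `missing` (tibble of absent designed
#'   groups), `unexpected` (tibble of observed groups not in the design),
#'   `replicate_counts` (tibble of per-group counts with an `ok` flag) and
#'   `pass` (logical).
#' @export
validate_against_design <- function(table, design) {
  table <- validate_cq_table(table)
  stopifnot(inherits(design, "design_grid"))
  expected <- dplyr::distinct(
    enumerate_wells(design)[, c(group_key_columns, "role")]
  )
  expected_samples <- expected[expected$role == "sample", group_key_columns]
  observed <- table[table$role == "sample", ]
  counts <- dplyr::count(observed, dplyr::across(dplyr::all_of(group_key_columns)),
                         name = "n_replicates")
  joined <- dplyr::full_join(
    dplyr::mutate(expected_samples, .designed = TRUE),
    dplyr::mutate(counts, .observed = TRUE),
    by = group_key_columns
  )
  missing <- joined[is.na(joined$.observed), group_key_columns]
  unexpected <- joined[is.na(joined$.designed),
                       c(group_key_columns, "n_replicates")]
  present <- joined[!is.na(joined$.observed) & !is.na(joined$.designed), ]
  replicate_counts <- tibble::as_tibble(
    present[, c(group_key_columns, "n_replicates")]
  )
  replicate_counts$ok <- replicate_counts$n_replicates >= 2
  pass <- nrow(missing) == 0 && nrow(unexpected) == 0 &&
    all(replicate_counts$ok)
  list(
    missing = tibble::as_tibble(missing),
    unexpected = tibble::as_tibble(unexpected),
    replicate_counts = replicate_counts,
    pass = pass
  )
}
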