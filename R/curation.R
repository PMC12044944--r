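#' Default ChEMBL export column mapping
#'
#' Maps the internal record fields to the column headers of a ChEMBL
#' activity export. Override any entry to parse other layouts.
#'
#' @return Named character vector with entries `id`, `smiles`, `relation`,
#'   `value`, `units`, `assay`.
#' @export
chembl_columns <- function() {
  c(id = "Molecule ChEMBL ID", smiles = "Smiles",
    relation = "Standard Relation", value = "Standard Value",
    units = "Standard Units", assay = "Assay Type")
}

#' Parse a ChEMBL-style activity table
#'
#' Reads a CSV/TSV activity export and converts rows into compound records.
#' Only rows whose standard relation is exactly `'='` are retained; rows with
#' other relations (`<`, `>`, `/`, ...), missing or non-positive values,
#' unconvertible units, or unparsable SMILES are dropped with an audited
#' reason. Retained rows get a pIC50 (`-log10` of the molar IC50). Input row
#' order is preserved.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, `.tsv`/`.txt` meaning tab).
#' @param column_map Named mapping of record fields to file columns; see
#'   [chembl_columns()]. Entries `units` and `assay` are optional columns.
#' @param units_policy `"convert"` to convert M/mM/uM/pM to nM, `"reject"`
#'   to drop any row not already in nM.
#' @return A tibble of records (`compound_id`, `smiles`, `relation`,
#'   `standard_value` in nM, `assay_kind`, `pic50`) with attribute `audit`,
#'   a tibble of per-row drop reasons (`row`, `reason`).
#' @export
parse_activity_table <- function(path, column_map = chembl_columns(),
                                 units_policy = c("convert", "reject")) {
  units_policy <- match.arg(units_policy)
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              class = "stackscreen_config_error")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  assert_that(nrow(raw) > 0, "empty input file",
              class = "stackscreen_empty_input")
  for (field in c("id", "smiles", "relation", "value")) {
    assert_that(column_map[[field]] %in% names(raw),
                sprintf("missing mandatory column '%s' (field '%s')",
                        column_map[[field]], field),
                class = "stackscreen_config_error")
  }
  get_col <- function(field, default = NA_character_) {
    cn <- column_map[[field]]
    if (!is.null(cn) && cn %in% names(raw)) as.character(raw[[cn]]) else
      rep(default, nrow(raw))
  }
  rel <- gsub("[\"' ]", "", get_col("relation"))
  val <- suppressWarnings(as.numeric(get_col("value")))
  units <- get_col("units", default = "nM")
  units[is.na(units) | units == ""] <- "nM"
  to_nm <- c(M = 1e9, mM = 1e6, uM = 1e3, `µM` = 1e3, nM = 1, pM = 1e-3)

  rows <- tibble(
    row = seq_len(nrow(raw)),
    compound_id = get_col("id"),
    smiles = get_col("smiles"),
    relation = rel,
    standard_value = val,
    units = units,
    assay_kind = get_col("assay", default = "")
  )
  reason <- rep(NA_character_, nrow(rows))
  reason[is.na(reason) & rows$relation != "="] <- "relation"
  reason[is.na(reason) & (is.na(rows$standard_value))] <- "missing value"
  reason[is.na(reason) & rows$standard_value <= 0] <- "nonpositive value"
  known <- rows$units %in% names(to_nm)
  if (units_policy == "reject") {
    reason[is.na(reason) & rows$units != "nM"] <- "units"
  } else {
    reason[is.na(reason) & !known] <- "units"
  }
  ok <- is.na(reason)
  parsed_smiles <- rep(NA_character_, nrow(rows))
  if (any(ok)) {
    std <- standardize_structure(rows$smiles[ok], on_error = "na")
    parsed_smiles[ok] <- std
    reason[ok][is.na(std)] <- "unparsable smiles"
  }
  ok <- is.na(reason)
  records <- rows[ok, ]
  records$standard_value <- unname(records$standard_value *
                                     to_nm[records$units])
  records$pic50 <- to_pic50(records$standard_value)
  records <- records[, c("compound_id", "smiles", "relation",
                         "standard_value", "assay_kind", "pic50")]
  audit <- tibble(row = rows$row[!is.na(reason)],
                  reason = reason[!is.na(reason)])
  attr(records, "audit") <- audit
  records
}

#' Convert an IC50 in nM to pIC50
#'
#' `pIC50 = -log10(IC50 [M]) = -log10(value * 1e-9)` for a value in nM, so
#' 1000 nM gives 6 and 1 nM gives 9. Strictly decreasing in the IC50.
#'
#' @param standard_value Positive IC50 values in nM.
#' @return Numeric pIC50 values.
#' @examples
#' to_pic50(c(1000, 1, 50))
#' @export
to_pic50 <- function(standard_value) {
  assert_that(all(standard_value > 0, na.rm = TRUE) && !anyNA(standard_value),
              "IC50 values must be positive and non-missing",
              class = "stackscreen_domain_error")
  -log10(standard_value * 1e-9)
}

#' Assign activity labels from pIC50 cutoffs
#'
#' Compounds at or above `active_cutoff` are active, below `inactive_cutoff`
#' inactive, and in between intermediate (excluded from modelling
#' downstream). Defaults follow the common potency convention of active at
#' pIC50 >= 6 (IC50 <= 1 uM) and inactive below 5 (IC50 > 10 uM).
#'
#' @param pic50 Numeric pIC50 values.
#' @param active_cutoff,inactive_cutoff Cutoffs with
#'   `active_cutoff >= inactive_cutoff`.
#' @return Character vector in `{"active", "inactive", "intermediate"}`.
#' @examples
#' label_activity(c(7, 4, 5.5))
#' @export
label_activity <- function(pic50, active_cutoff = 6, inactive_cutoff = 5) {
  assert_that(active_cutoff >= inactive_cutoff,
              "active_cutoff must be >= inactive_cutoff",
              class = "stackscreen_config_error")
  dplyr::case_when(
    pic50 >= active_cutoff ~ "active",
    pic50 < inactive_cutoff ~ "inactive",
    TRUE ~ "intermediate"
  )
}

new_curated_dataset <- function(data, audit = tibble(reason = character(),
                                                     n = integer())) {
  counts <- table(factor(data$label, levels = c("active", "inactive",
                                                "intermediate")))
  attr(data, "n_active") <- unname(counts[["active"]])
  attr(data, "n_inactive") <- unname(counts[["inactive"]])
  attr(data, "audit") <- audit
  class(data) <- unique(c("curated_tbl", class(data)))
  data
}

#' Curate parsed activity records into a labelled dataset
#'
#' Standardizes every structure to its canonical key (salt-stripped largest
#' organic fragment, canonical SMILES), collapses duplicate structures to a
#' single record at the median pIC50, assigns activity labels, and audits
#' every dropped or merged row. Intermediates are retained but flagged and
#' excluded from the class counts. Curation is idempotent: re-curating the
#' result changes nothing.
#'
#' @param records Tibble from [parse_activity_table()] (or any data frame
#'   with `compound_id`, `smiles` or `canonical_smiles`, and `pic50`).
#' @param active_cutoff,inactive_cutoff Passed to [label_activity()].
#' @return A `curated_tbl` tibble (`compound_id`, `canonical_smiles`,
#'   `pic50`, `label`) with attributes `n_active`, `n_inactive`, `audit`.
#' @export
curate_dataset <- function(records, active_cutoff = 6, inactive_cutoff = 5) {
  assert_that(nrow(records) > 0, "no records to curate",
              class = "stackscreen_empty_dataset")
  smiles_col <- if ("canonical_smiles" %in% names(records)) {
    "canonical_smiles"
  } else "smiles"
  std <- standardize_structure(records[[smiles_col]], on_error = "na")
  keep <- !is.na(std)
  n_unparsable <- sum(!keep)
  data <- tibble(
    compound_id = as.character(records$compound_id[keep]),
    canonical_smiles = std[keep],
    pic50 = records$pic50[keep]
  )
  n_in <- nrow(data)
  data <- data |>
    group_by(.data$canonical_smiles) |>
    summarise(compound_id = .data$compound_id[1],
              pic50 = median(.data$pic50), n_merged = n(),
              .groups = "drop") |>
    arrange(match(.data$compound_id, records$compound_id))
  n_dupes <- n_in - nrow(data)
  data$label <- label_activity(data$pic50, active_cutoff, inactive_cutoff)
  n_intermediate <- sum(data$label == "intermediate")
  assert_that(any(data$label %in% c("active", "inactive")),
              "no labelled records after curation",
              class = "stackscreen_empty_dataset")
  audit <- tibble(
    reason = c("unparsable smiles", "duplicate structure", "intermediate"),
    n = c(n_unparsable, n_dupes, n_intermediate)
  )
  data <- data[, c("compound_id", "canonical_smiles", "pic50", "label")]
  new_curated_dataset(data, audit = audit)
}

#' Stratified train/test split of a curated dataset
#'
#' Splits the labelled records (intermediates excluded) into train and test
#' partitions, preserving the class ratio: each class contributes
#' `round(train_fraction * class size)` compounds to the training partition.
#' Deterministic under `seed`; partitions are disjoint and their union is
#' the labelled set.
#'
#' @param data A `curated_tbl` (or data frame with a `label` column).
#' @param train_fraction Fraction per class assigned to training (default
#'   0.75).
#' @param seed Integer seed.
#' @return A list with `train` and `test` curated tibbles.
#' @export
split_train_test <- function(data, train_fraction = 0.75, seed = 1) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)",
              class = "stackscreen_config_error")
  labelled <- data[data$label %in% c("active", "inactive"), ]
  tab <- table(labelled$label)
  assert_that(length(tab) == 2 && all(tab >= 2),
              "each class needs at least 2 members for a stratified split",
              class = "stackscreen_stratification_error")
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(labelled)), labelled$label), function(ix) {
      n_tr <- max(1L, min(length(ix) - 1L, round(train_fraction * length(ix))))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  audit <- attr(data, "audit") %||% tibble(reason = character(), n = integer())
  list(
    train = new_curated_dataset(labelled[sort(idx_train), ], audit = audit),
    test = new_curated_dataset(labelled[-sort(idx_train), ], audit = audit)
  )
}

#' @export
print.curated_tbl <- function(x, ...) {
  cat(sprintf("Curated dataset: %d active, %d inactive (%d rows)\n",
              attr(x, "n_active"), attr(x, "n_inactive"), nrow(x)))
  NextMethod()
}

#' Write a curated dataset with its audit sidecar
#'
#' @param data A `curated_tbl`.
#' @param path Output CSV path; the audit is written to `<path>.audit.json`.
#' @return `path`, invisibly.
#' @export
write_curated <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  jsonlite::write_json(
    list(n_active = attr(data, "n_active"),
         n_inactive = attr(data, "n_inactive"),
         audit = attr(data, "audit")),
    paste0(path, ".audit.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
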