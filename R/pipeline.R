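# Bioactivity preprocessing: ChEMBL-export-style CSV -> cleaned, labeled,
# pIC50-annotated records with a train/test split.
#
# Stage order: clean (salts, missing IC50, annotation filter) -> dedupe ->
# label -> exclude intermediates -> pIC50 -> split. Counts removed by each
# rule are reported via message() and attached as attributes.

#' Load a bioactivity table from a ChEMBL-export-style CSV
#'
#' @param path CSV file with a header row.
#' @param smiles_col,value_col Column names holding the SMILES and the IC50
#'   standard value (nM).
#' @return A data frame preserving row order and all input columns, with
#'   standardized `canonical_smiles` and `ic50_nm` columns added (blank or
#'   unparsable values become `NA`).
#' @export
load_bioactivity_csv <- function(path, smiles_col = "canonical_smiles",
                                 value_col = "standard_value") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty bioactivity table: ", path, call. = FALSE)
  for (col in c(smiles_col, value_col)) {
    if (!col %in% names(df)) {
      .raise("math_missing_column_error",
             paste0("required column '", col, "' not found in ", path))
    }
  }
  df$canonical_smiles <- as.character(df[[smiles_col]])
  df$ic50_nm <- suppressWarnings(as.numeric(df[[value_col]]))
  df
}

#' Clean bioactivity records
#'
#' Applies, in order: (1) optional unit check (rows whose unit column is
#' neither `nM` nor blank are dropped); (2) removal of rows with missing
#' IC50; (3) salt stripping — multi-fragment (dot-disconnected) SMILES are
#' replaced by their largest fragment (heavy-atom count, ties broken by
#' molecular weight then lexicographic canonical SMILES); (4) optional
#' annotation filter dropping rows whose `annotation_col` matches any
#' `blocklist` pattern (case-insensitive), approximating the curation of
#' agonist/binder-only entries; (5) removal of unparsable SMILES. All
#' surviving SMILES are canonicalized, so the operation is idempotent.
#'
#' @param records Data frame with `canonical_smiles` and `ic50_nm` columns.
#' @param annotation_col Optional name of a column to filter on.
#' @param blocklist Character patterns (regular expressions) matched against
#'   the annotation column.
#' @param units_col Optional name of a units column to assert against `nM`.
#' @return The cleaned records; counts removed per rule are in the
#'   `"removed"` attribute and reported with `message()`.
#' @export
clean_compounds <- function(records, annotation_col = NULL,
                            blocklist = c("\\bagonist\\b", "\\bbinder\\b"),
                            units_col = NULL) {
  stopifnot(is.data.frame(records),
            all(c("canonical_smiles", "ic50_nm") %in% names(records)))
  removed <- c(bad_units = 0L, missing_value = 0L, annotation = 0L,
               unparsable = 0L)
  stripped <- 0L

  if (!is.null(units_col) && units_col %in% names(records)) {
    u <- trimws(as.character(records[[units_col]]))
    ok <- is.na(u) | u == "" | u == "nM"
    removed["bad_units"] <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }

  ok <- !is.na(records$ic50_nm)
  removed["missing_value"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  if (!is.null(annotation_col) && annotation_col %in% names(records)) {
    ann <- tolower(as.character(records[[annotation_col]]))
    hit <- Reduce(`|`, lapply(blocklist,
                              function(p) grepl(p, ann, perl = TRUE)))
    hit[is.na(hit)] <- FALSE
    removed["annotation"] <- sum(hit)
    records <- records[!hit, , drop = FALSE]
  }

  if (nrow(records)) {
    recs <- .mol_query("canon", records$canonical_smiles)
    parsable <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
    removed["unparsable"] <- sum(!parsable)
    records <- records[parsable, , drop = FALSE]
    recs <- recs[parsable]
    stripped <- sum(vapply(recs, function(r) r$n_fragments > 1L, logical(1)))
    records$canonical_smiles <- vapply(recs, function(r) r$canonical_smiles,
                                       character(1))
  }

  message("clean_compounds: dropped ", removed["bad_units"],
          " non-nM unit(s), ", removed["missing_value"],
          " missing IC50, ", removed["annotation"],
          " annotation-filtered, ", removed["unparsable"],
          " unparsable; stripped ", stripped, " salt(s)")
  attr(records, "removed") <- removed
  attr(records, "salts_stripped") <- stripped
  records
}

#' Remove duplicate canonical SMILES
#'
#' Keeps the first occurrence of each canonical SMILES in stable order.
#' With `aggregate = "median"` the kept row's IC50 is replaced by the
#' median over all measurements of that compound.
#'
#' @param records Data frame with a `canonical_smiles` column.
#' @param aggregate `"first"` (default) or `"median"`.
#' @return The deduplicated records; the number of rows removed is in the
#'   `"removed"` attribute.
#' @export
dedupe_smiles <- function(records, aggregate = c("first", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records))
  dup <- duplicated(records$canonical_smiles)
  out <- records[!dup, , drop = FALSE]
  if (aggregate == "median" && any(dup)) {
    med <- tapply(records$ic50_nm, records$canonical_smiles, stats::median,
                  na.rm = TRUE)
    out$ic50_nm <- as.numeric(med[out$canonical_smiles])
  }
  message("dedupe_smiles: removed ", sum(dup), " duplicate(s)")
  attr(out, "removed") <- sum(dup)
  out
}

#' Convert IC50 (nM) to pIC50
#'
#' `pIC50 = -log10(molar IC50) = 9 - log10(IC50 in nM)`.
#'
#' @param ic50_nm Positive IC50 values in nanomolar.
#' @return pIC50 values (dimensionless); strictly decreasing in `ic50_nm`.
#' @export
to_pic50 <- function(ic50_nm) {
  if (any(!is.finite(ic50_nm)) || any(ic50_nm <= 0)) {
    stop("IC50 values must be positive and finite", call. = FALSE)
  }
  9 - log10(ic50_nm)
}

#' Assign activity classes from IC50
#'
#' IC50 <= 1000 nM is `"active"`, >= 10000 nM is `"inactive"`, values in
#' between are `"intermediate"` (retained but flagged). Also adds the
#' `pic50` column.
#'
#' @param records Data frame with an `ic50_nm` column of positive values.
#' @return The records with `label` and `pic50` columns added.
#' @export
assign_labels <- function(records) {
  stopifnot(is.data.frame(records), "ic50_nm" %in% names(records))
  ic <- records$ic50_nm
  if (any(!is.finite(ic)) || any(ic <= 0)) {
    stop("IC50 values must be positive; run clean_compounds() first",
         call. = FALSE)
  }
  records$label <- ifelse(ic <= 1000, "active",
                          ifelse(ic >= 10000, "inactive", "intermediate"))
  records$pic50 <- to_pic50(ic)
  records
}

#' Random train/test split
#'
#' Excludes `"intermediate"` records, then assigns a random
#' `test_fraction` of the remainder to the test set, deterministically for
#' a given seed.
#'
#' @param records Labeled records (see [assign_labels()]).
#' @param test_fraction Fraction assigned to the test set, in (0, 1).
#' @param seed RNG seed.
#' @return A list with `train` and `test` data frames (disjoint, union
#'   equal to the non-intermediate input).
#' @export
split_dataset <- function(records, test_fraction = 0.2, seed = 42L) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  records <- records[records$label != "intermediate", , drop = FALSE]
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 non-intermediate records", call. = FALSE)
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n) {
    stop("split would leave an empty partition", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  out <- list(train = records[-test_idx, , drop = FALSE],
              test = records[test_idx, , drop = FALSE])
  for (part in c("train", "test")) {
    tab <- table(out[[part]]$label)
    message("split_dataset: ", part, " n=", nrow(out[[part]]), " (",
            paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  out
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper applying, in order: load (when `input` is a path),
#' clean, dedupe, label, intermediate exclusion, pIC50 and split.
#'
#' @param input CSV path or a data frame from [load_bioactivity_csv()].
#' @param test_fraction,seed Passed to [split_dataset()].
#' @param annotation_col,blocklist,units_col Passed to [clean_compounds()].
#' @param aggregate Passed to [dedupe_smiles()].
#' @param smiles_col,value_col Passed to [load_bioactivity_csv()].
#' @return A data frame with columns `canonical_smiles`, `ic50_nm`,
#'   `pic50`, `label` and `split` (`"train"`/`"test"`); stage-by-stage row
#'   counts are in the `"stage_counts"` attribute.
#' @export
prepare_bioactivity <- function(input, test_fraction = 0.2, seed = 42L,
                                annotation_col = NULL,
                                blocklist = c("\\bagonist\\b", "\\bbinder\\b"),
                                units_col = "standard_units",
                                aggregate = c("first", "median"),
                                smiles_col = "canonical_smiles",
                                value_col = "standard_value") {
  records <- if (is.character(input)) {
    load_bioactivity_csv(input, smiles_col, value_col)
  } else input
  if (!"canonical_smiles" %in% names(records)) {
    records$canonical_smiles <- as.character(records[[smiles_col]])
  }
  if (!"ic50_nm" %in% names(records)) {
    records$ic50_nm <- suppressWarnings(as.numeric(records[[value_col]]))
  }
  counts <- c(loaded = nrow(records))
  records <- clean_compounds(records, annotation_col, blocklist, units_col)
  counts["cleaned"] <- nrow(records)
  records <- dedupe_smiles(records, match.arg(aggregate))
  counts["deduped"] <- nrow(records)
  records <- assign_labels(records)
  counts["intermediate"] <- sum(records$label == "intermediate")
  parts <- split_dataset(records, test_fraction, seed)
  counts["final"] <- nrow(parts$train) + nrow(parts$test)
  parts$train$split <- "train"
  parts$test$split <- "test"
  out <- rbind(parts$train, parts$test)
  keep <- c("canonical_smiles", "ic50_nm", "pic50", "label", "split")
  out <- out[, c(keep, setdiff(names(out), keep)), drop = FALSE]
  attr(out, "stage_counts") <- counts
  out
}
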