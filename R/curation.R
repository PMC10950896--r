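#' Curation settings for raw IC50 records
#'
#' Numeric curation rules applied to raw activity records before modelling:
#' a strict molecular-mass cut-off, an inclusive potency window, and a
#' maximum fold-range for replicate aggregation.
#'
#' @param max_mass Molecular mass cut-off in Daltons; records must satisfy
#'   `mol_mass < max_mass` strictly (default 1000).
#' @param potency_window Inclusive IC50 window in molar units, default
#'   `c(1e-11, 1e-5)` (10 pM to 10 uM).
#' @param aggregation_span Maximum max/min fold-range over which replicate
#'   measurements for one compound-target pair are still averaged
#'   (default 10, i.e. one order of magnitude).
#' @param require_mass When `TRUE` (default) records without a molecular
#'   mass are dropped; when `FALSE` they pass the mass filter.
#' @return A `curation_config`.
#' @export
curation_config <- function(max_mass = 1000, potency_window = c(1e-11, 1e-5),
                            aggregation_span = 10, require_mass = TRUE) {
  stop_if_not_scalar_number(max_mass, "max_mass", positive = TRUE)
  if (length(potency_window) != 2L || potency_window[1L] >= potency_window[2L] ||
      any(potency_window <= 0)) {
    stop("potency_window must be c(low, high) in molar units with 0 < low < high")
  }
  if (aggregation_span <= 1) stop("aggregation_span must exceed 1")
  structure(list(max_mass = max_mass,
                 potency_window = as.numeric(potency_window),
                 aggregation_span = aggregation_span,
                 require_mass = isTRUE(require_mass)),
            class = "curation_config")
}

#' Convert molar IC50 to pIC50
#'
#' @param potency_molar IC50 in molar units (positive).
#' @return `-log10(potency_molar)`.
#' @examples pic50(1e-7)  # 7
#' @export
pic50 <- function(potency_molar) {
  if (any(potency_molar <= 0, na.rm = TRUE)) {
    stop("potency_molar must be positive")
  }
  -log10(potency_molar)
}

check_records <- function(records) {
  needed <- c("compound_id", "target_id", "potency_molar")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("record table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(records$potency_molar <= 0, na.rm = TRUE)) {
    stop("potency_molar values must be positive")
  }
  invisible(records)
}

#' Filter raw activity records
#'
#' Retains records with molecular mass strictly below the cut-off and IC50
#' inside the potency window (inclusive at both bounds). Records lacking a
#' mass are dropped in strict mode (`require_mass = TRUE`) and pass
#' otherwise. Input order is preserved, and the operation is idempotent.
#'
#' @param records Data frame with columns `compound_id`, `target_id`,
#'   `potency_molar` and optionally `mol_mass`.
#' @param config A [curation_config()].
#' @return The retained rows of `records`.
#' @export
filter_records <- function(records, config = curation_config()) {
  check_records(records)
  stopifnot(inherits(config, "curation_config"))
  pot <- records$potency_molar
  keep_pot <- !is.na(pot) & pot >= config$potency_window[1L] &
    pot <= config$potency_window[2L]
  if ("mol_mass" %in% names(records)) {
    mass <- records$mol_mass
    keep_mass <- ifelse(is.na(mass), !config$require_mass,
                        mass < config$max_mass)
  } else {
    keep_mass <- rep(!config$require_mass, nrow(records))
  }
  out <- records[keep_pot & keep_mass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate replicate potency measurements
#'
#' Groups records by compound-target pair. Groups whose potencies span at
#' most `aggregation_span`-fold (max/min ratio) are averaged on the pIC50
#' scale - the arithmetic mean of `-log10(IC50)`, i.e. the negative log of
#' the geometric-mean IC50 - and emit one row; wider groups are discarded
#' entirely. Singletons pass through.
#'
#' @param records Data frame with columns `compound_id`, `target_id`,
#'   `potency_molar`.
#' @param config A [curation_config()]; only `aggregation_span` is used.
#' @return Data frame with columns `compound_id`, `target_id`, `pic50`, one
#'   row per retained compound-target pair.
#' @export
aggregate_replicates <- function(records, config = curation_config()) {
  check_records(records)
  if (nrow(records) == 0L) {
    return(data.frame(compound_id = character(), target_id = character(),
                      pic50 = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    pot <- records$potency_molar[idx]
    if (max(pot) / min(pot) > config$aggregation_span) return(NULL)
    data.frame(compound_id = records$compound_id[idx[1L]],
               target_id = records$target_id[idx[1L]],
               pic50 = mean(pic50(pot)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(compound_id = character(), target_id = character(),
                      pic50 = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Structural-alert filter hook
#'
#' Delegation point for external keep/drop filters (PAINS, medicinal
#' chemistry rules, aggregator alerts, anti-target removal). The predicate
#' receives one record as a single-row data frame and returns `TRUE` to keep
#' it. With no predicate the input passes through unchanged; predicate
#' errors are re-signalled with the offending compound id attached.
#'
#' @param records Data frame of raw activity records.
#' @param predicate `function(record) -> logical(1)`, or `NULL`.
#' @return The retained rows of `records`.
#' @export
apply_alert_hook <- function(records, predicate = NULL) {
  if (is.null(predicate)) return(records)
  stopifnot(is.function(predicate))
  keep <- vapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    tryCatch(isTRUE(predicate(rec)),
             error = function(e) {
               stop(sprintf("alert predicate failed for compound `%s`: %s",
                            records$compound_id[i], conditionMessage(e)),
                    call. = FALSE)
             })
  }, logical(1L))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read raw activity records from CSV
#'
#' Expects headered columns matching the raw-record fields: `compound_id`,
#' `target_id`, `potency_molar`, optionally `mol_mass` and `smiles`.
#'
#' @param path CSV file path.
#' @return Data frame of records.
#' @export
read_raw_records <- function(path) {
  check_records(read.csv(path, stringsAsFactors = FALSE))
}
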