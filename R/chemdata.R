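#' @title Permeability record curation
#' @description
#' Reading/writing tabular permeability records, InChIKey deduplication,
#' swing-range labeling around the -log10(Papp) decision threshold,
#' Caco-2 absorption binning, macrocycle ring-size strata, and
#' inter-laboratory pair deviation statistics.
#' @name chemdata
NULL

ASSAY_LEVELS <- c("CACO2", "MDCK", "RRCK", "PAMPA", "SYNTHETIC")
LABEL_LEVELS <- c("PERMEABLE", "IMPERMEABLE", "EXCLUDED")

#' Swing-range labels for -log10(Papp) values
#'
#' Values inside the half-open swing interval
#' `[center - halfwidth, center + halfwidth)` are `EXCLUDED` as too close to
#' the decision threshold to label reliably. Outside the interval, the low
#' -logP side (high permeability) is `PERMEABLE` under the default
#' direction; `label_direction = "inverted"` swaps the two classes, matching
#' the alternative convention that treats -logP >= center as positive.
#'
#' @param neg_log_papp numeric vector, -log10 of apparent permeability (cm/s).
#' @param center swing center in -logP units (default 6, i.e. Papp = 1e-6 cm/s).
#' @param halfwidth swing half-width in -logP units, >= 0.
#' @param label_direction `"default"` (low -logP = PERMEABLE) or `"inverted"`.
#' @return factor with levels PERMEABLE, IMPERMEABLE, EXCLUDED.
#' @export
mp_swing_label <- function(neg_log_papp, center = 6, halfwidth = 0.5,
                           label_direction = c("default", "inverted")) {
  label_direction <- match.arg(label_direction)
  assert_finite(neg_log_papp)
  stopifnot(halfwidth >= 0, is.finite(center))
  excluded <- neg_log_papp >= (center - halfwidth) & neg_log_papp < (center + halfwidth)
  low_side <- neg_log_papp <= (center - halfwidth)
  lab <- ifelse(excluded, "EXCLUDED", ifelse(low_side, "PERMEABLE", "IMPERMEABLE"))
  if (label_direction == "inverted") {
    lab[lab == "PERMEABLE"] <- "tmp"
    lab[lab == "IMPERMEABLE"] <- "PERMEABLE"
    lab[lab == "tmp"] <- "IMPERMEABLE"
  }
  factor(lab, levels = LABEL_LEVELS)
}

#' Caco-2 three-bin absorption classes
#'
#' Papp < 1e-6 cm/s is poorly absorbed, 1e-6 to 1e-5 cm/s moderately, and
#' above 1e-5 cm/s well absorbed (the established Caco-2 thresholds, also
#' applied to MDCK/RRCK as Caco-2 surrogates).
#'
#' @param papp apparent permeability in cm/s, strictly positive.
#' @return factor with levels POOR, MODERATE, WELL.
#' @export
mp_caco2_bin <- function(papp) {
  assert_finite(papp)
  if (any(papp <= 0)) abort("`papp` must be strictly positive (cm/s)")
  factor(ifelse(papp < 1e-6, "POOR", ifelse(papp <= 1e-5, "MODERATE", "WELL")),
         levels = c("POOR", "MODERATE", "WELL"))
}

#' Macrocycle ring-size strata
#'
#' Largest-ring sizes below 12 atoms are non-macrocyclic; 12--15 atoms is
#' the small-ring stratum, 16--18 medium, above 18 large.
#'
#' @param largest_ring_size integer vector of largest ring sizes (0 if acyclic).
#' @return factor with levels NON_MACROCYCLE, SMALL, MEDIUM, LARGE.
#' @export
mp_ring_category <- function(largest_ring_size) {
  stopifnot(all(largest_ring_size >= 0))
  s <- largest_ring_size
  factor(ifelse(s < 12, "NON_MACROCYCLE",
                ifelse(s <= 15, "SMALL", ifelse(s <= 18, "MEDIUM", "LARGE"))),
         levels = c("NON_MACROCYCLE", "SMALL", "MEDIUM", "LARGE"))
}

#' Inter-laboratory pair deviation statistics
#'
#' For replicate measurements of the same compounds from independent
#' laboratories: the fraction of pairs agreeing to within `delta` -logP
#' units (boundary inclusive, to numerical tolerance), and the fraction
#' whose two values fall on opposite sides of the classification
#' threshold (conflicting labels).
#'
#' @param data data frame with columns `value_a` and `value_b` (-logP units),
#'   or NULL when `value_a`/`value_b` vectors are given directly.
#' @param value_a,value_b numeric vectors, used when `data` is NULL.
#' @param threshold classification threshold in -logP units.
#' @param delta agreement width in -logP units.
#' @return tibble with `n_pairs`, `frac_within_delta`, `frac_conflicting`.
#' @export
mp_pair_deviation_stats <- function(data = NULL, value_a = NULL, value_b = NULL,
                                    threshold = 6, delta = 0.5) {
  if (!is.null(data)) {
    stopifnot(all(c("value_a", "value_b") %in% names(data)))
    value_a <- data$value_a
    value_b <- data$value_b
  }
  if (length(value_a) == 0) abort("no pairs given")
  stopifnot(length(value_a) == length(value_b))
  assert_finite(c(value_a, value_b))
  within <- abs(value_a - value_b) <= delta + 1e-9
  conflict <- (value_a - threshold) * (value_b - threshold) < 0
  tibble(n_pairs = length(value_a),
         frac_within_delta = mean(within),
         frac_conflicting = mean(conflict))
}

#' Deduplicate records by InChIKey within assay
#'
#' Keeps the first record per (inchikey, assay) after an order-stable sort
#' by `source_id`; duplicates of a compound across different assays are
#' retained, as each assay is a distinct supervision signal. With
#' `aggregate = "mean"`, replicate -logP values within (inchikey, assay)
#' are averaged instead of dropped.
#'
#' @param data data frame of records with at least `inchikey` and `assay`
#'   columns (`smiles` is canonicalized and keyed first if `inchikey` is
#'   absent).
#' @param aggregate `"first"` (keep first) or `"mean"` (average -logP).
#' @return deduplicated tibble; the curation counts are attached as the
#'   `mp_report` attribute (see [mp_report()]).
#' @export
mp_dedup <- function(data, aggregate = c("first", "mean")) {
  aggregate <- match.arg(aggregate)
  data <- ensure_keys(as_tibble(data))
  n_input <- nrow(data)
  if (n_input == 0) {
    out <- data
  } else if (aggregate == "mean") {
    out <- data |>
      group_by(.data$inchikey, .data$assay) |>
      arrange(if ("source_id" %in% names(data)) .data$source_id else NULL,
              .by_group = TRUE) |>
      mutate(neg_log_papp = mean(.data$neg_log_papp)) |>
      slice(1) |>
      ungroup()
  } else {
    ord <- if ("source_id" %in% names(data)) order(data$inchikey, data$assay, data$source_id)
           else order(data$inchikey, data$assay)
    out <- data[ord, ][!duplicated(data[ord, c("inchikey", "assay")]), ]
  }
  report <- tibble(n_input = n_input, n_deduplicated = nrow(out),
                   n_excluded_swing = NA_integer_, n_positive = NA_integer_,
                   n_negative = NA_integer_, class_balance = NA_real_)
  attr(out, "mp_report") <- report
  out
}

ensure_keys <- function(data) {
  if (!"inchikey" %in% names(data)) {
    if (!"smiles" %in% names(data)) abort("need `inchikey` or `smiles` column")
    if (nrow(data) == 0) return(mutate(data, inchikey = character(0)))
    keys <- mp_canonicalize(data$smiles)
    data$inchikey <- keys$inchikey
  }
  bad <- !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", data$inchikey)
  if (any(bad)) abort(sprintf("malformed inchikey at rows: %s",
                              paste(utils::head(which(bad), 5), collapse = ", ")))
  data
}

#' Curate a permeability dataset
#'
#' The full curation pipeline: (optionally) canonicalize and key records,
#' deduplicate by InChIKey within assay, then apply swing-range labels.
#' `EXCLUDED` records are retained in the output with `y = NA` so callers
#' can audit them; modeling functions drop them.
#'
#' @inheritParams mp_dedup
#' @inheritParams mp_swing_label
#' @return labeled tibble with `label` (factor) and `y` (1 = PERMEABLE,
#'   0 = IMPERMEABLE, NA = EXCLUDED) columns and an `mp_report` attribute
#'   holding the [mp_report()] counts.
#' @export
mp_curate <- function(data, center = 6, halfwidth = 0.5,
                      label_direction = c("default", "inverted"),
                      aggregate = c("first", "mean")) {
  label_direction <- match.arg(label_direction)
  out <- mp_dedup(data, aggregate = aggregate)
  n_input <- attr(out, "mp_report")$n_input
  out$label <- mp_swing_label(out$neg_log_papp, center, halfwidth, label_direction)
  out$swing_center <- center
  out$swing_halfwidth <- halfwidth
  out$y <- ifelse(out$label == "PERMEABLE", 1L,
                  ifelse(out$label == "IMPERMEABLE", 0L, NA_integer_))
  n_pos <- sum(out$label == "PERMEABLE")
  n_neg <- sum(out$label == "IMPERMEABLE")
  n_exc <- sum(out$label == "EXCLUDED")
  attr(out, "mp_report") <- tibble(
    n_input = n_input, n_deduplicated = nrow(out),
    n_excluded_swing = n_exc, n_positive = n_pos, n_negative = n_neg,
    class_balance = if (n_pos + n_neg > 0) n_pos / (n_pos + n_neg) else NA_real_)
  out
}

#' Retrieve the curation report attached to a curated tibble
#'
#' @param data a tibble returned by [mp_dedup()] or [mp_curate()].
#' @return one-row tibble of curation counts.
#' @export
mp_report <- function(data) {
  rep <- attr(data, "mp_report")
  if (is.null(rep)) abort("no curation report attached; run mp_dedup()/mp_curate() first")
  rep
}

# --- dataset I/O -----------------------------------------------------------

REQUIRED_COLS <- c("smiles", "assay", "neg_log_papp")

#' Read a permeability dataset from CSV/TSV
#'
#' Requires columns `smiles`, `assay`, `neg_log_papp`; optional `ph`,
#' `temperature`, `source_id`, `inchikey` and any extra columns are carried
#' through. Schema violations raise an error listing the missing columns;
#' malformed numeric fields raise an error naming the row.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (default guessed from extension).
#' @return tibble of records.
#' @export
mp_read_dataset <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||% if (grepl("\\.tsv$", path)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("schema error: missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  num_cols <- intersect(c("neg_log_papp", "ph", "temperature", "largest_ring_size", "mu"),
                        names(raw))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(raw[[cn]]) & !is.na(raw[[cn]]))
    if (length(bad)) {
      abort(sprintf("malformed value in column `%s` at row %d: \"%s\"",
                    cn, bad[1], raw[[cn]][bad[1]]))
    }
    raw[[cn]] <- v
  }
  if (any(!raw$assay %in% ASSAY_LEVELS)) {
    bad <- which(!raw$assay %in% ASSAY_LEVELS)[1]
    abort(sprintf("unknown assay \"%s\" at row %d (expected %s)",
                  raw$assay[bad], bad, paste(ASSAY_LEVELS, collapse = "/")))
  }
  as_tibble(raw)
}

#' Write a permeability dataset to CSV/TSV with full precision
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip preserves every value bit-exactly.
#'
#' @param data tibble of records.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
mp_write_dataset <- function(data, path, format = NULL) {
  format <- format %||% if (grepl("\\.tsv$", path)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  out <- as.data.frame(data)
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
    if (is.factor(out[[cn]])) out[[cn]] <- as.character(out[[cn]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
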