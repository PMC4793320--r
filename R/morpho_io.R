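#' @title Morphometric trait tables
#' @description A `morpho_table` is a validated data frame of specimen-level
#'   trait measurements in micrometres: one row per specimen, required id
#'   columns `specimen_id` and `nest_id`, optional `species`, `lat`, `lon`,
#'   and one numeric column per trait code from [trait_catalog()]. Blank
#'   cells are missing values (never zero); all present measurements must be
#'   finite and strictly positive.
#' @name morpho_table
NULL

id_cols <- c("specimen_id", "nest_id")
meta_cols <- c("species", "lat", "lon")

#' Which columns of a morpho table are trait columns
#' @param x A `morpho_table` (or any data frame using catalog trait codes).
#' @return Character vector of trait codes present.
#' @export
trait_cols <- function(x) intersect(trait_catalog()$code, names(x))

#' Construct / validate a morpho table
#'
#' Validates the invariants (unique specimen ids, nest id present for every
#' specimen, strictly positive finite measurements, and, when `CS` is
#' present, `CS == (CL + CWb)/2` within tolerance) and stamps the class.
#'
#' @param df Data frame with `specimen_id`, `nest_id` and trait columns.
#' @param check_cs Tolerance for the `CS` identity check (relative).
#' @return The validated data frame, classed `morpho_table`.
#' @export
as_morpho_table <- function(df, check_cs = 1e-6) {
  stopifnot(is.data.frame(df))
  missing_ids <- setdiff(id_cols, names(df))
  if (length(missing_ids))
    stop("missing required column(s): ", paste(missing_ids, collapse = ", "))
  df$specimen_id <- as.character(df$specimen_id)
  df$nest_id <- as.character(df$nest_id)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  bad_nest <- is.na(df$nest_id) | !nzchar(df$nest_id)
  if (any(bad_nest))
    stop("missing nest_id for specimen(s): ",
         paste(df$specimen_id[bad_nest], collapse = ", "))
  traits <- trait_cols(df)
  if (!length(traits))
    stop("no known trait columns found; expected codes such as ",
         paste(utils::head(trait_catalog()$code, 5), collapse = ", "))
  for (tc in traits) {
    v <- df[[tc]]
    if (!is.numeric(v))
      stop("trait column '", tc, "' is not numeric")
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad))
      stop("non-positive or non-finite value in column '", tc,
           "' at row(s) ", paste(bad, collapse = ", "),
           " (specimen ", paste(df$specimen_id[bad], collapse = ", "), ")")
  }
  if (all(c("CS", "CL", "CWb") %in% names(df))) {
    ok <- is.na(df$CS) | abs(df$CS - (df$CL + df$CWb) / 2) <=
      check_cs * pmax(df$CS, 1)
    if (!all(ok, na.rm = TRUE))
      stop("CS != (CL + CWb)/2 for specimen(s): ",
           paste(df$specimen_id[!ok], collapse = ", "))
  }
  class(df) <- unique(c("morpho_table", class(df)))
  df
}

#' Read a morphometric trait table from CSV/TSV
#'
#' Reads a UTF-8 delimited file with a header row. Required columns are
#' `specimen_id` and `nest_id`; columns whose names match catalog trait
#' codes become measurements; any other columns are carried along untouched
#' as metadata. Blank cells become missing values, not zeros.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"` (default guessed from the extension).
#' @return A [morpho_table].
#' @export
read_morpho_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "na."), fileEncoding = "UTF-8")
  for (tc in trait_cols(df)) {
    v <- df[[tc]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric trait value in column '", tc, "' at row(s) ",
             paste(bad, collapse = ", "))
      df[[tc]] <- num
    }
  }
  as_morpho_table(df)
}

#' Write a morpho table to CSV/TSV
#'
#' Values are written at full precision (`format(..., digits = 17)`), so a
#' read back with [read_morpho_table()] round-trips bit-identically.
#'
#' @param x A [morpho_table].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_morpho_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(x)
  for (tc in trait_cols(out))
    out[[tc]] <- vapply(out[[tc]], function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 17), character(1))
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive absolute cephalic size CS
#'
#' Adds (or overwrites) the derived trait `CS = (CL + CWb)/2`.
#'
#' @param x A [morpho_table] with `CL` and `CWb` present for every specimen.
#' @return The table with a `CS` column.
#' @export
derive_cs <- function(x) {
  stopifnot(inherits(x, "morpho_table"))
  if (!all(c("CL", "CWb") %in% names(x)))
    stop("CL and CWb are required to derive CS")
  miss <- is.na(x$CL) | is.na(x$CWb)
  if (any(miss))
    stop("CL or CWb missing for specimen(s): ",
         paste(x$specimen_id[miss], collapse = ", "))
  x$CS <- (x$CL + x$CWb) / 2
  as_morpho_table(as.data.frame(x))
}

#' Table of dimensionless trait ratios
#'
#' Divides each requested numerator trait by a denominator trait (typically
#' `CS`), specimen-wise. Specimens with a missing numerator get a missing
#' ratio.
#'
#' @param x A [morpho_table].
#' @param denominator Trait code used as denominator.
#' @param numerators Character vector of numerator trait codes.
#' @return Data frame with `specimen_id`, `nest_id` and one column per
#'   ratio, named `"<num>/<den>"`.
#' @export
ratio_table <- function(x, denominator = "CS", numerators) {
  stopifnot(inherits(x, "morpho_table"))
  if (missing(numerators) || !length(numerators))
    stop("numerators must be a non-empty list of trait codes")
  for (tc in c(denominator, numerators))
    if (!tc %in% names(x)) stop("trait '", tc, "' not present in table")
  if (anyNA(x[[denominator]]))
    stop("denominator '", denominator, "' missing for some specimens")
  out <- x[, id_cols, drop = FALSE]
  for (tc in numerators)
    out[[paste0(tc, "/", denominator)]] <- x[[tc]] / x[[denominator]]
  as.data.frame(out)
}

#' Error-variance screen via within-class trait correlations
#'
#' Measurement error in one trait shows up as a lack of positive
#' correlation with the other traits once class (species or nest) means are
#' accounted for: real size variation correlates everything, error does
#' not. For every trait pair the Pearson correlation is computed within
#' each class and pooled across classes with weights `n_class - 1`; a trait
#' whose mean pooled correlation against all partners falls below
#' `threshold` is flagged. Flagging is advisory — dropping the column is a
#' separate, explicit step.
#'
#' @param x A [morpho_table].
#' @param class_labels Per-specimen class labels; default is the finest
#'   available grouping (the `species` column if present, else `nest_id`).
#' @param threshold Flagging threshold on the mean pooled correlation
#'   (default 0.2).
#' @param traits Trait columns to screen (default: all fully numeric trait
#'   columns present).
#' @return A `correlation_report`: data frame with per-trait `mean_r`,
#'   `min_r` and `flagged`, plus attributes `threshold` and
#'   `classes_used`.
#' @export
correlation_screen <- function(x, class_labels = NULL, threshold = 0.2,
                               traits = NULL) {
  stopifnot(inherits(x, "morpho_table"))
  if (is.null(class_labels))
    class_labels <- if ("species" %in% names(x) && !anyNA(x$species))
      x$species else x$nest_id
  stopifnot(length(class_labels) == nrow(x))
  if (is.null(traits)) {
    traits <- trait_cols(x)
    traits <- traits[vapply(traits, function(tc) !anyNA(x[[tc]]), logical(1))]
  }
  if (length(traits) < 2) stop("need at least 2 complete traits to screen")
  usable <- names(which(table(class_labels) >= 3))
  if (!length(usable))
    stop("no class with >= 3 specimens; cannot estimate within-class correlations")
  M <- as.matrix(as.data.frame(x)[, traits, drop = FALSE])
  p <- length(traits)
  # pooled r for each unordered trait pair, weighted by class df
  pooled <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    num <- 0; den <- 0
    for (cl in usable) {
      idx <- which(class_labels == cl)
      r <- suppressWarnings(stats::cor(M[idx, i], M[idx, j]))
      if (is.na(r)) next
      w <- length(idx) - 1
      num <- num + w * r
      den <- den + w
    }
    if (den > 0) pooled[i, j] <- pooled[j, i] <- num / den
  }
  mean_r <- rowMeans(pooled, na.rm = TRUE)
  min_r <- apply(pooled, 1, min, na.rm = TRUE)
  rep <- data.frame(trait = traits, mean_r = mean_r, min_r = min_r,
                    flagged = mean_r < threshold, row.names = NULL)
  structure(rep, class = c("correlation_report", "data.frame"),
            threshold = threshold, classes_used = usable, pooled_r = pooled)
}

#' Centre and scale the columns of a numeric table
#'
#' Each column is transformed to mean 0 and sample standard deviation 1,
#' the preprocessing used before multivariate ratio analysis. Constant
#' columns are an error.
#'
#' @param m Numeric matrix or all-numeric data frame with >= 2 rows.
#' @return Matrix of the same shape.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to standardize")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Within-class correlation screen (threshold ",
      attr(x, "threshold"), ", ", length(attr(x, "classes_used")),
      " classes)\n", sep = "")
  print.data.frame(x, digits = 3)
  flagged <- x$trait[x$flagged]
  cat(if (length(flagged)) paste("Flagged:", paste(flagged, collapse = ", "))
      else "No trait flagged", "\n")
  invisible(x)
}
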