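# Mandatory patient-record columns. `smoker` is carried when present but is
# never used by the analysis.
.cohort_columns <- c("id", "age", "sex", "bmi", "gold", "fev1_l", "fev1_pct",
                     "ic_tlc", "dlco_pct", "smwd", "sgrq", "mmrc", "bode",
                     "dead_3y", "il6", "il8", "il16", "tnfa", "mmp9", "vegf",
                     "parc", "mcp1")
.cohort_numeric <- setdiff(.cohort_columns, c("id", "sex"))

#' Read a cohort table
#'
#' Reads a per-patient CSV/TSV with the documented header vocabulary
#' (demographics, lung function, 6MWD, SGRQ, mMRC, BODE, 3-year vital status,
#' and the eight serum biomarkers). Column names are normalized to lower
#' case, `""` and `"NA"` are missing, and numeric columns are parsed
#' strictly: an unparseable cell is an error naming its row and column.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A data.frame with one row per patient.
#' @export
read_cohort <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(.cohort_numeric, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop(sprintf("unparseable numeric value %s in column '%s', row %d",
                   dQuote(raw[bad[1]]), col, bad[1]), call. = FALSE)
    }
    df[[col]] <- num
  }
  # extra (non-mandatory) columns: numeric when fully parseable
  for (col in setdiff(names(df), c(.cohort_numeric, "id", "sex"))) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (!any(!is.na(df[[col]]) & is.na(num))) df[[col]] <- num
  }
  for (col in intersect(c("gold", "mmrc", "dead_3y", "bode", "smoker"),
                        names(df))) {
    if (is.numeric(df[[col]])) df[[col]] <- as.integer(round(df[[col]]))
  }
  message(sprintf("read %d patient records from %s", nrow(df), path))
  df
}

#' Write a cohort table
#'
#' Numeric cells are written at 6 significant digits; [read_cohort] of the
#' result reproduces the table up to that formatting.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  out <- cohort
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.6g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

# GOLD stage implied by FEV1 % predicted.
.gold_from_fev1pct <- function(fev1_pct) {
  ifelse(fev1_pct >= 80, 1L,
         ifelse(fev1_pct >= 50, 2L, ifelse(fev1_pct >= 30, 3L, 4L)))
}

#' Validate a cohort table
#'
#' Produces a per-column missingness summary and a list of invariant
#' violations (IC/TLC outside (0, 1), SGRQ outside \[0, 100\], BODE outside
#' \[0, 10\], vital status not 0/1, GOLD stage inconsistent with FEV1 %
#' predicted). Violations are informative, not fatal; validation fails only
#' when the table is empty or a mandatory analysis variable is more than half
#' missing.
#'
#' @param cohort Cohort data.frame.
#' @param stop_on_fatal Raise an error on a fatal condition (default) rather
#'   than only recording it.
#' @return An object of class `cohort_validation`: `n`, `missing_counts`,
#'   `violations` (data.frame of column/row/message), `fatal`,
#'   `fatal_reasons`.
#' @export
validate_cohort <- function(cohort, stop_on_fatal = TRUE) {
  fatal_reasons <- character()
  if (nrow(cohort) == 0) fatal_reasons <- "cohort table is empty"
  present <- intersect(.cohort_columns, names(cohort))
  miss <- vapply(cohort[present], function(x) sum(is.na(x)), integer(1))
  if (nrow(cohort) > 0) {
    frac <- miss / nrow(cohort)
    over <- names(frac)[frac > 0.5]
    if (length(over)) {
      fatal_reasons <- c(fatal_reasons,
                         paste0("mandatory variable(s) >50% missing: ",
                                paste(over, collapse = ", ")))
    }
  }
  viol <- list()
  flag <- function(col, rows, msg) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.frame(column = col, row = rows,
                                               message = msg,
                                               stringsAsFactors = FALSE)
    }
  }
  if (nrow(cohort) > 0) {
    with_col <- function(col) col %in% names(cohort)
    if (with_col("ic_tlc")) {
      flag("ic_tlc", which(!is.na(cohort$ic_tlc) &
                             (cohort$ic_tlc <= 0 | cohort$ic_tlc >= 1)),
           "ic_tlc outside (0, 1)")
    }
    if (with_col("sgrq")) {
      flag("sgrq", which(!is.na(cohort$sgrq) &
                           (cohort$sgrq < 0 | cohort$sgrq > 100)),
           "sgrq outside [0, 100]")
    }
    if (with_col("bode")) {
      flag("bode", which(!is.na(cohort$bode) &
                           (cohort$bode < 0 | cohort$bode > 10)),
           "bode outside [0, 10]")
    }
    if (with_col("dead_3y")) {
      flag("dead_3y", which(!is.na(cohort$dead_3y) &
                              !(cohort$dead_3y %in% c(0, 1))),
           "dead_3y not 0/1")
    }
    if (with_col("gold") && with_col("fev1_pct")) {
      both <- !is.na(cohort$gold) & !is.na(cohort$fev1_pct)
      flag("gold", which(both &
                           .gold_from_fev1pct(cohort$fev1_pct) != cohort$gold),
           "gold inconsistent with fev1_pct cut-points")
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(column = character(), row = integer(), message = character(),
               stringsAsFactors = FALSE)
  rep <- structure(list(n = nrow(cohort), missing_counts = miss,
                        violations = violations,
                        fatal = length(fatal_reasons) > 0,
                        fatal_reasons = fatal_reasons),
                   class = "cohort_validation")
  if (rep$fatal && stop_on_fatal) {
    stop("cohort validation failed: ", paste(fatal_reasons, collapse = "; "),
         call. = FALSE)
  }
  rep
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("<cohort_validation> %d records, %d violation(s)%s\n", x$n,
              nrow(x$violations), if (x$fatal) " [FATAL]" else ""))
  if (x$fatal) cat("  fatal: ", paste(x$fatal_reasons, collapse = "; "), "\n")
  tot <- sum(x$missing_counts)
  if (tot > 0) {
    mc <- x$missing_counts[x$missing_counts > 0]
    cat("  missing:", paste(sprintf("%s=%d", names(mc), mc), collapse = " "),
        "\n")
  }
  if (nrow(x$violations) > 0) {
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}

#' BODE index from its four components
#'
#' Composite 0-10 prognostic score summing points for airflow Obstruction
#' (FEV1 % predicted), Exercise capacity (6-minute walk distance), Dyspnea
#' (mMRC grade) and Body-mass index:
#' FEV1% >= 65 scores 0, 50-64 scores 1, 36-49 scores 2, <= 35 scores 3;
#' 6MWD >= 350 m scores 0, 250-349 scores 1, 150-249 scores 2, <= 149 scores
#' 3; mMRC 0-1 scores 0, then grade minus one; BMI > 21 scores 0, else 1.
#' Any missing component gives a missing score (never zero).
#'
#' @param fev1_pct FEV1 percent predicted.
#' @param smwd Six-minute walk distance, meters.
#' @param mmrc mMRC dyspnea grade 0-4.
#' @param bmi Body-mass index, kg/m^2.
#' @return Integer score in 0-10 (NA where any component is NA); vectorized.
#' @examples
#' compute_bode(91, 530, 0, 26)   # mild-disease profile: 0
#' compute_bode(23, 314, 4, 20)   # severe profile: 8
#' @export
compute_bode <- function(fev1_pct, smwd, mmrc, bmi) {
  if (any(!is.na(mmrc) & !(mmrc %in% 0:4))) {
    stop("mmrc grades must be integers 0-4", call. = FALSE)
  }
  p_fev <- ifelse(fev1_pct >= 65, 0L,
                  ifelse(fev1_pct >= 50, 1L, ifelse(fev1_pct >= 36, 2L, 3L)))
  p_walk <- ifelse(smwd >= 350, 0L,
                   ifelse(smwd >= 250, 1L, ifelse(smwd >= 150, 2L, 3L)))
  p_mmrc <- ifelse(mmrc <= 1, 0L, as.integer(mmrc) - 1L)
  p_bmi <- ifelse(bmi > 21, 0L, 1L)
  as.integer(p_fev + p_walk + p_mmrc + p_bmi)
}
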