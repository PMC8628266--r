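# Biodistribution ingestion and summarization: per-animal %ID/g records to
# per-group organ time-activity curves (mean +/- SD, n).

BIODIST_COLUMNS <- c("animal_id", "group", "organ", "time_h",
                     "percent_id_per_g", "body_weight_g")

#' Default organ whitelist
#'
#' Organs and tissues sampled in a standard antibody biodistribution study:
#' blood, lung, liver, spleen, pancreas, intestine, kidney, muscle, bone and
#' the tumor. Used to validate organ labels at ingestion; pass a different
#' vector to permit other tissue panels.
#'
#' @return Character vector of organ labels.
#' @export
default_organs <- function() {
  c("blood", "lung", "liver", "spleen", "pancreas", "intestine",
    "kidney", "muscle", "bone", "tumor")
}

#' Validate a table of biodistribution records
#'
#' Checks the presence and validity of the columns `animal_id`, `group`,
#' `organ`, `time_h`, `percent_id_per_g`, `body_weight_g`. %ID/g and time
#' must be non-negative, body weight strictly positive, organ labels must
#' belong to the whitelist. Row order is preserved.
#'
#' @param df data.frame of raw records.
#' @param organs organ whitelist, or `NULL` to accept any label.
#' @return The validated data.frame with class `biodist_records`.
#' @export
biodistribution_records <- function(df, organs = default_organs()) {
  missing_cols <- setdiff(BIODIST_COLUMNS, names(df))
  if (length(missing_cols))
    stop_parse("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, c(BIODIST_COLUMNS,
                              setdiff(names(df), BIODIST_COLUMNS))]
  for (col in c("time_h", "percent_id_per_g", "body_weight_g")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop_parse("non-numeric value in column '", col, "' at row ",
                 bad %||% 1)
    }
    if (anyNA(v))
      stop_parse("missing value in column '", col, "' at row ",
                 which(is.na(v))[1])
  }
  bad_row <- function(cond) if (any(cond)) which(cond)[1] else 0L
  if ((r <- bad_row(df$percent_id_per_g < 0)) > 0)
    stop_parse("negative percent_id_per_g at row ", r)
  if ((r <- bad_row(df$time_h < 0)) > 0)
    stop_parse("negative time_h at row ", r)
  if ((r <- bad_row(df$body_weight_g <= 0)) > 0)
    stop_parse("non-positive body_weight_g at row ", r)
  if (!is.null(organs)) {
    unknown <- setdiff(unique(df$organ), organs)
    if (length(unknown))
      stop_parse("organ label(s) not in whitelist: ",
                 paste(unknown, collapse = ", "))
  }
  class(df) <- c("biodist_records", "data.frame")
  df
}

#' Read biodistribution measurements from a delimited text file
#'
#' Expects a UTF-8 table (comma-separated by default; tab accepted and
#' auto-detected from the header line) with header columns `animal_id`,
#' `group`, `organ`, `time_h`, `percent_id_per_g`, `body_weight_g`. Parse
#' and validation errors name the offending row and column.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects "," vs tab.
#' @param organs organ whitelist (see [default_organs()]); `NULL` disables.
#' @return A `biodist_records` data.frame, row order as in the file.
#' @export
read_biodistribution <- function(path, sep = NULL, organs = default_organs()) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  biodistribution_records(df, organs = organs)
}

#' Normalize %ID/g to a reference body weight
#'
#' Scales each measurement as %ID/g * (body weight / reference), expressing
#' all animals as if they weighed the reference mass (20 g by default, the
#' conventional normalization for nude-mouse biodistribution data). Linear
#' in %ID/g and the identity when the animal already weighs the reference.
#'
#' @param records `biodist_records` table (or a single-row data.frame).
#' @param reference_bw_g reference body weight in grams (> 0).
#' @return Records with `percent_id_per_g` rescaled; other fields unchanged.
#' @export
normalize_to_reference_bw <- function(records, reference_bw_g = 20) {
  check_number(reference_bw_g, "reference_bw_g", lower = 0, strict = TRUE)
  records$percent_id_per_g <-
    records$percent_id_per_g * (records$body_weight_g / reference_bw_g)
  records
}

#' Summarize records into per-group organ time-activity curves
#'
#' Produces, for each (group, organ), the per-time mean, sample SD
#' (denominator n - 1; defined as 0 when n = 1) and animal count of %ID/g.
#' Body-weight normalization is applied per record before averaging unless
#' disabled.
#'
#' @param records `biodist_records` table.
#' @param normalize apply [normalize_to_reference_bw()] first (default TRUE).
#' @param reference_bw_g reference weight passed through when normalizing.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Long-format data.frame of class `tac_table` with columns
#'   `group`, `organ`, `time_h`, `mean_pidg`, `sd_pidg`, `n`, ordered by
#'   group, organ, time. Empty input yields an empty table.
#' @export
summarize_curves <- function(records, normalize = TRUE, reference_bw_g = 20,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(records) == 0L) {
    out <- data.frame(group = character(), organ = character(),
                      time_h = numeric(), mean_pidg = numeric(),
                      sd_pidg = numeric(), n = integer())
    class(out) <- c("tac_table", "data.frame")
    return(out)
  }
  if (normalize)
    records <- normalize_to_reference_bw(records, reference_bw_g)
  key <- interaction(records$group, records$organ, records$time_h,
                     drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(records, key), function(d) {
    n <- nrow(d)
    v <- d$percent_id_per_g
    s <- if (n == 1L) 0 else if (sd_type == "sample") stats::sd(v) else
      sqrt(sum((v - mean(v))^2) / n)
    data.frame(group = d$group[1], organ = d$organ[1], time_h = d$time_h[1],
               mean_pidg = mean(v), sd_pidg = s, n = n)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$group, out$organ, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tac_table", "data.frame")
  out
}

#' Extract one time-activity curve from a summary table
#'
#' @param curves a `tac_table` from [summarize_curves()].
#' @param group,organ labels selecting the curve.
#' @return Single-curve data.frame (class `tac`) with strictly increasing
#'   `time_h`.
#' @export
get_curve <- function(curves, group, organ) {
  sel <- curves[curves$group == group & curves$organ == organ, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop_domain("no curve for group '", group, "', organ '", organ, "'")
  sel <- sel[order(sel$time_h), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("tac", "data.frame")
  sel
}

#' Fold change between two curves at a time point
#'
#' Ratio of group means at one sampling time, e.g. SQAP over saline tumor
#' uptake at 1 h. Times are matched exactly -- no interpolation.
#'
#' @param curve_a numerator curve (a `tac` or data.frame with `time_h`,
#'   `mean_pidg`).
#' @param curve_b denominator curve.
#' @param time_h sampling time that must be present in both curves.
#' @return Single ratio `mean_a(time) / mean_b(time)`.
#' @examples
#' a <- data.frame(time_h = 1, mean_pidg = 4.4)
#' b <- data.frame(time_h = 1, mean_pidg = 3.2)
#' fold_change(a, b, 1)  # 1.375
#' @export
fold_change <- function(curve_a, curve_b, time_h) {
  ia <- match(time_h, curve_a$time_h)
  ib <- match(time_h, curve_b$time_h)
  if (is.na(ia) || is.na(ib))
    stop_domain("time ", time_h, " h absent from ",
                if (is.na(ia)) "numerator" else "denominator", " curve")
  den <- curve_b$mean_pidg[ib]
  if (den <= 0) stop_domain("denominator mean must be > 0 (got ", den, ")")
  curve_a$mean_pidg[ia] / den
}

#' Write / read a curve summary table
#'
#' Long-format UTF-8 CSV with columns group, organ, time_h, mean_pidg,
#' sd_pidg, n.
#'
#' @param curves `tac_table` to serialize.
#' @param path output file.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("tac_table", "data.frame")
  out
}
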