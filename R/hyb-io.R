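# hyb-format file I/O: tab-delimited, one hybrid per line, 15 fixed
# columns plus an optional key=value;... flags column.

#' The hyb file dialect
#'
#' Column layout of a hyb-format line: id, seq, energy, then six fields per
#' segment (ref_name, read_start, read_end, ref_start, ref_end, score) for
#' the two segments, then an optional flags column — 15 or 16 tab-separated
#' fields. The token `"."` marks a missing value in energy, ref_start,
#' ref_end, and score; id, seq, ref_name, read_start, and read_end may
#' never be missing.
#'
#' @param n_fixed_columns Number of fixed columns (15).
#' @param flags_column_optional Whether the 16th column may be absent.
#' @param missing_value_token Token marking a missing numeric value.
#' @return An object of class `hyb_dialect`.
#' @export
hyb_dialect <- function(n_fixed_columns = 15L, flags_column_optional = TRUE,
                        missing_value_token = ".") {
  structure(list(n_fixed_columns = as.integer(n_fixed_columns),
                 flags_column_optional = flags_column_optional,
                 missing_value_token = missing_value_token),
            class = "hyb_dialect")
}

# parse one numeric field that may be the missing token; returns list(value, token)
.parse_opt_num <- function(tok, dialect, what, line = NULL) {
  if (tok == dialect$missing_value_token)
    return(list(value = NA_real_, token = NULL))
  if (!.is_num_token(tok))
    .stop_hyb("numeric-parse", sprintf("%s field '%s' is not numeric", what, tok), line)
  list(value = as.numeric(tok), token = tok)
}

.parse_coord <- function(tok, what, line = NULL) {
  if (!.is_int_token(tok))
    .stop_hyb("numeric-parse",
              sprintf("%s field '%s' is not a positive integer", what, tok), line)
  as.integer(tok)
}

#' Parse one hyb-format line into a record
#'
#' @param line A non-empty, non-comment record line.
#' @param dialect A [hyb_dialect()].
#' @param line_number Optional line number carried into error messages.
#' @return A [hyb_record()]. Original textual tokens of the energy and
#'   score fields are retained internally so unmodified records round-trip
#'   byte-exactly through [write_hyb_line()].
#' @export
#' @examples
#' ln <- paste("r1", "AAACCCGGGTTT", "-12.3",
#'             "MIMAT0_mir1_hsa-miR-1_microRNA", 1, 6, 1, 6, "0.001",
#'             "ENSG0_ENST0_GENEA_mRNA", 7, 12, 100, 105, "0.002",
#'             "count_total=5", sep = "\t")
#' parse_hyb_line(ln)
parse_hyb_line <- function(line, dialect = hyb_dialect(), line_number = NULL) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  nf <- dialect$n_fixed_columns
  if (!(length(f) == nf || (dialect$flags_column_optional && length(f) == nf + 1L)))
    .stop_hyb("field-count",
              sprintf("expected %d or %d tab-separated fields, found %d",
                      nf, nf + 1L, length(f)), line_number)
  if (!nzchar(f[1]))
    .stop_hyb("record-id", "empty id field", line_number)
  if (!nzchar(f[2]))
    .stop_hyb("record-seq", "empty seq field", line_number)
  parse_seg <- function(i, label) {
    rs <- .parse_coord(f[i + 1L], paste0(label, " read_start"), line_number)
    re <- .parse_coord(f[i + 2L], paste0(label, " read_end"), line_number)
    refs <- .parse_opt_num(f[i + 3L], dialect, paste0(label, " ref_start"), line_number)
    refe <- .parse_opt_num(f[i + 4L], dialect, paste0(label, " ref_end"), line_number)
    sc <- .parse_opt_num(f[i + 5L], dialect, paste0(label, " score"), line_number)
    seg <- tryCatch(
      seg_info(f[i], rs, re, refs$value, refe$value, sc$value),
      hyb_error = function(e) .stop_hyb(e$code, conditionMessage(e), line_number))
    seg$score_token <- sc$token
    seg
  }
  en <- .parse_opt_num(f[3], dialect, "energy", line_number)
  seg1 <- parse_seg(4L, "seg1")
  seg2 <- parse_seg(10L, "seg2")
  flags <- if (length(f) == nf + 1L) {
    tryCatch(parse_flag_string(f[nf + 1L]),
             hyb_error = function(e) .stop_hyb(e$code, conditionMessage(e), line_number))
  } else NULL
  rec <- tryCatch(
    hyb_record(f[1], f[2], seg1, seg2, energy = en$value, flags = flags),
    hyb_error = function(e) .stop_hyb(e$code, conditionMessage(e), line_number))
  rec$energy_token <- en$token
  rec
}

.fmt_opt <- function(value, token, dialect) {
  if (is.null(value) || is.na(value)) return(dialect$missing_value_token)
  if (!is.null(token) && as.numeric(token) == value) return(token)
  .format_num(value)
}

#' Serialize a hybrid record to one hyb-format line
#'
#' Inverse of [parse_hyb_line()]: absent numeric values are written as the
#' missing token, integer coordinates without a decimal point, and the
#' flags column is omitted entirely when the flag table is empty. Energy
#' and score fields keep their original file tokens when the parsed value
#' was not modified, so clean records round-trip byte-identically.
#'
#' @param record A [hyb_record()].
#' @param dialect A [hyb_dialect()].
#' @return A single tab-separated line (no trailing newline).
#' @export
write_hyb_line <- function(record, dialect = hyb_dialect()) {
  stopifnot(inherits(record, "hyb_record"))
  seg_fields <- function(s) {
    c(s$ref_name,
      as.character(s$read_start), as.character(s$read_end),
      .fmt_opt(s$ref_start, NULL, dialect),
      .fmt_opt(s$ref_end, NULL, dialect),
      .fmt_opt(s$score, s$score_token, dialect))
  }
  fields <- c(record$id, record$seq,
              .fmt_opt(record$energy, record$energy_token, dialect),
              seg_fields(record$seg1), seg_fields(record$seg2))
  if (length(record$flags) > 0L) fields <- c(fields, flag_string(record))
  if (any(grepl("[\t\n]", fields)))
    .stop_hyb("serialize", sprintf("record '%s': field contains tab or newline", record$id))
  paste(fields, collapse = "\t")
}

#' Read a hyb-format file
#'
#' Lines beginning with `#` are comments; blank lines are ignored.
#' Gzip-compressed inputs are detected automatically. Under
#' `on_error = "warn_skip"`, malformed lines are skipped and counted (the
#' count is attached as attribute `"n_skipped"` and reported in a
#' warning); under `"raise"` the first malformed line aborts with its line
#' number.
#'
#' @param path File path or text connection.
#' @param dialect A [hyb_dialect()].
#' @param on_error `"raise"` or `"warn_skip"`.
#' @return A list of [hyb_record()] objects of class `hyb_record_list`,
#'   with attribute `n_skipped`.
#' @export
read_hyb <- function(path, dialect = hyb_dialect(),
                     on_error = c("raise", "warn_skip")) {
  on_error <- match.arg(on_error)
  lines <- .read_lines_auto(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  records <- vector("list", length(idx))
  n_ok <- 0L; n_skipped <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    rec <- tryCatch(parse_hyb_line(lines[i], dialect, line_number = i),
                    hyb_error = function(e) e)
    if (inherits(rec, "hyb_error")) {
      if (on_error == "raise") stop(rec)
      n_skipped <- n_skipped + 1L
    } else {
      n_ok <- n_ok + 1L
      records[[n_ok]] <- rec
    }
  }
  records <- records[seq_len(n_ok)]
  if (n_skipped > 0L)
    warning(sprintf("read_hyb: skipped %d malformed line(s)", n_skipped))
  structure(records, class = "hyb_record_list", n_skipped = n_skipped)
}

#' Write hybrid records to a hyb-format file
#'
#' Records are written one per line, UTF-8, Unix newlines, with a single
#' trailing newline. Comments are never written.
#'
#' @param records A list of [hyb_record()] objects.
#' @param path Output file path or connection.
#' @param dialect A [hyb_dialect()].
#' @return Invisibly, the number of records written.
#' @export
write_hyb <- function(records, path, dialect = hyb_dialect()) {
  lines <- vapply(records, write_hyb_line, character(1), dialect = dialect)
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(length(lines))
}

#' @export
print.hyb_record_list <- function(x, ...) {
  cat(sprintf("<hyb_record_list> %d records", length(x)))
  ns <- attr(x, "n_skipped")
  if (!is.null(ns) && ns > 0L) cat(sprintf(" (%d malformed lines skipped)", ns))
  cat("\n")
  invisible(x)
}

#' Validate a hyb file and report findings
#'
#' Line-level quality control for hyb files. Error-level findings mark
#' lines that do not parse into a valid record (wrong field count,
#' non-numeric coordinates, reversed spans, spans past the sequence end,
#' empty id/seq). Warning-level findings mark suspicious but legal
#' content: seg1 starting after seg2 (`seg-order`), overlapping segment
#' read spans (`span-overlap`), and duplicate read ids (`duplicate-id`).
#'
#' @param path Input hyb file.
#' @param dialect A [hyb_dialect()].
#' @return An object of class `check_report`: a data frame of findings
#'   (`line`, `severity`, `code`, `message`) with attributes `file`,
#'   `n_records`, and `summary` (counts by code). Zero error rows means
#'   the file is parseable.
#' @export
check_hyb <- function(path, dialect = hyb_dialect()) {
  lines <- .read_lines_auto(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  findings <- list()
  add <- function(line, severity, code, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(line = line, severity = severity, code = code,
                 message = message, stringsAsFactors = FALSE)
  }
  seen_ids <- new.env(parent = emptyenv())
  n_records <- 0L
  for (i in idx) {
    rec <- tryCatch(parse_hyb_line(lines[i], dialect, line_number = i),
                    hyb_error = function(e) e)
    if (inherits(rec, "hyb_error")) {
      add(i, "error", rec$code, conditionMessage(rec))
      next
    }
    n_records <- n_records + 1L
    if (rec$seg1$read_start > rec$seg2$read_start)
      add(i, "warning", "seg-order",
          sprintf("record '%s': seg1 read_start %d > seg2 read_start %d",
                  rec$id, rec$seg1$read_start, rec$seg2$read_start))
    else if (rec$seg1$read_end >= rec$seg2$read_start)
      add(i, "warning", "span-overlap",
          sprintf("record '%s': segment read spans overlap (%d-%d vs %d-%d)",
                  rec$id, rec$seg1$read_start, rec$seg1$read_end,
                  rec$seg2$read_start, rec$seg2$read_end))
    if (exists(rec$id, envir = seen_ids))
      add(i, "warning", "duplicate-id",
          sprintf("read id '%s' already seen on line %d",
                  rec$id, get(rec$id, envir = seen_ids)))
    else assign(rec$id, i, envir = seen_ids)
  }
  df <- if (length(findings)) do.call(rbind, findings) else
    data.frame(line = integer(0), severity = character(0),
               code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  file_name <- if (is.character(path)) path else "<connection>"
  structure(df, class = c("check_report", "data.frame"),
            file = file_name, n_records = n_records,
            summary = table(df$code))
}

#' @export
print.check_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat(sprintf("<check_report> %s: %d record(s), %d error(s), %d warning(s)\n",
              attr(x, "file"), attr(x, "n_records"), n_err, n_warn))
  if (nrow(x) > 0L) {
    for (i in seq_len(nrow(x)))
      cat(sprintf("  line %d [%s/%s] %s\n",
                  x$line[i], x$severity[i], x$code[i], x$message[i]))
  }
  invisible(x)
}

#' Write a check report as machine-readable TSV findings
#'
#' @param report A [check_hyb()] report.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_check_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
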