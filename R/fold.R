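# Vienna dot-bracket fold records: 3-line records (header, sequence,
# dot-bracket + optional "(energy)"), plus concurrent hyb+fold merging.

#' Construct a fold (Vienna dot-bracket) record
#'
#' Holds the predicted intramolecular secondary structure of one hybrid:
#' sequence, dot-bracket string over `(`, `)`, `.`, and optional Gibbs
#' free energy in kcal/mol. The dot-bracket must be the same length as the
#' sequence and balanced (the running count of `(` minus `)` never goes
#' negative and ends at zero).
#'
#' @param id Record identifier (Vienna header without the leading `>`).
#' @param seq Nucleotide sequence.
#' @param fold Dot-bracket string.
#' @param energy Optional free energy (kcal/mol), `NA` if absent.
#' @return An object of class `fold_record`.
#' @export
#' @examples
#' fold_record("r1", "ACGU", "(..)", -1.0)
fold_record <- function(id, seq, fold, energy = NA_real_) {
  if (!is.character(id) || !nzchar(id))
    .stop_hyb("fold-id", "fold record id must be non-empty")
  if (nchar(fold) != nchar(seq))
    .stop_hyb("fold-length",
              sprintf("record '%s': fold length %d != seq length %d",
                      id, nchar(fold), nchar(seq)))
  if (grepl("[^().]", fold))
    .stop_hyb("fold-alphabet",
              sprintf("record '%s': fold contains characters outside ( ) .", id))
  depth <- cumsum((strsplit(fold, "")[[1]] == "(") -
                  (strsplit(fold, "")[[1]] == ")"))
  if (length(depth) && (any(depth < 0L) || depth[length(depth)] != 0L))
    .stop_hyb("fold-unbalanced",
              sprintf("record '%s': unbalanced dot-bracket string", id))
  structure(list(id = id, seq = seq, fold = fold,
                 energy = as.numeric(energy), energy_token = NULL),
            class = "fold_record")
}

#' @export
print.fold_record <- function(x, ...) {
  en <- if (is.na(x$energy)) "" else sprintf(" (%.1f)", x$energy)
  cat(sprintf("<fold_record> %s  (%d nt%s)\n", x$id, nchar(x$seq), en))
  invisible(x)
}

#' Parse one 3-line Vienna record
#'
#' Line 1 must begin with `>` (the id is the header text up to the first
#' whitespace); line 2 is the sequence; line 3 is the dot-bracket,
#' optionally followed by whitespace and a parenthesized energy such as
#' `(-12.30)`.
#'
#' @param three_lines Character vector of the three record lines.
#' @param record_index Optional record index carried into error messages.
#' @return A [fold_record()].
#' @export
#' @examples
#' parse_vienna_record(c(">r1", "AAACCCGGGTTT", "..((....))..\t(-8.5)"))
parse_vienna_record <- function(three_lines, record_index = NULL) {
  at <- function() if (is.null(record_index)) "" else
    sprintf(" (vienna record %d)", record_index)
  if (length(three_lines) != 3L)
    .stop_hyb("vienna-truncated",
              sprintf("expected 3 lines, got %d%s", length(three_lines), at()))
  if (!startsWith(three_lines[1], ">"))
    .stop_hyb("vienna-header", sprintf("header does not begin with '>'%s", at()))
  id <- sub("\\s.*$", "", sub("^>", "", three_lines[1]))
  seq <- three_lines[2]
  m <- regmatches(three_lines[3],
                  regexec("^([().]*)(?:\\s+\\(\\s*([+-]?[0-9]+(?:\\.[0-9]+)?)\\s*\\))?\\s*$",
                          three_lines[3]))[[1]]
  if (length(m) == 0L)
    .stop_hyb("vienna-fold", sprintf("unparseable dot-bracket line%s", at()))
  fold <- m[2]
  energy <- if (nzchar(m[3])) as.numeric(m[3]) else NA_real_
  rec <- tryCatch(fold_record(id, seq, fold, energy),
                  hyb_error = function(e) .stop_hyb(e$code,
                    paste0(conditionMessage(e), at())))
  if (nzchar(m[3])) rec$energy_token <- m[3]
  rec
}

#' Serialize a fold record to its three Vienna lines
#'
#' The energy, when present, is appended after a single tab as `(%.1f)`;
#' the original file token is kept when the value was not modified.
#'
#' @param record A [fold_record()].
#' @return Character vector of three lines.
#' @export
write_vienna_record <- function(record) {
  stopifnot(inherits(record, "fold_record"))
  line3 <- record$fold
  if (!is.na(record$energy)) {
    tok <- if (!is.null(record$energy_token) &&
               as.numeric(record$energy_token) == record$energy)
      record$energy_token else sprintf("%.1f", record$energy)
    line3 <- sprintf("%s\t(%s)", line3, tok)
  }
  c(paste0(">", record$id), record$seq, line3)
}

#' Read a Vienna dot-bracket file
#'
#' The file must consist of consecutive 3-line records; multi-structure
#' records (more than one dot-bracket line per header) are rejected.
#' Blank lines between records are tolerated; gzip input is auto-detected.
#'
#' @param path Input path or connection.
#' @param on_error `"raise"` or `"warn_skip"` (skip unparseable records,
#'   counted in attribute `n_skipped`).
#' @return List of [fold_record()] of class `fold_record_list` with
#'   attribute `n_skipped`.
#' @export
read_vienna <- function(path, on_error = c("raise", "warn_skip")) {
  on_error <- match.arg(on_error)
  lines <- .read_lines_auto(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(lines) && length(starts) == 0L)
    .stop_hyb("vienna-header", "no '>' headers found")
  records <- vector("list", length(starts))
  n_ok <- 0L; n_skipped <- 0L
  for (k in seq_along(starts)) {
    lo <- starts[k]
    hi <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    chunk <- lines[lo:hi]
    rec <- tryCatch({
      if (length(chunk) != 3L)
        .stop_hyb("vienna-structure",
                  sprintf("vienna record %d has %d line(s); only 3-line records are supported",
                          k, length(chunk)))
      parse_vienna_record(chunk, record_index = k)
    }, hyb_error = function(e) e)
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
    warning(sprintf("read_vienna: skipped %d malformed record(s)", n_skipped))
  structure(records, class = "fold_record_list", n_skipped = n_skipped)
}

#' Write fold records to a Vienna file
#'
#' @param records List of [fold_record()] objects.
#' @param path Output path or connection.
#' @return Invisibly, the number of records written.
#' @export
write_vienna <- function(records, path) {
  lines <- unlist(lapply(records, write_vienna_record), use.names = FALSE)
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(length(records))
}

#' @export
print.fold_record_list <- function(x, ...) {
  cat(sprintf("<fold_record_list> %d records\n", length(x)))
  invisible(x)
}

#' Policy for merging hyb and fold records
#'
#' @param match_mode `"static"` (sequences must be equal length, compared
#'   at offset 0) or `"dynamic"` (the fold sequence may be a contiguous
#'   substring of the hyb sequence; the smallest admissible offset wins).
#' @param max_mismatch Maximum tolerated mismatching positions (T and U
#'   are treated as equal).
#' @param on_error `"raise"` or `"warn_skip"` for [merge_hyb_fold()].
#' @param id_must_match Require equal record ids in addition to sequence
#'   agreement.
#' @return An object of class `merge_policy`.
#' @export
merge_policy <- function(match_mode = c("static", "dynamic"),
                         max_mismatch = 0L,
                         on_error = c("raise", "warn_skip"),
                         id_must_match = TRUE) {
  structure(list(match_mode = match.arg(match_mode),
                 max_mismatch = as.integer(max_mismatch),
                 on_error = match.arg(on_error),
                 id_must_match = id_must_match),
            class = "merge_policy")
}

# Hamming distance with T/U equivalence (hyb files are DNA-alphabet,
# folders emit RNA)
.tu_mismatches <- function(a, b) {
  a <- chartr("U", "T", a); b <- chartr("U", "T", b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Match a fold record against a hyb record's sequence
#'
#' Static mode requires equal-length sequences and counts mismatches at
#' offset 0. Dynamic mode slides the fold sequence along the hyb sequence
#' and returns the smallest offset with at most `max_mismatch`
#' mismatches. A fold sequence longer than the hyb sequence is a match
#' failure, not a reverse search.
#'
#' @param hyb A [hyb_record()].
#' @param fold A [fold_record()].
#' @param policy A [merge_policy()].
#' @return A list with `ok` (logical), `offset` (0-based, `NA` on
#'   failure), `mismatch_count`, and `reason` (`NA` on success).
#' @export
#' @examples
#' h <- hyb_record("r1", "AAACGT", seg_info("a_b_c_miRNA", 1, 3),
#'                 seg_info("d_e_f_mRNA", 4, 6))
#' f <- fold_record("r1", "ACGU", "(..)")
#' match_fold(h, f, merge_policy("dynamic"))
match_fold <- function(hyb, fold, policy = merge_policy()) {
  fail <- function(reason)
    list(ok = FALSE, offset = NA_integer_, mismatch_count = NA_integer_,
         reason = reason)
  if (policy$id_must_match && hyb$id != fold$id)
    return(fail(sprintf("id mismatch: hyb '%s' vs fold '%s'", hyb$id, fold$id)))
  nh <- nchar(hyb$seq); nf <- nchar(fold$seq)
  if (policy$match_mode == "static") {
    if (nh != nf)
      return(fail(sprintf("length mismatch under static mode: %d vs %d", nh, nf)))
    mm <- .tu_mismatches(hyb$seq, fold$seq)
    if (mm > policy$max_mismatch)
      return(fail(sprintf("%d sequence mismatch(es) exceed max_mismatch=%d",
                          mm, policy$max_mismatch)))
    return(list(ok = TRUE, offset = 0L, mismatch_count = mm, reason = NA_character_))
  }
  if (nf > nh)
    return(fail(sprintf("fold sequence (%d nt) longer than hyb sequence (%d nt)", nf, nh)))
  for (off in 0:(nh - nf)) {
    mm <- .tu_mismatches(substr(hyb$seq, off + 1L, off + nf), fold$seq)
    if (mm <= policy$max_mismatch)
      return(list(ok = TRUE, offset = off, mismatch_count = mm,
                  reason = NA_character_))
  }
  fail(sprintf("no offset aligns fold within hyb at max_mismatch=%d",
               policy$max_mismatch))
}

#' Merge fold records into hyb records by position
#'
#' Record correspondence is positional: the k-th hyb record is paired with
#' the k-th fold record (the order-matched output of upstream pipelines),
#' with id equality as an additional check by default. Each merged record
#' carries its fold and the match offset. Under `on_error = "warn_skip"`
#' mismatched pairs are skipped and counted; under `"raise"` the first
#' failure aborts, naming both record ids and the pair index.
#'
#' @param hyb_records List of [hyb_record()] objects.
#' @param fold_records List of [fold_record()] objects; must have the same
#'   length (an unequal length is an error naming the exhausted stream).
#' @param policy A [merge_policy()].
#' @param n_parse_skipped Optional counts of records already dropped at
#'   parse time, carried into the statistics.
#' @return A list with `records` (merged `hyb_record_list`) and `stats`
#'   (class `merge_stats`: `yielded`, `skipped_mismatch`, `skipped_parse`).
#' @export
merge_hyb_fold <- function(hyb_records, fold_records, policy = merge_policy(),
                           n_parse_skipped = 0L) {
  nh <- length(hyb_records); nf <- length(fold_records)
  if (nh != nf) {
    short <- if (nh < nf) "hyb" else "fold"
    .stop_hyb("stream-exhausted",
              sprintf("%s stream exhausted: %d hyb record(s) vs %d fold record(s)",
                      short, nh, nf))
  }
  merged <- vector("list", nh)
  n_ok <- 0L; n_skip <- 0L
  for (k in seq_len(nh)) {
    h <- hyb_records[[k]]; f <- fold_records[[k]]
    res <- match_fold(h, f, policy)
    if (!res$ok) {
      if (policy$on_error == "raise")
        .stop_hyb("merge-mismatch",
                  sprintf("pair %d (hyb '%s', fold '%s'): %s",
                          k, h$id, f$id, res$reason))
      n_skip <- n_skip + 1L
      next
    }
    h$fold <- f
    h$fold_offset <- res$offset
    n_ok <- n_ok + 1L
    merged[[n_ok]] <- h
  }
  stats <- structure(list(yielded = n_ok, skipped_mismatch = n_skip,
                          skipped_parse = as.integer(n_parse_skipped)),
                     class = "merge_stats")
  list(records = structure(merged[seq_len(n_ok)], class = "hyb_record_list",
                           n_skipped = 0L),
       stats = stats)
}

#' @export
print.merge_stats <- function(x, ...) {
  cat(sprintf("<merge_stats> yielded %d, skipped (mismatch) %d, skipped (parse) %d\n",
              x$yielded, x$skipped_mismatch, x$skipped_parse))
  invisible(x)
}
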