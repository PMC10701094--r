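# HybRecord model: one chimeric (hybrid) read with two aligned segments
# and a key=value flag table, as written by the Hyb pipeline.

RECOGNIZED_FLAGS <- c(
  "count_total", "count_last_clustering", "two_way_merged",
  "seq_IDs_in_cluster", "read_count", "orient", "det",
  "seg1_type", "seg2_type", "seg1_det", "seg2_det",
  "miRNA_seg", "target_reg", "ext", "dataset"
)

MIRNA_SEG_CODES <- c(FIVE_P = "5p", THREE_P = "3p", BOTH = "B",
                     NONE = "N", UNEVALUATED = "U")

.default_mirna_types <- c("miRNA", "microRNA")

#' Construct one aligned segment of a hybrid read
#'
#' A segment is one of the two aligned portions of a chimeric read, mapped
#' to a reference identifier with a span in read coordinates and optionally
#' a span in reference coordinates plus a mapping score. All coordinates are
#' 1-based inclusive, following the upstream Hyb output convention.
#'
#' @param ref_name Reference identifier (e.g. a Hyb-style four-part
#'   underscore-joined ID such as `"ENSG0_ENST0_GENEA_mRNA"`). Must be
#'   non-empty and contain no tab characters.
#' @param read_start,read_end 1-based inclusive span in the chimeric read;
#'   `read_start <= read_end`, both `>= 1`.
#' @param ref_start,ref_end Optional 1-based inclusive span in the
#'   reference (`NA` when absent).
#' @param score Optional mapping score / e-value as emitted upstream
#'   (`NA` when absent).
#' @return An object of class `seg_info`.
#' @seealso [hyb_record()]
#' @export
#' @examples
#' seg_info("MIMAT0000062_MIR0062_hsa-let-7a_microRNA", 1, 22)
seg_info <- function(ref_name, read_start, read_end,
                     ref_start = NA_real_, ref_end = NA_real_,
                     score = NA_real_) {
  if (!is.character(ref_name) || length(ref_name) != 1L || !nzchar(ref_name))
    .stop_hyb("seg-ref-name", "segment ref_name must be a non-empty string")
  if (grepl("\t", ref_name))
    .stop_hyb("seg-ref-name", "segment ref_name must not contain tabs")
  read_start <- as.integer(read_start); read_end <- as.integer(read_end)
  if (is.na(read_start) || is.na(read_end) || read_start < 1L)
    .stop_hyb("coordinate", "read span coordinates must be integers >= 1")
  if (read_end < read_start)
    .stop_hyb("coordinate-order",
              sprintf("read_end (%d) < read_start (%d)", read_end, read_start))
  ref_start <- suppressWarnings(as.numeric(ref_start))
  ref_end <- suppressWarnings(as.numeric(ref_end))
  if (!is.na(ref_start) && !is.na(ref_end) && ref_end < ref_start)
    .stop_hyb("coordinate-order", "ref_end < ref_start")
  structure(list(ref_name = ref_name,
                 read_start = read_start, read_end = read_end,
                 ref_start = ref_start, ref_end = ref_end,
                 score = as.numeric(score),
                 score_token = NULL),
            class = "seg_info")
}

#' Construct a hybrid (chimeric read) record
#'
#' A `hyb_record` holds one chimeric read as produced by a CLASH-family
#' hybrid caller: read identifier, read sequence, optional hybrid energy,
#' two aligned segments (5' segment first), and an ordered `key=value` flag
#' table carrying annotations.
#'
#' By convention `seg1` is the segment with the smaller read start (the 5'
#' segment). Records read from files that violate this keep file order; the
#' violation is surfaced by [check_hyb()] as a warning-level finding, so the
#' constructor does not reject it.
#'
#' @param id Read identifier; non-empty, no whitespace.
#' @param seq Read sequence over the alphabet A, C, G, T, U, N.
#' @param seg1,seg2 [seg_info()] objects for the 5' and 3' segments.
#' @param energy Optional hybrid folding energy (kcal/mol), `NA` if absent.
#' @param flags Named character vector of flags; order is preserved when
#'   written. `NULL` or empty for no flags.
#' @param fold Optional attached [fold_record()].
#' @param fold_offset Offset (0-based) at which the fold sequence aligns
#'   within the read sequence; meaningful only when `fold` is attached.
#' @return An object of class `hyb_record`.
#' @export
#' @examples
#' rec <- hyb_record(
#'   id = "r1", seq = "AAACCCGGGTTT",
#'   seg1 = seg_info("MIMAT0_mir1_hsa-miR-1_microRNA", 1, 6),
#'   seg2 = seg_info("ENSG0_ENST0_GENEA_mRNA", 7, 12),
#'   energy = -12.3, flags = c(count_total = "5"))
#' rec
hyb_record <- function(id, seq, seg1, seg2, energy = NA_real_,
                       flags = NULL, fold = NULL, fold_offset = NA_integer_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    .stop_hyb("record-id", "record id must be non-empty with no whitespace")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    .stop_hyb("record-seq", "record seq must be a non-empty string")
  if (!grepl("^[ACGTUN]+$", seq))
    .stop_hyb("record-seq",
              sprintf("record '%s': seq contains characters outside A/C/G/T/U/N", id))
  stopifnot(inherits(seg1, "seg_info"), inherits(seg2, "seg_info"))
  n <- nchar(seq)
  for (s in list(seg1, seg2)) {
    if (s$read_end > n)
      .stop_hyb("span-exceeds-seq",
                sprintf("record '%s': segment '%s' read_end %d exceeds seq length %d",
                        id, s$ref_name, s$read_end, n))
  }
  flags <- .as_flag_table(flags)
  rec <- structure(list(id = id, seq = seq, energy = as.numeric(energy),
                        energy_token = NULL,
                        seg1 = seg1, seg2 = seg2, flags = flags,
                        fold = fold, fold_offset = as.integer(fold_offset)),
                   class = "hyb_record")
  rec
}

# normalize flags input to a uniquely-named ordered character vector
.as_flag_table <- function(flags) {
  if (is.null(flags) || length(flags) == 0L) {
    return(structure(character(0), names = character(0)))
  }
  flags <- vapply(flags, as.character, character(1))
  keys <- names(flags)
  if (is.null(keys) || any(!nzchar(keys)))
    .stop_hyb("flag-format", "flags must be a named character vector")
  if (anyDuplicated(keys))
    .stop_hyb("flag-format", "duplicate flag keys")
  .check_flag_chars(keys, values = flags)
  flags
}

.check_flag_chars <- function(keys, values) {
  bad_key <- grepl("[\t\n;=]", keys)
  bad_val <- grepl("[\t\n;]", values)
  if (any(bad_key))
    .stop_hyb("flag-format",
              sprintf("flag key '%s' contains a forbidden character", keys[bad_key][1]))
  if (any(bad_val))
    .stop_hyb("flag-format",
              sprintf("flag value '%s' contains a forbidden character", values[bad_val][1]))
  invisible(TRUE)
}

#' Set an annotation flag on a hybrid record
#'
#' Existing keys are overwritten in place (their position in the flag table
#' is kept); new keys are appended at the end, preserving write order.
#'
#' @param record A [hyb_record()].
#' @param key,value Flag key and value. Keys may not contain tab, newline,
#'   semicolon, or equals; values may not contain tab, newline, or
#'   semicolon.
#' @param allow_undefined If `FALSE`, setting a key outside the recognized
#'   hyb flag vocabulary (see `RECOGNIZED_FLAGS`) is an error.
#' @return The updated record.
#' @export
#' @examples
#' rec <- hyb_record("r1", "ACGT", seg_info("a_b_c_miRNA", 1, 2),
#'                   seg_info("d_e_f_mRNA", 3, 4))
#' rec <- set_flag(rec, "seg1_type", "miRNA")
#' flag_string(rec)
set_flag <- function(record, key, value, allow_undefined = TRUE) {
  stopifnot(inherits(record, "hyb_record"))
  value <- as.character(value)
  .check_flag_chars(key, value)
  if (!allow_undefined && !(key %in% RECOGNIZED_FLAGS))
    .stop_hyb("flag-policy",
              sprintf("flag key '%s' is not in the recognized flag set", key))
  flags <- record$flags
  if (key %in% names(flags)) {
    flags[[key]] <- value
  } else {
    flags <- c(flags, structure(value, names = key))
  }
  record$flags <- flags
  record
}

#' Read one flag value, or a default when absent
#'
#' @param record A [hyb_record()].
#' @param key Flag key.
#' @param default Value returned when the flag is absent.
#' @return Character flag value or `default`.
#' @export
get_flag <- function(record, key, default = NA_character_) {
  if (key %in% names(record$flags)) unname(record$flags[[key]]) else default
}

#' Serialize a record's flag table to the hyb flags-column string
#'
#' Pairs are written as `key=value` joined by `;`, in table order, with no
#' trailing semicolon.
#'
#' @param record A [hyb_record()] (or a named character vector of flags).
#' @return A single string; empty string for an empty flag table.
#' @export
flag_string <- function(record) {
  flags <- if (inherits(record, "hyb_record")) record$flags else .as_flag_table(record)
  if (length(flags) == 0L) return("")
  paste(names(flags), unname(flags), sep = "=", collapse = ";")
}

#' Parse a hyb flags-column string into a flag table
#'
#' Accepts an optional trailing semicolon on read (never emitted on write).
#'
#' @param s The flags column text.
#' @return Named character vector, insertion-ordered.
#' @export
parse_flag_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(.as_flag_table(NULL))
  s <- sub(";$", "", s)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  bad <- !grepl("^[^=]+=", parts)
  if (any(bad))
    .stop_hyb("flag-format", sprintf("malformed flag pair '%s'", parts[bad][1]))
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  .as_flag_table(structure(vals, names = keys))
}

#' Record count under an explicit counting mode
#'
#' Analyses can weight each hybrid by 1 (`"record"`), by its `read_count`
#' flag, or by its `count_total` flag. The mode is explicit so aggregated
#' results are reproducible under a stated weighting. A missing flag falls
#' back to 1.
#'
#' @param record A [hyb_record()].
#' @param mode One of `"record"`, `"read_count"`, `"count_total"`.
#' @return A positive integer count.
#' @export
#' @examples
#' rec <- hyb_record("r1", "ACGT", seg_info("a_b_c_miRNA", 1, 2),
#'                   seg_info("d_e_f_mRNA", 3, 4), flags = c(count_total = "5"))
#' get_count(rec, "count_total")
get_count <- function(record, mode = c("record", "read_count", "count_total")) {
  mode <- match.arg(mode)
  if (mode == "record") return(1L)
  tok <- get_flag(record, mode)
  if (is.na(tok)) return(1L)
  if (!.is_int_token(tok) || as.numeric(tok) < 1)
    .stop_hyb("malformed-flag",
              sprintf("record '%s': flag '%s' value '%s' is not a positive integer",
                      record$id, mode, tok))
  as.integer(tok)
}

#' Classify the miRNA placement of a hybrid
#'
#' Determines whether the miRNA occupies the 5' segment (`5p`), the 3'
#' segment (`3p`), both (`B`), neither (`N`), or cannot be evaluated
#' because a segment type annotation is missing (`U`). The result is also
#' written to the `miRNA_seg` flag.
#'
#' A segment is miRNA-typed when its `seg1_type`/`seg2_type` flag value is
#' a member of `mirna_types` (case-sensitive).
#'
#' @param record A [hyb_record()] with `seg1_type`/`seg2_type` flags
#'   (either may be absent, yielding `U`).
#' @param mirna_types Character set of type strings counted as miRNA.
#' @return The updated record, with the placement code in flag `miRNA_seg`.
#' @seealso [mirna_placement()] for the code without mutating the record.
#' @export
mirna_segment <- function(record, mirna_types = .default_mirna_types) {
  code <- mirna_placement(record, mirna_types)
  set_flag(record, "miRNA_seg", code)
}

#' miRNA placement code of a record
#'
#' @inheritParams mirna_segment
#' @return One of `"5p"`, `"3p"`, `"B"`, `"N"`, `"U"`.
#' @export
mirna_placement <- function(record, mirna_types = .default_mirna_types) {
  stopifnot(length(mirna_types) >= 1L)
  t1 <- get_flag(record, "seg1_type")
  t2 <- get_flag(record, "seg2_type")
  if (is.na(t1) || is.na(t2)) return("U")
  m1 <- t1 %in% mirna_types
  m2 <- t2 %in% mirna_types
  if (m1 && m2) "B" else if (m1) "5p" else if (m2) "3p" else "N"
}

#' Extract the miRNA and target subsequences of a hybrid
#'
#' Returns the read subsequence spanned by the miRNA-typed segment and by
#' the other (target) segment, in `(miRNA, target)` order, using the
#' record's `miRNA_seg` flag to decide which segment is the miRNA.
#'
#' @param record A [hyb_record()] whose `miRNA_seg` flag is `5p` or `3p`.
#' @return Named character vector `c(mirna = ..., target = ...)`.
#' @export
#' @examples
#' rec <- hyb_record("r1", "AAACCCGGGTTT",
#'                   seg_info("m_m_m_microRNA", 1, 6),
#'                   seg_info("g_g_g_mRNA", 7, 12),
#'                   flags = c(seg1_type = "miRNA", seg2_type = "mRNA",
#'                             miRNA_seg = "5p"))
#' extract_subsequences(rec)
extract_subsequences <- function(record) {
  code <- get_flag(record, "miRNA_seg")
  if (is.na(code) || !(code %in% c("5p", "3p")))
    .stop_hyb("not-applicable",
              sprintf("record '%s': miRNA_seg is '%s'; subsequence extraction needs 5p or 3p",
                      record$id, if (is.na(code)) "absent" else code))
  mir_seg <- if (code == "5p") record$seg1 else record$seg2
  tgt_seg <- if (code == "5p") record$seg2 else record$seg1
  c(mirna = substr(record$seq, mir_seg$read_start, mir_seg$read_end),
    target = substr(record$seq, tgt_seg$read_start, tgt_seg$read_end))
}

#' Field-by-field equality of two hybrid records
#'
#' Compares id, sequence, energy, both segments, and the flag key/value
#' sets. Flag order is ignored for equality (it is preserved for writing);
#' attached fold records are not compared.
#'
#' @param a,b [hyb_record()] objects.
#' @return Logical scalar.
#' @export
records_equal <- function(a, b) {
  stopifnot(inherits(a, "hyb_record"), inherits(b, "hyb_record"))
  num_eq <- function(x, y) (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && x == y)
  seg_eq <- function(s, t) {
    s$ref_name == t$ref_name &&
      s$read_start == t$read_start && s$read_end == t$read_end &&
      num_eq(s$ref_start, t$ref_start) && num_eq(s$ref_end, t$ref_end) &&
      num_eq(s$score, t$score)
  }
  if (!(a$id == b$id && a$seq == b$seq && num_eq(a$energy, b$energy)))
    return(FALSE)
  if (!(seg_eq(a$seg1, b$seg1) && seg_eq(a$seg2, b$seg2))) return(FALSE)
  fa <- a$flags; fb <- b$flags
  if (length(fa) != length(fb)) return(FALSE)
  if (!setequal(names(fa), names(fb))) return(FALSE)
  all(unname(fa[names(fb)]) == unname(fb))
}

#' @export
print.hyb_record <- function(x, ...) {
  en <- if (is.na(x$energy)) "." else format(x$energy)
  cat(sprintf("<hyb_record> %s  (%d nt, energy %s)\n", x$id, nchar(x$seq), en))
  cat(sprintf("  seg1: %s [%d-%d]\n", x$seg1$ref_name, x$seg1$read_start, x$seg1$read_end))
  cat(sprintf("  seg2: %s [%d-%d]\n", x$seg2$ref_name, x$seg2$read_start, x$seg2$read_end))
  if (length(x$flags)) cat("  flags:", flag_string(x), "\n")
  if (!is.null(x$fold)) cat(sprintf("  fold attached (offset %d)\n", x$fold_offset))
  invisible(x)
}
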