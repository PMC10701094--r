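# Segment-type classification from reference identifiers, and writing of
# seg1_type / seg2_type / miRNA_seg annotation flags.

#' Default type alias table
#'
#' Normalizes reference-library type vocabulary to canonical strings; the
#' shipped table maps `microRNA` to `miRNA` and is user-extensible.
#' Alias application is a single lookup and therefore idempotent.
#'
#' @param extra Optional additional named character vector
#'   (raw type -> canonical type), merged over the default.
#' @return Named character vector alias table.
#' @export
type_alias <- function(extra = NULL) {
  tab <- c(microRNA = "miRNA")
  if (!is.null(extra)) {
    extra <- vapply(extra, as.character, character(1))
    tab[names(extra)] <- extra
  }
  tab
}

.apply_alias <- function(type, alias) {
  if (is.null(alias) || is.na(type)) return(type)
  if (type %in% names(alias)) unname(alias[[type]]) else type
}

#' Segment-type classification methods
#'
#' Constructs a classification method object used by [classify_segment()]
#' and [evaluate_types()]. Four methods are supported:
#'
#' * `hyb_split`: split the reference identifier on a separator and take a
#'   positional element — by default the last underscore-delimited field,
#'   matching the Hyb hOH7 identifier layout `gene_transcript_name_type`.
#' * `string_match`: an ordered list of `(kind, pattern, type)` rules,
#'   kind one of `prefix`, `suffix`, `contains`, `full`; the first
#'   matching rule wins.
#' * `id_map`: exact identifier-to-type lookup table.
#' * `callable`: a user-supplied function `function(ref_name) type`.
#'
#' @param method One of `"hyb_split"`, `"string_match"`, `"id_map"`,
#'   `"callable"`.
#' @param sep,position `hyb_split` parameters: separator (default `"_"`)
#'   and element position (`"last"`, `"first"`, or an integer).
#' @param rules `string_match` rule table: data frame with columns
#'   `kind`, `pattern`, `type` (see [read_match_rules()]).
#' @param map `id_map` table: named character vector or data frame of
#'   identifier -> type (see [read_id_map()]).
#' @param fun `callable` classifier function.
#' @return An object of class `type_method`.
#' @export
#' @examples
#' m <- type_method("hyb_split")
#' classify_segment("ENSG0_ENST0_GENEA_mRNA", m)
type_method <- function(method = c("hyb_split", "string_match", "id_map", "callable"),
                        sep = "_", position = "last",
                        rules = NULL, map = NULL, fun = NULL) {
  method <- match.arg(method)
  obj <- list(method = method)
  if (method == "hyb_split") {
    obj$sep <- sep
    obj$position <- position
  } else if (method == "string_match") {
    if (is.null(rules) || nrow(rules) == 0L)
      .stop_hyb("config", "string_match requires a non-empty rule table")
    stopifnot(all(c("kind", "pattern", "type") %in% names(rules)))
    bad <- !(rules$kind %in% c("prefix", "suffix", "contains", "full"))
    if (any(bad))
      .stop_hyb("config", sprintf("unknown rule kind '%s'", rules$kind[bad][1]))
    obj$rules <- rules
  } else if (method == "id_map") {
    if (is.data.frame(map)) map <- structure(as.character(map[[2]]),
                                             names = as.character(map[[1]]))
    if (is.null(map) || is.null(names(map)))
      .stop_hyb("config", "id_map requires a named identifier -> type table")
    if (anyDuplicated(names(map)))
      .stop_hyb("config", "id_map has duplicate identifier keys")
    obj$map <- map
  } else {
    if (!is.function(fun))
      .stop_hyb("config", "callable method requires a function")
    obj$fun <- fun
  }
  structure(obj, class = "type_method")
}

#' Load a string-match rule file
#'
#' Tab- or comma-delimited lines `kind, pattern, type`; `#` comments and
#' blank lines are ignored; rule order in the file is match order.
#'
#' @param path Rule file path.
#' @return Data frame with columns `kind`, `pattern`, `type`.
#' @export
read_match_rules <- function(path) {
  lines <- .read_lines_auto(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    .stop_hyb("config", sprintf("rule file '%s' contains no rules", path))
  parts <- strsplit(lines, "[\t,]")
  bad <- lengths(parts) != 3L
  if (any(bad))
    .stop_hyb("config",
              sprintf("rule file '%s': line '%s' does not have 3 fields",
                      path, lines[bad][1]))
  m <- do.call(rbind, parts)
  data.frame(kind = trimws(m[, 1]), pattern = trimws(m[, 2]),
             type = trimws(m[, 3]), stringsAsFactors = FALSE)
}

#' Load an identifier-to-type CSV map
#'
#' Two comma-delimited columns (identifier, type); an optional header line
#' `id,type` is skipped; duplicate identifier keys are a load-time error.
#'
#' @param path CSV path.
#' @return Named character vector (identifier -> type).
#' @export
read_id_map <- function(path) {
  lines <- .read_lines_auto(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    .stop_hyb("config",
              sprintf("id map '%s': line '%s' does not have 2 fields",
                      path, lines[bad][1]))
  m <- do.call(rbind, parts)
  keys <- trimws(m[, 1]); vals <- trimws(m[, 2])
  if (length(keys) && tolower(keys[1]) == "id" && tolower(vals[1]) == "type") {
    keys <- keys[-1]; vals <- vals[-1]
  }
  if (anyDuplicated(keys))
    .stop_hyb("config",
              sprintf("id map '%s': duplicate key '%s'", path,
                      keys[duplicated(keys)][1]))
  structure(vals, names = keys)
}

#' Classify one segment identifier to a sequence type
#'
#' A pure function of its inputs. Unresolved identifiers return
#' `NA_character_`, a distinct value rather than an error (policy is
#' applied by [evaluate_types()]).
#'
#' @param ref_name Segment reference identifier.
#' @param method A [type_method()].
#' @param alias Optional alias table from [type_alias()] applied to the
#'   raw result.
#' @return Type string, or `NA_character_` when unresolved.
#' @export
#' @examples
#' classify_segment("MIMAT0_mir1_hsa-miR-1_microRNA", type_method("hyb_split"),
#'                  alias = type_alias())
classify_segment <- function(ref_name, method, alias = NULL) {
  stopifnot(inherits(method, "type_method"), nzchar(ref_name))
  raw <- switch(method$method,
    hyb_split = {
      parts <- strsplit(ref_name, method$sep, fixed = TRUE)[[1]]
      if (length(parts) < 2L) NA_character_
      else if (identical(method$position, "last")) parts[length(parts)]
      else if (identical(method$position, "first")) parts[1]
      else {
        pos <- as.integer(method$position)
        if (is.na(pos) || pos < 1L || pos > length(parts)) NA_character_
        else parts[pos]
      }
    },
    string_match = {
      hit <- NA_character_
      for (i in seq_len(nrow(method$rules))) {
        k <- method$rules$kind[i]; p <- method$rules$pattern[i]
        ok <- switch(k,
          prefix = startsWith(ref_name, p),
          suffix = endsWith(ref_name, p),
          contains = grepl(p, ref_name, fixed = TRUE),
          full = identical(ref_name, p))
        if (ok) { hit <- method$rules$type[i]; break }
      }
      hit
    },
    id_map = if (ref_name %in% names(method$map))
      unname(method$map[[ref_name]]) else NA_character_,
    callable = {
      out <- method$fun(ref_name)
      if (is.null(out) || length(out) != 1L || is.na(out)) NA_character_
      else as.character(out)
    })
  .apply_alias(raw, alias)
}

#' Annotate a record's segment types
#'
#' Writes `seg1_type` and `seg2_type` flags from the segments' reference
#' identifiers. Re-evaluation overwrites prior type flags (iterative
#' workflows). With `allow_unknown = TRUE` an unresolved identifier gets
#' the type string `"unknown"`; with `FALSE` it is an error naming the
#' offending identifier.
#'
#' @param record A [hyb_record()].
#' @param method A [type_method()].
#' @param alias Optional [type_alias()] table.
#' @param allow_unknown Unresolved-identifier policy.
#' @return The annotated record.
#' @export
evaluate_types <- function(record, method, alias = NULL, allow_unknown = TRUE) {
  for (slot in c("seg1", "seg2")) {
    type <- classify_segment(record[[slot]]$ref_name, method, alias)
    if (is.na(type)) {
      if (!allow_unknown)
        .stop_hyb("unresolved-type",
                  sprintf("record '%s': identifier '%s' could not be classified",
                          record$id, record[[slot]]$ref_name))
      type <- "unknown"
    }
    record <- set_flag(record, paste0(slot, "_type"), type)
  }
  record
}

#' Annotate a record's miRNA placement
#'
#' Delegates to [mirna_segment()]: writes the `miRNA_seg` flag from the
#' `seg1_type`/`seg2_type` flags (`U` when either is missing).
#'
#' @param record A [hyb_record()].
#' @param mirna_types Type strings counted as miRNA.
#' @return The annotated record.
#' @export
evaluate_mirna <- function(record, mirna_types = c("miRNA", "microRNA")) {
  mirna_segment(record, mirna_types)
}

#' Annotate every record in a list
#'
#' Convenience wrapper applying [evaluate_types()] then
#' [evaluate_mirna()] to each record.
#'
#' @param records List of [hyb_record()] objects.
#' @inheritParams evaluate_types
#' @inheritParams evaluate_mirna
#' @return `hyb_record_list` of annotated records.
#' @export
evaluate_records <- function(records, method, alias = NULL,
                             allow_unknown = TRUE,
                             mirna_types = c("miRNA", "microRNA")) {
  out <- lapply(records, function(r)
    evaluate_mirna(evaluate_types(r, method, alias, allow_unknown), mirna_types))
  structure(out, class = "hyb_record_list", n_skipped = 0L)
}
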