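# Predicate-based record selection: a filter spec is a set of atoms
# combined with all/any under include/exclude polarity.

#' Build a filter atom
#'
#' Atoms are the predicate vocabulary of [filter_spec()]:
#'
#' * `seg_type_contains(t)` — either segment is typed `t`
#' * `seg_type_is(t1, t2)` — the unordered type pair equals `{t1, t2}`
#' * `any_seg_type_in(set)` — either segment's type is in `set`
#' * `mirna_seg_in(codes)` — `miRNA_seg` flag is in `codes`
#' * `id_in(set)` — record id exact membership
#' * `id_matches(kind, pattern)` — record id pattern match, kind one of
#'   `prefix`, `suffix`, `contains`, `full`
#' * `ref_name_contains(s)` — either segment's reference id contains `s`
#' * `flag_equals(key, value)` — exact flag comparison
#' * `energy_le(x)` / `energy_ge(x)` — record energy bound
#' * `count_ge(n, mode)` — record count under a [get_count()] mode
#'
#' Predicates referencing a missing flag or absent energy never error:
#' they simply do not match.
#'
#' @param kind Atom kind (one of the names above).
#' @param ... Atom parameters, as listed.
#' @return An object of class `filter_atom`.
#' @export
#' @examples
#' filter_atom("seg_type_contains", type = "miRNA")
#' filter_atom("count_ge", n = 2, mode = "count_total")
filter_atom <- function(kind, ...) {
  params <- list(...)
  kinds <- c("seg_type_contains", "seg_type_is", "any_seg_type_in",
             "mirna_seg_in", "id_in", "id_matches", "ref_name_contains",
             "flag_equals", "energy_le", "energy_ge", "count_ge")
  if (!(kind %in% kinds))
    .stop_hyb("config", sprintf("unknown filter atom kind '%s'", kind))
  structure(c(list(kind = kind), params), class = "filter_atom")
}

#' Build a filter specification
#'
#' @param ... One or more [filter_atom()] objects (or a single list of
#'   them). At least one atom is required.
#' @param combine `"all"` (conjunction) or `"any"` (disjunction).
#' @param polarity `"include"` (keep matching records) or `"exclude"`
#'   (keep exactly the records an include spec would drop).
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' spec <- filter_spec(filter_atom("seg_type_contains", type = "miRNA"))
filter_spec <- function(..., combine = c("all", "any"),
                        polarity = c("include", "exclude")) {
  atoms <- list(...)
  if (length(atoms) == 1L && !inherits(atoms[[1]], "filter_atom"))
    atoms <- atoms[[1]]
  if (length(atoms) == 0L)
    .stop_hyb("config", "filter spec requires at least one atom")
  stopifnot(all(vapply(atoms, inherits, logical(1), "filter_atom")))
  structure(list(atoms = atoms, combine = match.arg(combine),
                 polarity = match.arg(polarity)),
            class = "filter_spec")
}

.seg_types <- function(record) {
  c(get_flag(record, "seg1_type"), get_flag(record, "seg2_type"))
}

.match_pattern <- function(x, kind, pattern) {
  switch(kind,
    prefix = startsWith(x, pattern),
    suffix = endsWith(x, pattern),
    contains = grepl(pattern, x, fixed = TRUE),
    full = identical(x, pattern),
    .stop_hyb("config", sprintf("unknown pattern kind '%s'", kind)))
}

.atom_matches <- function(record, atom) {
  switch(atom$kind,
    seg_type_contains = {
      ts <- .seg_types(record)
      any(!is.na(ts) & ts == atom$type)
    },
    seg_type_is = {
      ts <- .seg_types(record)
      if (anyNA(ts)) FALSE
      else all(sort(ts) == sort(c(atom$type1, atom$type2)))
    },
    any_seg_type_in = {
      ts <- .seg_types(record)
      any(!is.na(ts) & ts %in% atom$types)
    },
    mirna_seg_in = {
      code <- get_flag(record, "miRNA_seg")
      !is.na(code) && code %in% atom$codes
    },
    id_in = record$id %in% atom$ids,
    id_matches = .match_pattern(record$id, atom$pattern_kind, atom$pattern),
    ref_name_contains =
      grepl(atom$value, record$seg1$ref_name, fixed = TRUE) ||
      grepl(atom$value, record$seg2$ref_name, fixed = TRUE),
    flag_equals = {
      v <- get_flag(record, atom$key)
      !is.na(v) && v == atom$value
    },
    energy_le = !is.na(record$energy) && record$energy <= atom$threshold,
    energy_ge = !is.na(record$energy) && record$energy >= atom$threshold,
    count_ge = get_count(record, atom$mode) >= atom$n)
}

#' Test a record against a filter specification
#'
#' Under `combine = "all"` the record matches when every atom matches;
#' under `"any"` when at least one does. `polarity = "exclude"` negates
#' the result, so exclude keeps exactly the records include drops.
#'
#' @param record A [hyb_record()].
#' @param spec A [filter_spec()].
#' @return Logical: keep this record?
#' @export
hyb_matches <- function(record, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  hits <- vapply(spec$atoms, function(a) isTRUE(.atom_matches(record, a)),
                 logical(1))
  m <- if (spec$combine == "all") all(hits) else any(hits)
  if (spec$polarity == "exclude") !m else m
}

#' Filter a list of hybrid records
#'
#' Single-pass and stable: kept records preserve input order.
#'
#' @param records List of [hyb_record()] objects.
#' @param spec A [filter_spec()], or a list of specs applied in sequence
#'   (include specs first is the documented CLI precedence; here they are
#'   applied in the order given).
#' @return A list with `records` (kept, class `hyb_record_list`) and
#'   `stats` (class `filter_stats`: `n_in`, `n_kept`, `n_dropped`).
#' @export
filter_hyb <- function(records, spec) {
  specs <- if (inherits(spec, "filter_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "filter_spec")))
  n_in <- length(records)
  kept <- records
  for (s in specs) {
    keep <- vapply(kept, hyb_matches, logical(1), spec = s)
    kept <- kept[keep]
  }
  stats <- structure(list(n_in = n_in, n_kept = length(kept),
                          n_dropped = n_in - length(kept)),
                     class = "filter_stats")
  list(records = structure(kept, class = "hyb_record_list", n_skipped = 0L),
       stats = stats)
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf("<filter_stats> in %d, kept %d, dropped %d\n",
              x$n_in, x$n_kept, x$n_dropped))
  invisible(x)
}

#' Parse a CLI filter-atom expression
#'
#' Grammar used by the `hyb_filter` command line:
#' `seg_type_contains=miRNA`, `seg_type_is=miRNA,mRNA`,
#' `any_seg_type_in=tRNA,rRNA`, `mirna_seg_in=5p,3p`, `id_in=r1,r2`,
#' `id_matches=prefix:hsa`, `ref_name_contains=ENSG`,
#' `flag_equals=dataset:rep1`, `energy_le=-10`, `energy_ge=-25`,
#' `count_ge=5:count_total` (mode optional, default `record`).
#'
#' @param expr One atom expression string.
#' @return A [filter_atom()].
#' @export
parse_filter_atom <- function(expr) {
  m <- regmatches(expr, regexec("^([a-z_]+)=(.*)$", expr))[[1]]
  if (length(m) == 0L)
    .stop_hyb("config", sprintf("unparseable filter atom '%s'", expr))
  kind <- m[2]; arg <- m[3]
  split2 <- function(x, sep) strsplit(x, sep, fixed = TRUE)[[1]]
  switch(kind,
    seg_type_contains = filter_atom(kind, type = arg),
    seg_type_is = {
      p <- split2(arg, ",")
      if (length(p) != 2L)
        .stop_hyb("config", "seg_type_is needs two comma-separated types")
      filter_atom(kind, type1 = p[1], type2 = p[2])
    },
    any_seg_type_in = filter_atom(kind, types = split2(arg, ",")),
    mirna_seg_in = filter_atom(kind, codes = split2(arg, ",")),
    id_in = filter_atom(kind, ids = split2(arg, ",")),
    id_matches = {
      p <- split2(arg, ":")
      if (length(p) != 2L)
        .stop_hyb("config", "id_matches needs kind:pattern")
      filter_atom(kind, pattern_kind = p[1], pattern = p[2])
    },
    ref_name_contains = filter_atom(kind, value = arg),
    flag_equals = {
      p <- split2(arg, ":")
      if (length(p) != 2L)
        .stop_hyb("config", "flag_equals needs key:value")
      filter_atom(kind, key = p[1], value = p[2])
    },
    energy_le = filter_atom(kind, threshold = as.numeric(arg)),
    energy_ge = filter_atom(kind, threshold = as.numeric(arg)),
    count_ge = {
      p <- split2(arg, ":")
      mode <- if (length(p) >= 2L) p[2] else "record"
      filter_atom(kind, n = as.numeric(p[1]), mode = mode)
    },
    .stop_hyb("config", sprintf("unknown filter atom kind '%s'", kind)))
}
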