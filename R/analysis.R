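# Streaming descriptive analyses: records are added one at a time to an
# accumulator so every enabled analysis runs in a single pass over the
# data. Five analyses: energy, type, mirna, target, fold.

ANALYSIS_NAMES <- c("energy", "type", "mirna", "target", "fold")

#' Create an analysis accumulator
#'
#' The accumulator applies any subset of the five descriptive analyses
#' simultaneously while records are added with [add_records()]:
#'
#' * `energy` — distribution of the hybrid-record energy column
#'   (histogram, weighted mean, min, max).
#' * `type` — counters over `seg1_type`, `seg2_type`, and the unordered
#'   segment-type pair (the miRNA member is listed first when present).
#' * `mirna` — counter over miRNA placement codes (`5p`, `3p`, `B`, `N`,
#'   `U`) and over miRNA/target type pairs.
#' * `target` — per-miRNA counters of individual target references, with
#'   per-miRNA totals and unique-target counts.
#' * `fold` — per-nucleotide miRNA binding profile from attached
#'   dot-bracket folds, plus the fold-energy distribution.
#'
#' Records lacking what an analysis needs (type flags, `miRNA_seg`, an
#' attached fold) are tallied as skipped for that analysis, never errors.
#' All counting uses the configured [get_count()] mode; the binding
#' profile additionally always reports the unweighted per-record
#' denominators alongside the weighted ones.
#'
#' Records with `miRNA_seg = "B"` (both segments miRNA-typed) count under
#' `B` in the placement distribution but are excluded from the target
#' analysis and binding profile by default; `both_as_seg1 = TRUE` treats
#' their 5' segment as the miRNA instead.
#'
#' @param analyses Subset of `c("energy", "type", "mirna", "target",
#'   "fold")`.
#' @param count_mode A [get_count()] mode used to weight every analysis.
#' @param bin_width Histogram bin width for energies, kcal/mol.
#' @param mirna_types Type strings counted as miRNA.
#' @param both_as_seg1 Treat `B`-placement records as 5p in target and
#'   fold analyses.
#' @return An object of class `hyb_analysis`.
#' @seealso [add_records()], [finalize_analysis()]
#' @export
hyb_analysis <- function(analyses = ANALYSIS_NAMES,
                         count_mode = c("record", "read_count", "count_total"),
                         bin_width = 1.0,
                         mirna_types = c("miRNA", "microRNA"),
                         both_as_seg1 = FALSE) {
  analyses <- match.arg(analyses, ANALYSIS_NAMES, several.ok = TRUE)
  count_mode <- match.arg(count_mode)
  zero <- numeric(0)
  structure(list(
    analyses = analyses, count_mode = count_mode, bin_width = bin_width,
    mirna_types = mirna_types, both_as_seg1 = both_as_seg1,
    n_added = 0L,
    skipped = structure(integer(length(analyses)), names = analyses),
    energy_values = zero, energy_weights = zero,
    seg1_counts = zero, seg2_counts = zero, pair_counts = zero,
    placement_counts = structure(numeric(5), names = c("5p", "3p", "B", "N", "U")),
    pair_type_counts = zero,
    target_counts = list(),
    fold_bound_rec = zero, fold_total_rec = zero,
    fold_bound_wt = zero, fold_total_wt = zero,
    fold_energy_values = zero, fold_energy_weights = zero
  ), class = "hyb_analysis")
}

.bump <- function(counter, key, by) {
  if (key %in% names(counter)) counter[[key]] <- counter[[key]] + by
  else counter[[key]] <- by
  counter
}

.pair_key <- function(t1, t2, mirna_types) {
  # unordered pair; miRNA member listed first when present, else lexicographic
  m1 <- t1 %in% mirna_types; m2 <- t2 %in% mirna_types
  if (m1 && !m2) c(t1, t2)
  else if (m2 && !m1) c(t2, t1)
  else c(min(t1, t2), max(t1, t2))
}

#' Per-nucleotide miRNA binding positions of one merged record
#'
#' For a record with an attached fold and a `5p` or `3p` miRNA placement,
#' returns a logical vector over the miRNA's nucleotides (5' to 3' of the
#' miRNA): position i is `TRUE` when the dot-bracket character at the
#' miRNA's i-th nucleotide is `(` or `)`, i.e. predicted paired with the
#' target. The miRNA read span is translated by the fold match offset;
#' spans falling outside the fold are not applicable.
#'
#' @param record A merged [hyb_record()] (fold attached).
#' @return Logical vector of length equal to the miRNA segment, or `NULL`
#'   when the record is not applicable (no fold, placement not `5p`/`3p`,
#'   or span outside the fold).
#' @export
mirna_binding_positions <- function(record) {
  code <- get_flag(record, "miRNA_seg")
  if (is.na(code) || !(code %in% c("5p", "3p"))) return(NULL)
  if (is.null(record$fold) || is.na(record$fold_offset)) return(NULL)
  seg <- if (code == "3p") record$seg2 else record$seg1
  lo <- seg$read_start - record$fold_offset
  hi <- seg$read_end - record$fold_offset
  if (lo < 1L || hi > nchar(record$fold$fold)) return(NULL)
  chars <- strsplit(substr(record$fold$fold, lo, hi), "")[[1]]
  chars == "(" | chars == ")"
}

#' Add records to an analysis accumulator
#'
#' @param acc A [hyb_analysis()] accumulator.
#' @param records A single [hyb_record()] or a list of them.
#' @return The updated accumulator.
#' @export
add_records <- function(acc, records) {
  stopifnot(inherits(acc, "hyb_analysis"))
  if (inherits(records, "hyb_record")) records <- list(records)
  for (rec in records) acc <- .add_one(acc, rec)
  acc
}

.add_one <- function(acc, rec) {
  stopifnot(inherits(rec, "hyb_record"))
  acc$n_added <- acc$n_added + 1L
  n <- get_count(rec, acc$count_mode)
  t1 <- get_flag(rec, "seg1_type"); t2 <- get_flag(rec, "seg2_type")
  code <- get_flag(rec, "miRNA_seg")

  if ("energy" %in% acc$analyses) {
    if (is.na(rec$energy)) {
      acc$skipped[["energy"]] <- acc$skipped[["energy"]] + 1L
    } else {
      acc$energy_values <- c(acc$energy_values, rec$energy)
      acc$energy_weights <- c(acc$energy_weights, n)
    }
  }

  if ("type" %in% acc$analyses) {
    if (is.na(t1) || is.na(t2)) {
      acc$skipped[["type"]] <- acc$skipped[["type"]] + 1L
    } else {
      acc$seg1_counts <- .bump(acc$seg1_counts, t1, n)
      acc$seg2_counts <- .bump(acc$seg2_counts, t2, n)
      pk <- .pair_key(t1, t2, acc$mirna_types)
      acc$pair_counts <- .bump(acc$pair_counts, paste(pk, collapse = "--"), n)
    }
  }

  if ("mirna" %in% acc$analyses) {
    if (is.na(code)) {
      acc$skipped[["mirna"]] <- acc$skipped[["mirna"]] + 1L
    } else {
      acc$placement_counts <- .bump(acc$placement_counts, code, n)
      if (code %in% c("5p", "3p")) {
        tm <- if (code == "5p") t1 else t2
        tt <- if (code == "5p") t2 else t1
        acc$pair_type_counts <- .bump(acc$pair_type_counts,
                                      paste(tm, tt, sep = "--"), n)
      }
    }
  }

  if ("target" %in% acc$analyses) {
    eff <- if (code %in% c("5p", "3p")) code
           else if (identical(code, "B") && acc$both_as_seg1) "5p"
           else NA_character_
    if (is.na(eff)) {
      acc$skipped[["target"]] <- acc$skipped[["target"]] + 1L
    } else {
      mir <- if (eff == "5p") rec$seg1$ref_name else rec$seg2$ref_name
      tgt <- if (eff == "5p") rec$seg2$ref_name else rec$seg1$ref_name
      if (is.null(acc$target_counts[[mir]]))
        acc$target_counts[[mir]] <- numeric(0)
      acc$target_counts[[mir]] <- .bump(acc$target_counts[[mir]], tgt, n)
    }
  }

  if ("fold" %in% acc$analyses) {
    rec2 <- rec
    if (identical(code, "B") && acc$both_as_seg1)
      rec2 <- set_flag(rec, "miRNA_seg", "5p")
    bvec <- if (identical(code, "B") && !acc$both_as_seg1) NULL
            else mirna_binding_positions(rec2)
    if (is.null(bvec)) {
      acc$skipped[["fold"]] <- acc$skipped[["fold"]] + 1L
    } else {
      L <- length(bvec)
      grow <- function(v) { length(v) <- max(length(v), L); v[is.na(v)] <- 0; v }
      acc$fold_bound_rec <- grow(acc$fold_bound_rec)
      acc$fold_total_rec <- grow(acc$fold_total_rec)
      acc$fold_bound_wt <- grow(acc$fold_bound_wt)
      acc$fold_total_wt <- grow(acc$fold_total_wt)
      idx <- seq_len(L)
      acc$fold_bound_rec[idx] <- acc$fold_bound_rec[idx] + bvec
      acc$fold_total_rec[idx] <- acc$fold_total_rec[idx] + 1
      acc$fold_bound_wt[idx] <- acc$fold_bound_wt[idx] + bvec * n
      acc$fold_total_wt[idx] <- acc$fold_total_wt[idx] + n
      if (!is.na(rec$fold$energy)) {
        acc$fold_energy_values <- c(acc$fold_energy_values, rec$fold$energy)
        acc$fold_energy_weights <- c(acc$fold_energy_weights, n)
      }
    }
  }

  acc
}

# named counter -> data.frame sorted by descending count, ties lexicographic
.counter_table <- function(counter, name_col = "category") {
  if (length(counter) == 0L) {
    df <- data.frame(category = character(0), count = numeric(0),
                     stringsAsFactors = FALSE)
    names(df)[1] <- name_col
    return(df)
  }
  o <- order(-unname(counter), names(counter))
  df <- data.frame(category = names(counter)[o],
                   count = unname(counter)[o], stringsAsFactors = FALSE)
  names(df)[1] <- name_col
  df
}

.weighted_summary <- function(values, weights, bin_width) {
  if (length(values) == 0L) {
    return(list(n = 0, mean = NA_real_, min = NA_real_, max = NA_real_,
                histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                       count = numeric(0))))
  }
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bins <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(weights[bins == b]), numeric(1))
  list(n = sum(weights),
       mean = sum(values * weights) / sum(weights),
       min = min(values), max = max(values),
       histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1], count = counts))
}

#' Finalize an analysis accumulator into result tables
#'
#' Counter tables are sorted by descending count with ties broken
#' lexicographically, so results are deterministic and invariant under
#' permutation of the input records.
#'
#' @param acc A [hyb_analysis()] accumulator (empty is allowed).
#' @return An object of class `hyb_analysis_results`: a list with one
#'   element per enabled analysis —
#'   `type` (`seg1`, `seg2`, `pairs` tables), `mirna` (`placement`,
#'   `pair_types` tables), `target` (`counts` and `summary` tables),
#'   `energy` (n/mean/min/max and histogram), `fold` (`energy` summary
#'   and the binding `profile` table with both per-record and weighted
#'   denominators) — plus `skipped` tallies, `count_mode`, and
#'   `n_added`.
#' @export
finalize_analysis <- function(acc) {
  stopifnot(inherits(acc, "hyb_analysis"))
  res <- list(analyses = acc$analyses, count_mode = acc$count_mode,
              n_added = acc$n_added, skipped = acc$skipped)
  if ("type" %in% acc$analyses) {
    res$type <- list(seg1 = .counter_table(acc$seg1_counts, "type"),
                     seg2 = .counter_table(acc$seg2_counts, "type"),
                     pairs = .counter_table(acc$pair_counts, "type_pair"))
  }
  if ("mirna" %in% acc$analyses) {
    pc <- acc$placement_counts[acc$placement_counts > 0]
    res$mirna <- list(placement = .counter_table(pc, "placement"),
                      pair_types = .counter_table(acc$pair_type_counts,
                                                  "mirna_target_types"))
  }
  if ("target" %in% acc$analyses) {
    rows <- list(); srows <- list()
    for (mir in sort(names(acc$target_counts))) {
      tab <- .counter_table(acc$target_counts[[mir]], "target")
      if (nrow(tab) == 0L) next
      rows[[mir]] <- data.frame(mirna = mir, tab, stringsAsFactors = FALSE)
      srows[[mir]] <- data.frame(mirna = mir, total = sum(tab$count),
                                 unique_targets = nrow(tab),
                                 stringsAsFactors = FALSE)
    }
    counts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mirna = character(0), target = character(0),
                 count = numeric(0), stringsAsFactors = FALSE)
    summary <- if (length(srows)) do.call(rbind, srows) else
      data.frame(mirna = character(0), total = numeric(0),
                 unique_targets = integer(0), stringsAsFactors = FALSE)
    # order miRNAs by descending total, ties lexicographic
    if (nrow(summary)) {
      o <- order(-summary$total, summary$mirna)
      summary <- summary[o, , drop = FALSE]
      counts <- do.call(rbind, rows[summary$mirna])
    }
    rownames(counts) <- NULL; rownames(summary) <- NULL
    res$target <- list(counts = counts, summary = summary)
  }
  if ("energy" %in% acc$analyses) {
    res$energy <- .weighted_summary(acc$energy_values, acc$energy_weights,
                                    acc$bin_width)
  }
  if ("fold" %in% acc$analyses) {
    L <- length(acc$fold_total_rec)
    profile <- data.frame(
      position = seq_len(L),
      bound_record = if (L) acc$fold_bound_rec else numeric(0),
      total_record = if (L) acc$fold_total_rec else numeric(0),
      bound_weighted = if (L) acc$fold_bound_wt else numeric(0),
      total_weighted = if (L) acc$fold_total_wt else numeric(0))
    profile$frac_record <- ifelse(profile$total_record > 0,
                                  profile$bound_record / profile$total_record,
                                  NA_real_)
    profile$frac_weighted <- ifelse(profile$total_weighted > 0,
                                    profile$bound_weighted / profile$total_weighted,
                                    NA_real_)
    res$fold <- list(energy = .weighted_summary(acc$fold_energy_values,
                                                acc$fold_energy_weights,
                                                acc$bin_width),
                     profile = profile)
  }
  structure(res, class = "hyb_analysis_results")
}

#' @export
print.hyb_analysis <- function(x, ...) {
  cat(sprintf("<hyb_analysis> %d record(s) added; analyses: %s; count mode: %s\n",
              x$n_added, paste(x$analyses, collapse = ", "), x$count_mode))
  invisible(x)
}

#' @export
print.hyb_analysis_results <- function(x, ...) {
  cat(sprintf("<hyb_analysis_results> %d record(s), count mode %s\n",
              x$n_added, x$count_mode))
  for (a in x$analyses)
    cat(sprintf("  %s: %d record(s) skipped\n", a, x$skipped[[a]]))
  invisible(x)
}

#' Write analysis results as TSV files
#'
#' One or more TSV files per enabled analysis, named
#' `<prefix>.<analysis>[...].tsv` under `dir`:
#' `type` (columns `table`, `category`, `count`; tables `seg1`, `seg2`,
#' `pair`), `mirna` (same layout; tables `placement`, `pair_types`),
#' `target` and `target_summary`, `energy` (histogram), `fold_energy`
#' (histogram) and `fold_profile` (per-position bound/total counts and
#' fractions under both weightings).
#'
#' @param results A [finalize_analysis()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_analysis_tsv <- function(results, dir, prefix = "analysis") {
  stopifnot(inherits(results, "hyb_analysis_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, sprintf("%s.%s.tsv", prefix, name))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  long <- function(tabs) {
    do.call(rbind, lapply(names(tabs), function(nm) {
      df <- tabs[[nm]]
      if (nrow(df) == 0L)
        return(data.frame(table = character(0), category = character(0),
                          count = numeric(0), stringsAsFactors = FALSE))
      data.frame(table = nm, category = df[[1]], count = df$count,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(results$type))
    emit(long(list(seg1 = results$type$seg1, seg2 = results$type$seg2,
                   pair = results$type$pairs)), "type")
  if (!is.null(results$mirna))
    emit(long(list(placement = results$mirna$placement,
                   pair_types = results$mirna$pair_types)), "mirna")
  if (!is.null(results$target)) {
    emit(results$target$counts, "target")
    emit(results$target$summary, "target_summary")
  }
  if (!is.null(results$energy))
    emit(results$energy$histogram, "energy")
  if (!is.null(results$fold)) {
    emit(results$fold$energy$histogram, "fold_energy")
    emit(results$fold$profile, "fold_profile")
  }
  invisible(written)
}
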