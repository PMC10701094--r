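# Test helpers: compact record construction and randomized filter specs.

mk_rec <- function(id = "r1", seq = "AAACCCGGGTTT",
                   s1 = c(1, 6), s2 = c(7, 12),
                   ref1 = "MIMAT0_mir1_hsa-miR-1_microRNA",
                   ref2 = "ENSG0_ENST0_GENEA_mRNA",
                   energy = NA_real_, flags = NULL) {
  hyb_record(id, seq,
             seg_info(ref1, s1[1], s1[2]),
             seg_info(ref2, s2[1], s2[2]),
             energy = energy, flags = flags)
}

# annotated record with an attached fold whose dot-bracket is given
mk_merged <- function(fold_str, placement = "5p", ...) {
  rec <- mk_rec(...)
  rec <- set_flag(rec, "seg1_type",
                  if (placement %in% c("5p", "B")) "miRNA" else "mRNA")
  rec <- set_flag(rec, "seg2_type",
                  if (placement %in% c("3p", "B")) "miRNA" else "mRNA")
  rec <- set_flag(rec, "miRNA_seg", placement)
  rec$fold <- fold_record(rec$id, chartr("T", "U", rec$seq), fold_str)
  rec$fold_offset <- 0L
  rec
}

# one randomized filter spec drawn from the vocabulary, parameterized
# from an observed record population
random_filter_spec <- function(records) {
  types <- unique(unlist(lapply(records, function(r)
    c(get_flag(r, "seg1_type"), get_flag(r, "seg2_type")))))
  types <- types[!is.na(types)]
  ids <- vapply(records, function(r) r$id, character(1))
  pick <- function(x) x[sample.int(length(x), 1)]
  atom <- switch(pick(c("type", "pair", "set", "mirna", "id", "idpat",
                        "refname", "flag", "energy", "count")),
    type = filter_atom("seg_type_contains", type = pick(types)),
    pair = filter_atom("seg_type_is", type1 = pick(types), type2 = pick(types)),
    set = filter_atom("any_seg_type_in",
                      types = sample(types, min(2, length(types)))),
    mirna = filter_atom("mirna_seg_in",
                        codes = sample(c("5p", "3p", "B", "N"),
                                       sample.int(3, 1))),
    id = filter_atom("id_in", ids = sample(ids, min(5, length(ids)))),
    idpat = filter_atom("id_matches", pattern_kind = "prefix",
                        pattern = substr(pick(ids), 1, 6)),
    refname = filter_atom("ref_name_contains",
                          value = pick(c("miR", "ENSG", "GENE"))),
    flag = filter_atom("flag_equals", key = "count_total",
                       value = as.character(sample.int(4, 1))),
    energy = filter_atom(pick(c("energy_le", "energy_ge")),
                         threshold = runif(1, -6, -1)),
    count = filter_atom("count_ge", n = sample.int(3, 1),
                        mode = "count_total"))
  n_extra <- sample.int(2, 1) - 1L
  atoms <- c(list(atom), lapply(seq_len(n_extra), function(i)
    filter_atom("seg_type_contains", type = pick(types))))
  filter_spec(atoms, combine = pick(c("all", "any")), polarity = "include")
}

# brute-force binding profile recomputed directly from dot-bracket strings
brute_force_profile <- function(records, count_mode = "record") {
  L_max <- 0L
  rows <- list()
  for (rec in records) {
    code <- get_flag(rec, "miRNA_seg")
    if (is.na(code) || !(code %in% c("5p", "3p"))) next
    if (is.null(rec$fold)) next
    seg <- if (code == "5p") rec$seg1 else rec$seg2
    lo <- seg$read_start - rec$fold_offset
    hi <- seg$read_end - rec$fold_offset
    if (lo < 1 || hi > nchar(rec$fold$fold)) next
    chars <- strsplit(substr(rec$fold$fold, lo, hi), "")[[1]]
    rows[[length(rows) + 1L]] <-
      list(bound = chars %in% c("(", ")"), w = get_count(rec, count_mode))
    L_max <- max(L_max, hi - lo + 1L)
  }
  bound <- numeric(L_max); total <- numeric(L_max)
  for (r in rows) {
    idx <- seq_along(r$bound)
    bound[idx] <- bound[idx] + r$bound * r$w
    total[idx] <- total[idx] + r$w
  }
  list(bound = bound, total = total)
}
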