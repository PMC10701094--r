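# Seeded synthetic generator of paired hyb + Vienna files with a ground
# truth table, emulating qCLASH-style miRNA/target chimera datasets for
# testing complete workflows without external data.

#' Specification for a synthetic hyb + Vienna fixture dataset
#'
#' Defines the study conditions a generated dataset emulates: reference
#' pools with Hyb-style four-part identifiers, the target biotype
#' mixture, the miRNA placement mixture, a geometric read-count
#' distribution, and a simple duplex model (a contiguous block of `b`
#' paired miRNA nucleotides at a random offset, with pseudo-energy
#' `-0.5 * b` plus uniform noise on (-0.5, 0.5) kcal/mol). miRNA pool
#' sequences are 18-22 nt, targets 20-40 nt. The pseudo-energy model is
#' deliberately simple and synthetic: it exercises plumbing and weighted
#' statistics, not thermodynamics.
#'
#' Generation is a pure function of the spec (which includes the seed):
#' a single seeded stream drives every choice, so one integer reproduces
#' a dataset.
#'
#' @param n_records Number of hybrid records to generate.
#' @param seed Integer seed driving all randomness.
#' @param n_mirnas,n_targets Reference pool sizes.
#' @param type_mixture Named probabilities of target biotypes (must sum
#'   to 1).
#' @param placement_mixture Named probabilities over placements `5p`
#'   (miRNA is the 5' segment), `3p`, `B` (both segments miRNA), `N`
#'   (no miRNA); must sum to 1.
#' @param count_p Geometric parameter for `count_total` (counts are
#'   `1 + rgeom(count_p)`).
#' @param bound_range Range (inclusive) from which the number of bound
#'   miRNA nucleotides `b` is drawn uniformly.
#' @param mismatch_rate Fraction of records whose Vienna sequence gets a
#'   single substituted nucleotide (negative controls for merge
#'   checking).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_records = 100L, seed = 1L,
                         n_mirnas = 8L, n_targets = 24L,
                         type_mixture = c(mRNA = 0.6, lncRNA = 0.3, rRNA = 0.1),
                         placement_mixture = c("5p" = 0.70, "3p" = 0.20,
                                               "B" = 0.05, "N" = 0.05),
                         count_p = 0.5,
                         bound_range = c(4L, 10L),
                         mismatch_rate = 0) {
  if (abs(sum(type_mixture) - 1) > 1e-8)
    .stop_hyb("config", "type_mixture probabilities must sum to 1")
  if (abs(sum(placement_mixture) - 1) > 1e-8)
    .stop_hyb("config", "placement_mixture probabilities must sum to 1")
  if (!all(names(placement_mixture) %in% c("5p", "3p", "B", "N")))
    .stop_hyb("config", "placement_mixture names must be 5p, 3p, B, N")
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 n_mirnas = as.integer(n_mirnas),
                 n_targets = as.integer(n_targets),
                 type_mixture = type_mixture,
                 placement_mixture = placement_mixture,
                 count_p = count_p,
                 bound_range = as.integer(bound_range),
                 mismatch_rate = mismatch_rate),
            class = "fixture_spec")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.make_pools <- function(spec) {
  mirnas <- lapply(seq_len(spec$n_mirnas), function(i) {
    list(name = sprintf("MIMAT%07d_MIR%04d_hsa-miR-%d_microRNA", i, i, i),
         seq = .rand_seq(sample(18:22, 1)))
  })
  types <- names(spec$type_mixture)
  # at least one pool entry per biotype, remainder assigned proportionally
  tt <- rep(types, length.out = max(spec$n_targets, length(types)))
  if (spec$n_targets > length(types)) {
    extra <- sample(types, spec$n_targets - length(types), replace = TRUE,
                    prob = spec$type_mixture)
    tt <- c(types, extra)
  }
  targets <- lapply(seq_along(tt), function(i) {
    list(name = sprintf("ENSG%07d_ENST%07d_GENE%d_%s", i, i, i, tt[i]),
         seq = .rand_seq(sample(20:40, 1)), type = tt[i])
  })
  list(mirnas = mirnas, targets = targets)
}

#' Generate a synthetic hyb + Vienna dataset with ground truth
#'
#' Builds `n_records` hybrid records: each read sequence is the
#' concatenation of its two segment sequences with 1-based inclusive
#' coordinates; the paired Vienna record covers the full read (RNA
#' alphabet, so T/U equivalence is exercised), with the dot-bracket
#' encoding exactly the truth table's bound positions as a `(` block on
#' the 5' partner and a matching `)` block on the 3' partner. The hyb and
#' Vienna streams are record-aligned (k-th with k-th).
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `hyb_fixture`: `hyb` (a `hyb_record_list`),
#'   `vienna` (a `fold_record_list`), and `truth` (a data frame with one
#'   row per record: id, placement, segment references and types, miRNA
#'   and target references, `count_total`, number of bound nucleotides
#'   `b`, the bound vector over miRNA positions as a 0/1 string, energy,
#'   and whether a fold-sequence mismatch was injected).
#' @export
#' @examples
#' fix <- generate_fixture(fixture_spec(n_records = 5, seed = 42))
#' fix$truth$placement
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    pools <- .make_pools(spec)
    tgt_by_type <- split(seq_along(pools$targets),
                         vapply(pools$targets, `[[`, character(1), "type"))
    hyb <- vector("list", spec$n_records)
    vienna <- vector("list", spec$n_records)
    truth <- vector("list", spec$n_records)
    placements <- sample(names(spec$placement_mixture), spec$n_records,
                         replace = TRUE, prob = spec$placement_mixture)
    for (k in seq_len(spec$n_records)) {
      id <- sprintf("read_%05d", k)
      pl <- placements[k]
      pick_target <- function() {
        ty <- sample(names(spec$type_mixture), 1, prob = spec$type_mixture)
        idxs <- tgt_by_type[[ty]]
        pools$targets[[idxs[sample.int(length(idxs), 1)]]]
      }
      pick_mirna <- function() pools$mirnas[[sample.int(length(pools$mirnas), 1)]]
      if (pl == "5p") { p5 <- pick_mirna(); p3 <- pick_target() }
      else if (pl == "3p") { p5 <- pick_target(); p3 <- pick_mirna() }
      else if (pl == "B") { p5 <- pick_mirna(); p3 <- pick_mirna() }
      else { p5 <- pick_target(); p3 <- pick_target() }
      l5 <- nchar(p5$seq); l3 <- nchar(p3$seq)
      seq <- paste0(p5$seq, p3$seq)
      brng <- spec$bound_range[1]:spec$bound_range[2]
      b <- brng[sample.int(length(brng), 1)]
      b <- min(b, l5, l3)
      off5 <- sample.int(l5 - b + 1L, 1) - 1L
      off3 <- sample.int(l3 - b + 1L, 1) - 1L
      fold_chars <- rep(".", l5 + l3)
      fold_chars[(off5 + 1L):(off5 + b)] <- "("
      fold_chars[(l5 + off3 + 1L):(l5 + off3 + b)] <- ")"
      fold <- paste(fold_chars, collapse = "")
      energy <- round(-0.5 * b + stats::runif(1, -0.5, 0.5), 1)
      count <- 1L + stats::rgeom(1, spec$count_p)
      seg1 <- seg_info(p5$name, 1L, l5, 1L, l5, 0.001)
      seg1$score_token <- "0.001"
      seg2 <- seg_info(p3$name, l5 + 1L, l5 + l3, 1L, l3, 0.001)
      seg2$score_token <- "0.001"
      rec <- hyb_record(id, seq, seg1, seg2, energy = energy,
                        flags = c(count_total = as.character(count)))
      rec$energy_token <- sprintf("%.1f", energy)
      fold_seq <- chartr("T", "U", seq)
      mismatched <- stats::runif(1) < spec$mismatch_rate
      if (mismatched) {
        pos <- sample.int(nchar(fold_seq), 1)
        cur <- substr(fold_seq, pos, pos)
        repl <- setdiff(c("A", "C", "G", "U"), cur)[1]
        substr(fold_seq, pos, pos) <- repl
      }
      vrec <- fold_record(id, fold_seq, fold, energy)
      vrec$energy_token <- sprintf("%.1f", energy)
      # truth bound vector over miRNA positions (5' to 3' of the miRNA);
      # for B the 5' segment is taken, for N there is no miRNA
      mir_side <- switch(pl, "5p" = "5", "3p" = "3", "B" = "5", "N" = NA)
      bound <- if (is.na(mir_side)) "" else {
        L <- if (mir_side == "5") l5 else l3
        v <- integer(L)
        if (mir_side == "5") v[(off5 + 1L):(off5 + b)] <- 1L
        else v[(off3 + 1L):(off3 + b)] <- 1L
        paste(v, collapse = "")
      }
      type_of <- function(p) if (grepl("_microRNA$", p$name)) "miRNA" else p$type
      truth[[k]] <- data.frame(
        id = id, placement = pl,
        seg1_ref = p5$name, seg2_ref = p3$name,
        seg1_type = type_of(p5), seg2_type = type_of(p3),
        mirna_ref = switch(pl, "5p" = p5$name, "3p" = p3$name, NA_character_),
        target_ref = switch(pl, "5p" = p3$name, "3p" = p5$name, NA_character_),
        count = count, b = b, bound = bound, energy = energy,
        fold_mismatch = mismatched, stringsAsFactors = FALSE)
      hyb[[k]] <- rec
      vienna[[k]] <- vrec
    }
    structure(list(spec = spec,
                   hyb = structure(hyb, class = "hyb_record_list", n_skipped = 0L),
                   vienna = structure(vienna, class = "fold_record_list",
                                      n_skipped = 0L),
                   truth = do.call(rbind, truth)),
              class = "hyb_fixture")
  })
}

#' @export
print.hyb_fixture <- function(x, ...) {
  cat(sprintf("<hyb_fixture> %d records (seed %d)\n",
              length(x$hyb), x$spec$seed))
  print(table(x$truth$placement))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes `<prefix>.hyb`, `<prefix>.vienna`, and `<prefix>.truth.tsv`
#' under `dir`.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, prefix = "fixture") {
  stopifnot(inherits(fixture, "hyb_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(hyb = file.path(dir, paste0(prefix, ".hyb")),
             vienna = file.path(dir, paste0(prefix, ".vienna")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  write_hyb(fixture$hyb, paths[["hyb"]])
  write_vienna(fixture$vienna, paths[["vienna"]])
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Generate a fixture with one deliberately defective record
#'
#' Produces the same files as [generate_fixture()]/[write_fixture()]
#' would, then injects exactly one defect of the requested kind into the
#' serialized lines, returning the text lines plus a manifest naming the
#' defective record.
#'
#' Defects: `field-count` (a hyb line loses its last field),
#' `bad-coordinate` (a hyb line's seg1 read span is reversed),
#' `unbalanced-fold` (a dot-bracket line loses a closing bracket),
#' `seq-mismatch` (one Vienna sequence nucleotide substituted, so the
#' merge check fails).
#'
#' @param spec A [fixture_spec()].
#' @param defect One of `"field-count"`, `"bad-coordinate"`,
#'   `"unbalanced-fold"`, `"seq-mismatch"`.
#' @param record_index Which record to damage (default: the middle one).
#' @return A list with `hyb_lines`, `vienna_lines`, and `manifest` (data
#'   frame: `record_index`, `hyb_line`, `defect`).
#' @export
generate_malformed <- function(spec,
                               defect = c("field-count", "bad-coordinate",
                                          "unbalanced-fold", "seq-mismatch"),
                               record_index = NULL) {
  defect <- match.arg(defect)
  fix <- generate_fixture(spec)
  if (is.null(record_index)) record_index <- max(1L, spec$n_records %/% 2L)
  stopifnot(record_index >= 1L, record_index <= spec$n_records)
  hyb_lines <- vapply(fix$hyb, write_hyb_line, character(1))
  vienna_lines <- unlist(lapply(fix$vienna, write_vienna_record),
                         use.names = FALSE)
  i <- record_index
  if (defect == "field-count") {
    # drop the last two fields so the line falls below 15 columns even
    # when the optional flags column was present
    hyb_lines[i] <- sub("\t[^\t]*\t[^\t]*$", "", hyb_lines[i])
  } else if (defect == "bad-coordinate") {
    f <- strsplit(hyb_lines[i], "\t", fixed = TRUE)[[1]]
    tmp <- f[5]; f[5] <- f[6]; f[6] <- tmp
    if (f[5] == f[6]) f[5] <- as.character(as.integer(f[5]) + 1L)
    hyb_lines[i] <- paste(f, collapse = "\t")
  } else if (defect == "unbalanced-fold") {
    vi <- 3L * (i - 1L) + 3L
    vienna_lines[vi] <- sub("\\)", ".", vienna_lines[vi])
  } else {
    vi <- 3L * (i - 1L) + 2L
    s <- vienna_lines[vi]
    cur <- substr(s, 1L, 1L)
    repl <- setdiff(c("A", "C", "G", "U"), cur)[1]
    substr(s, 1L, 1L) <- repl
    vienna_lines[vi] <- s
  }
  list(hyb_lines = hyb_lines, vienna_lines = vienna_lines,
       manifest = data.frame(record_index = i, hyb_line = i, defect = defect,
                             stringsAsFactors = FALSE))
}
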