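# Streaming analyses: accumulation, finalization, binding profile, plots.

test_that("type analysis counts pairs unordered with miRNA listed first", {
  rec <- mk_rec(flags = c(seg1_type = "miRNA", seg2_type = "mRNA",
                          count_total = "5"))
  acc <- hyb_analysis("type", count_mode = "count_total")
  acc <- add_records(acc, rec)
  res <- finalize_analysis(acc)
  expect_identical(res$type$pairs$type_pair, "miRNA--mRNA")
  expect_identical(res$type$pairs$count, 5)
  # reversed orientation lands in the same unordered pair
  rev_rec <- mk_rec(id = "r2", flags = c(seg1_type = "mRNA",
                                         seg2_type = "miRNA"))
  res2 <- finalize_analysis(add_records(acc, rev_rec))
  expect_identical(res2$type$pairs$count, 6)
})

test_that("mirna analysis counts placements and tallies skipped records", {
  recs <- list(
    set_flag(mk_rec(id = "a"), "miRNA_seg", "5p"),
    set_flag(mk_rec(id = "b"), "miRNA_seg", "5p"),
    set_flag(mk_rec(id = "c"), "miRNA_seg", "3p"),
    mk_rec(id = "d"))  # no flag: skipped
  res <- finalize_analysis(add_records(hyb_analysis("mirna"), recs))
  expect_identical(res$mirna$placement$placement, c("5p", "3p"))
  expect_identical(res$mirna$placement$count, c(2, 1))
  expect_identical(unname(res$skipped[["mirna"]]), 1L)
})

test_that("records without a fold are tallied fold-skipped, others still count", {
  with_fold <- mk_merged("((((((......))))))", seq = "AAACCCGGGTTTAAACCC",
                         s1 = c(1, 6), s2 = c(7, 18))
  without <- set_flag(mk_rec(id = "r2"), "miRNA_seg", "5p")
  without <- set_flag(without, "seg1_type", "miRNA")
  without <- set_flag(without, "seg2_type", "mRNA")
  acc <- add_records(hyb_analysis(c("type", "fold")),
                     list(with_fold, without))
  res <- finalize_analysis(acc)
  expect_identical(unname(res$skipped[["fold"]]), 1L)
  expect_identical(sum(res$type$pairs$count), 2)
})

test_that("binding positions read the dot-bracket over the miRNA span", {
  rec <- mk_merged("..((((....))))....", seq = "AAACCCGGGTTTAAACCC",
                   s1 = c(1, 6), s2 = c(7, 18))
  expect_identical(mirna_binding_positions(rec),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  unbound <- mk_merged(strrep(".", 18), seq = "AAACCCGGGTTTAAACCC",
                       s1 = c(1, 6), s2 = c(7, 18))
  expect_identical(mirna_binding_positions(unbound), rep(FALSE, 6))
  # 3p miRNA: vector is still 5'->3' over the miRNA (second) segment
  rec3 <- mk_merged("((((((......))))))", placement = "3p",
                    seq = "AAACCCGGGTTTAAACCC", s1 = c(1, 12), s2 = c(13, 18))
  expect_identical(mirna_binding_positions(rec3), rep(TRUE, 6))
  # span translated outside the fold: not applicable
  short <- set_flag(mk_rec(seq = "AAACCCGGGTTT", s1 = c(1, 6), s2 = c(7, 12)),
                    "miRNA_seg", "5p")
  short$fold <- fold_record("r1", "ACGU", "....")
  short$fold_offset <- 0L  # miRNA span 1-6 overruns the 4-nt fold
  expect_null(mirna_binding_positions(short))
  expect_null(mirna_binding_positions(set_flag(rec, "miRNA_seg", "N")))
})

test_that("finalize sorts counters by count then name and does the target math", {
  recs <- list(
    mk_rec(id = "a", flags = c(seg1_type = "miRNA", seg2_type = "mRNA",
                               miRNA_seg = "5p", count_total = "5")),
    mk_rec(id = "b", ref2 = "ENSG1_ENST1_GENEB_mRNA",
           flags = c(seg1_type = "miRNA", seg2_type = "mRNA",
                     miRNA_seg = "5p", count_total = "4")))
  res <- finalize_analysis(add_records(
    hyb_analysis("target", count_mode = "count_total"), recs))
  expect_identical(res$target$summary$total, 9)
  expect_identical(res$target$summary$unique_targets, 2L)
  expect_identical(res$target$counts$count, c(5, 4))
  # ties break lexicographically
  acc <- hyb_analysis("mirna")
  for (cd in c("N", "B", "3p", "5p"))
    acc <- add_records(acc, set_flag(mk_rec(id = paste0("r", cd)),
                                     "miRNA_seg", cd))
  res2 <- finalize_analysis(acc)
  expect_identical(res2$mirna$placement$placement, c("3p", "5p", "B", "N"))
})

test_that("energy summaries use the configured count weighting", {
  recs <- list(mk_rec(id = "a", energy = -10, flags = c(count_total = "1")),
               mk_rec(id = "b", energy = -20, flags = c(count_total = "3")))
  res <- finalize_analysis(add_records(
    hyb_analysis("energy", count_mode = "count_total"), recs))
  expect_equal(res$energy$mean, -17.5)   # (-10*1 + -20*3) / 4
  expect_equal(res$energy$n, 4)
  expect_equal(res$energy$min, -20)
  expect_equal(res$energy$max, -10)
  expect_equal(sum(res$energy$histogram$count), 4)
  # unweighted mode gives the plain mean
  res_u <- finalize_analysis(add_records(hyb_analysis("energy"), recs))
  expect_equal(res_u$energy$mean, -15)
})

test_that("accumulator results are invariant under input permutation", {
  fix <- generate_fixture(fixture_spec(n_records = 40, seed = 31))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  recs <- merge_hyb_fold(recs, fix$vienna, merge_policy("static"))$records
  run <- function(rr) finalize_analysis(add_records(
    hyb_analysis(count_mode = "count_total"), rr))
  set.seed(1)
  r1 <- run(recs)
  r2 <- run(sample(recs))
  expect_equal(r1$type, r2$type)
  expect_equal(r1$mirna, r2$mirna)
  expect_equal(r1$target, r2$target)
  expect_equal(r1$energy, r2$energy)
  expect_equal(r1$fold$profile, r2$fold$profile)
})

test_that("pair-counter totals are conserved against the record counts", {
  fix <- generate_fixture(fixture_spec(n_records = 50, seed = 37))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  res <- finalize_analysis(add_records(
    hyb_analysis(c("type", "mirna"), count_mode = "count_total"), recs))
  expect_equal(sum(res$type$pairs$count), sum(fix$truth$count))
  expect_equal(sum(res$mirna$placement$count), sum(fix$truth$count))
})

test_that("the accumulator profile equals the brute-force dot-bracket oracle", {
  fix <- generate_fixture(fixture_spec(n_records = 60, seed = 41))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  recs <- merge_hyb_fold(recs, fix$vienna, merge_policy("static"))$records
  res <- finalize_analysis(add_records(
    hyb_analysis("fold", count_mode = "count_total"), recs))
  oracle_rec <- brute_force_profile(recs, "record")
  oracle_wt <- brute_force_profile(recs, "count_total")
  expect_equal(res$fold$profile$bound_record, oracle_rec$bound)
  expect_equal(res$fold$profile$total_record, oracle_rec$total)
  expect_equal(res$fold$profile$bound_weighted, oracle_wt$bound)
  expect_equal(res$fold$profile$total_weighted, oracle_wt$total)
})

test_that("TSV output writes one file per analysis with stable contents", {
  fix <- generate_fixture(fixture_spec(n_records = 30, seed = 43))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  recs <- merge_hyb_fold(recs, fix$vienna, merge_policy("static"))$records
  res <- finalize_analysis(add_records(hyb_analysis(), recs))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_analysis_tsv(res, d1, "run")
  f2 <- write_analysis_tsv(res, d2, "run")
  expect_setequal(basename(f1),
                  c("run.type.tsv", "run.mirna.tsv", "run.target.tsv",
                    "run.target_summary.tsv", "run.energy.tsv",
                    "run.fold_energy.tsv", "run.fold_profile.tsv"))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("plots are written for populated results and skipped when empty", {
  fix <- generate_fixture(fixture_spec(n_records = 30, seed = 47))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  recs <- merge_hyb_fold(recs, fix$vienna, merge_policy("static"))$records
  res <- finalize_analysis(add_records(hyb_analysis(), recs))
  d <- withr::local_tempdir()
  for (w in c("type", "mirna", "target", "energy", "fold_profile")) {
    p <- file.path(d, paste0(w, ".png"))
    plot_analysis(res, w, p)
    expect_true(file.exists(p))
    expect_gt(file.size(p), 0)
  }
  empty <- finalize_analysis(hyb_analysis())
  p0 <- file.path(d, "empty.png")
  expect_warning(plot_analysis(empty, "type", p0), "empty")
  expect_false(file.exists(p0))
})
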