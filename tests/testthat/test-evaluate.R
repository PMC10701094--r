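# Segment-type classification methods and annotation flags.

test_that("hyb_split takes the positional identifier field, then aliases", {
  m <- type_method("hyb_split")
  expect_identical(classify_segment("ENSG0_ENST0_GENEA_mRNA", m), "mRNA")
  expect_identical(classify_segment("MIMAT0_mir1_hsa-miR-1_microRNA", m,
                                    alias = type_alias()), "miRNA")
  expect_identical(classify_segment("MIMAT0_mir1_hsa-miR-1_microRNA", m),
                   "microRNA")
  # a name lacking the separator is unresolved, not an error
  expect_true(is.na(classify_segment("noseparator", m)))
  m1 <- type_method("hyb_split", position = "first")
  expect_identical(classify_segment("tRNA_x_y", m1), "tRNA")
  m2 <- type_method("hyb_split", position = 2)
  expect_identical(classify_segment("a_b_c", m2), "b")
  expect_true(is.na(classify_segment("a_b", type_method("hyb_split",
                                                        position = 5))))
})

test_that("string_match applies ordered rules, first match wins", {
  rules <- data.frame(kind = c("suffix", "contains", "prefix"),
                      pattern = c("_tRNA", "rRNA", "hsa-"),
                      type = c("tRNA", "rRNA", "miRNA"),
                      stringsAsFactors = FALSE)
  m <- type_method("string_match", rules = rules)
  # "LSU-rRNA_X": suffix rule misses, contains rule fires
  expect_identical(classify_segment("LSU-rRNA_X", m), "rRNA")
  expect_identical(classify_segment("Gly_tRNA", m), "tRNA")
  # suffix rule outranks contains for names matching both
  expect_identical(classify_segment("rRNA-like_tRNA", m), "tRNA")
  expect_identical(classify_segment("hsa-miR-21", m), "miRNA")
  expect_true(is.na(classify_segment("SNORD1", m)))
  expect_error(type_method("string_match",
                           rules = data.frame(kind = "glob", pattern = "x",
                                              type = "y")), "kind")
})

test_that("id_map is an exact lookup with duplicate keys rejected at load", {
  m <- type_method("id_map", map = c(geneA = "mRNA", mir1 = "miRNA"))
  expect_identical(classify_segment("geneA", m), "mRNA")
  expect_true(is.na(classify_segment("geneB", m)))
  path <- withr::local_tempfile(lines = c("id,type", "geneA,mRNA",
                                          "mir1,miRNA"))
  m2 <- type_method("id_map", map = read_id_map(path))
  expect_identical(classify_segment("mir1", m2), "miRNA")
  dup <- withr::local_tempfile(lines = c("geneA,mRNA", "geneA,tRNA"))
  expect_error(read_id_map(dup), "duplicate")
})

test_that("rule files load with comments ignored and order preserved", {
  path <- withr::local_tempfile(lines = c("# ribosomal first",
                                          "suffix\t_tRNA\ttRNA",
                                          "contains,rRNA,rRNA"))
  rules <- read_match_rules(path)
  expect_identical(rules$kind, c("suffix", "contains"))
  m <- type_method("string_match", rules = rules)
  expect_identical(classify_segment("LSU-rRNA_X", m), "rRNA")
})

test_that("a callable classifier is delegated to", {
  m <- type_method("callable", fun = function(x)
    if (grepl("miR", x)) "miRNA" else NA_character_)
  expect_identical(classify_segment("hsa-miR-1", m), "miRNA")
  expect_true(is.na(classify_segment("GENEA", m)))
})

test_that("classify_segment is pure over repeated generated identifiers", {
  set.seed(12)
  m <- type_method("hyb_split")
  for (i in 1:30) {
    nm <- paste(replicate(sample(1:4, 1),
                          paste(sample(letters, 4), collapse = "")),
                collapse = "_")
    expect_identical(classify_segment(nm, m), classify_segment(nm, m))
  }
})

test_that("evaluate_types writes both flags and honors the unknown policy", {
  rec <- mk_rec()
  out <- evaluate_types(rec, type_method("hyb_split"), type_alias())
  expect_identical(get_flag(out, "seg1_type"), "miRNA")
  expect_identical(get_flag(out, "seg2_type"), "mRNA")
  # idempotent: re-running leaves flags unchanged
  again <- evaluate_types(out, type_method("hyb_split"), type_alias())
  expect_true(records_equal(out, again))
  expect_identical(names(out$flags), names(again$flags))

  bad <- mk_rec(ref1 = "nounderscore")
  out2 <- evaluate_types(bad, type_method("hyb_split"), allow_unknown = TRUE)
  expect_identical(get_flag(out2, "seg1_type"), "unknown")
  expect_error(evaluate_types(bad, type_method("hyb_split"),
                              allow_unknown = FALSE), "nounderscore")
})

test_that("evaluate_mirna composes the full truth table after typing", {
  combos <- list(c("miRNA", "mRNA", "5p"), c("lncRNA", "miRNA", "3p"),
                 c("miRNA", "miRNA", "B"), c("mRNA", "mRNA", "N"))
  for (cb in combos) {
    rec <- mk_rec(flags = c(seg1_type = cb[1], seg2_type = cb[2]))
    expect_identical(get_flag(evaluate_mirna(rec), "miRNA_seg"), cb[3])
  }
  untyped <- mk_rec()
  expect_identical(get_flag(evaluate_mirna(untyped), "miRNA_seg"), "U")
})

test_that("evaluate_records reproduces the generator's truth annotations", {
  fix <- generate_fixture(fixture_spec(n_records = 80, seed = 13))
  recs <- evaluate_records(fix$hyb, type_method("hyb_split"), type_alias())
  for (k in seq_along(recs)) {
    expect_identical(get_flag(recs[[k]], "seg1_type"), fix$truth$seg1_type[k])
    expect_identical(get_flag(recs[[k]], "seg2_type"), fix$truth$seg2_type[k])
    expect_identical(get_flag(recs[[k]], "miRNA_seg"), fix$truth$placement[k])
  }
})
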