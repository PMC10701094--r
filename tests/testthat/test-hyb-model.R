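# Record model: counts, flags, miRNA placement, subsequence extraction.

test_that("get_count honors the explicit counting mode with fallback to 1", {
  rec <- mk_rec(flags = c(count_total = "5"))
  expect_identical(get_count(rec, "count_total"), 5L)
  expect_identical(get_count(rec, "record"), 1L)
  expect_identical(get_count(mk_rec(), "read_count"), 1L)
  expect_identical(get_count(mk_rec(flags = c(read_count = "3")), "read_count"), 3L)
})

test_that("get_count rejects non-positive or non-integer count flags", {
  expect_error(get_count(mk_rec(flags = c(count_total = "0")), "count_total"),
               "positive integer")
  expect_error(get_count(mk_rec(flags = c(count_total = "2.5")), "count_total"),
               "positive integer")
  expect_error(get_count(mk_rec(flags = c(read_count = "x")), "read_count"),
               class = "hyb_error")
})

test_that("set_flag overwrites in place and appends new keys at the end", {
  rec <- mk_rec()
  rec <- set_flag(rec, "seg1_type", "miRNA")
  expect_identical(flag_string(rec), "seg1_type=miRNA")
  rec <- set_flag(rec, "seg2_type", "mRNA")
  rec <- set_flag(rec, "seg1_type", "mRNA")
  expect_identical(names(rec$flags), c("seg1_type", "seg2_type"))
  expect_identical(flag_string(rec), "seg1_type=mRNA;seg2_type=mRNA")
})

test_that("set_flag rejects forbidden characters and enforces the key policy", {
  rec <- mk_rec()
  expect_error(set_flag(rec, "my;key", "x"), class = "hyb_error")
  expect_error(set_flag(rec, "k=v", "x"), class = "hyb_error")
  expect_error(set_flag(rec, "ok", "a;b"), class = "hyb_error")
  expect_error(set_flag(rec, "custom_key", "x", allow_undefined = FALSE),
               "recognized")
  expect_silent(set_flag(rec, "custom_key", "x", allow_undefined = TRUE))
  expect_silent(set_flag(rec, "miRNA_seg", "5p", allow_undefined = FALSE))
})

test_that("miRNA placement follows the exhaustive five-case truth table", {
  cases <- list(
    list(t1 = "miRNA", t2 = "mRNA", code = "5p"),
    list(t1 = "microRNA", t2 = "mRNA", code = "5p"),
    list(t1 = "lncRNA", t2 = "miRNA", code = "3p"),
    list(t1 = "miRNA", t2 = "microRNA", code = "B"),
    list(t1 = "mRNA", t2 = "mRNA", code = "N"),
    list(t1 = NA, t2 = "mRNA", code = "U"),
    list(t1 = "miRNA", t2 = NA, code = "U"),
    list(t1 = NA, t2 = NA, code = "U"))
  for (cs in cases) {
    rec <- mk_rec()
    if (!is.na(cs$t1)) rec <- set_flag(rec, "seg1_type", cs$t1)
    if (!is.na(cs$t2)) rec <- set_flag(rec, "seg2_type", cs$t2)
    rec <- mirna_segment(rec)
    expect_identical(get_flag(rec, "miRNA_seg"), cs$code)
    expect_identical(mirna_placement(rec), cs$code)
  }
})

test_that("miRNA type matching is by set membership, case-sensitive", {
  rec <- mk_rec()
  rec <- set_flag(rec, "seg1_type", "MIRNA")
  rec <- set_flag(rec, "seg2_type", "mRNA")
  expect_identical(mirna_placement(rec), "N")
  expect_identical(mirna_placement(rec, mirna_types = "MIRNA"), "5p")
})

test_that("extract_subsequences returns (miRNA, target) by placement", {
  rec <- mk_rec(seq = "AAACCCGGGTTT", s1 = c(1, 6), s2 = c(7, 12))
  rec5 <- set_flag(rec, "miRNA_seg", "5p")
  expect_identical(extract_subsequences(rec5),
                   c(mirna = "AAACCC", target = "GGGTTT"))
  rec3 <- set_flag(rec, "miRNA_seg", "3p")
  expect_identical(extract_subsequences(rec3),
                   c(mirna = "GGGTTT", target = "AAACCC"))
  recN <- set_flag(rec, "miRNA_seg", "N")
  expect_error(extract_subsequences(recN), "5p or 3p")
  expect_error(extract_subsequences(rec), "5p or 3p")
})

test_that("segment subsequences with the gap filled reproduce a seq substring", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(24:40, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    e1 <- sample(8:(L %/% 2), 1)
    s2 <- sample((e1 + 1):(L - 5), 1)
    rec <- mk_rec(seq = seq, s1 = c(1, e1), s2 = c(s2, L))
    rec <- set_flag(rec, "miRNA_seg", "5p")
    sub <- extract_subsequences(rec)
    gap <- if (s2 > e1 + 1) substr(seq, e1 + 1, s2 - 1) else ""
    expect_identical(paste0(sub[["mirna"]], gap, sub[["target"]]),
                     substr(seq, 1, L))
  }
})

test_that("records_equal ignores flag order but not field values", {
  a <- mk_rec(flags = c(seg1_type = "miRNA", seg2_type = "mRNA"))
  b <- mk_rec(flags = c(seg2_type = "mRNA", seg1_type = "miRNA"))
  expect_true(records_equal(a, a))
  expect_true(records_equal(a, b))
  d <- mk_rec(s2 = c(7, 11), flags = c(seg1_type = "miRNA", seg2_type = "mRNA"))
  expect_false(records_equal(a, d))
  expect_false(records_equal(a, mk_rec(flags = c(seg1_type = "miRNA"))))
  expect_false(records_equal(a, set_flag(a, "seg1_type", "mRNA")))
})

test_that("flag serialize-then-parse is the identity", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample.int(6, 1)
    keys <- paste0("k", sample.int(50, n))
    vals <- replicate(n, paste(sample(c(letters, 0:9, ".", "-"),
                                      sample.int(8, 1), replace = TRUE),
                               collapse = ""))
    rec <- mk_rec()
    for (j in seq_len(n)) rec <- set_flag(rec, keys[j], vals[j])
    expect_identical(parse_flag_string(flag_string(rec)), rec$flags)
  }
  # optional trailing semicolon accepted on read
  expect_identical(parse_flag_string("a=1;b=2;"),
                   parse_flag_string("a=1;b=2"))
})

test_that("record constructor enforces its invariants", {
  expect_error(mk_rec(id = "has space"), class = "hyb_error")
  expect_error(mk_rec(seq = "ACGTX"), class = "hyb_error")
  expect_error(mk_rec(s2 = c(7, 13)), "span-exceeds-seq")
  expect_error(seg_info("x", 5, 2), "coordinate-order")
  expect_error(seg_info("", 1, 2), class = "hyb_error")
})
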