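mk_aln <- function(rows, groups) {
  ss <- seq_set(sprintf("s%02d", seq_along(rows)), rows, aligned = TRUE)
  grouped_alignment(ss, stats::setNames(groups, ss$id), unique(groups))
}

test_that("group logos report frequencies, gap fractions and IC in bits", {
  a <- mk_aln(c("AAD", "AAD", "CCD", "-GD"), c("g1", "g1", "g1", "g1"))
  logo <- build_group_logo(a, "g1", segment_spec(list(c(1, 3))))
  # column 1: A,A,C,- -> A 2/3, C 1/3, gap fraction 1/4
  expect_equal(unname(logo$freq["A", 1]), 2 / 3)
  expect_equal(unname(logo$freq["C", 1]), 1 / 3)
  expect_equal(unname(logo$gap_fraction[1]), 1 / 4)

  single <- mk_aln(c("DKE"), "solo")
  ls <- build_group_logo(single, "solo", segment_spec(list(c(1, 3))))
  expect_equal(unname(ls$freq["D", 1]), 1)
  expect_equal(unname(ls$ic[1]), log2(20))

  unif <- mk_aln(AA20, rep("u", 20))
  lu <- build_group_logo(unif, "u", segment_spec(list(c(1, 1))))
  expect_equal(unname(lu$ic[1]), 0)

  allgap <- mk_aln(c("-A", "-A"), c("g", "g"))
  lg <- build_group_logo(allgap, "g", segment_spec(list(c(1, 2))))
  expect_true(lg$all_gap[1])
  expect_true(is.na(lg$ic[1]))
})

test_that("pattern assembly serializes classes, wildcards and respects min_freq", {
  a <- mk_aln(c("DDAAG", "DNAAG", "DDAAG"), rep("g", 3))
  spec <- segment_spec(list(c(1, 2), c(5, 5)), gap_ranges = list(c(2, 5)))
  logo <- build_group_logo(a, "g", spec)
  pat <- assemble_pattern(logo, spec)
  expect_equal(pat$text, "D-[DN]-x(2,5)-G")
  # parse(assemble) reproduces the element list
  expect_equal(parse_pattern(pat$text)$elements, pat$elements)

  a2 <- mk_aln(c("A", "A", "A", "C", "C"), rep("g", 5))
  logo2 <- build_group_logo(a2, "g", segment_spec(list(c(1, 1))))
  pat2 <- assemble_pattern(logo2, min_freq = 0.5)
  expect_equal(pat2$text, "A")

  expect_error(assemble_pattern(
    build_group_logo(mk_aln(c("-", "-"), c("g", "g")),
                     "g", segment_spec(list(c(1, 1))))),
    "column 1")
})

test_that("pattern text parsing round-trips and rejects junk", {
  for (tx in c("D", "[DN]", "x", "x(3)", "x(2,5)", "D-[ACD]-x(0,2)-W")) {
    expect_equal(parse_pattern(tx)$text, tx)
  }
  expect_error(parse_pattern("D-[D"), "parse")
  expect_error(parse_pattern("x(5,2)"), "min > max")
  expect_error(prosite_pattern(list(list(type = "class",
                                         residues = character(0)))),
               "empty")
})

test_that("scanner reports all starts with leftmost-shortest expansion", {
  allaa <- prosite_pattern(list(list(type = "class", residues = AA20),
                                list(type = "class", residues = AA20)))
  h <- scan_pattern(allaa, c(q = "ACDEF"))
  expect_equal(h$start, 1:4)

  expect_equal(nrow(scan_pattern("D-x(0,3)-E", c(e = ""))), 0L)

  # leftmost-shortest: with D-x(0,2)-E on "DAEAE" the x takes 1, not 3
  h2 <- scan_pattern("D-x(0,2)-E", c(s = "DAEAE"))
  expect_equal(h2$end[h2$start == 1], 3L)

  # segment spans cover the class runs around the wildcard
  h3 <- scan_pattern("D-D-x(1,2)-E", c(s = "KDDAEK"))
  expect_equal(h3$segments[[1]][1, ], c(2L, 3L))
  expect_equal(h3$segments[[1]][2, ], c(5L, 5L))
})

test_that("scanner agrees with the regex-translation oracle on random inputs", {
  set.seed(42)
  seqs <- stats::setNames(
    vapply(1:50, function(i) random_protein(sample(20:60, 1),
                                            alphabet = AA20[1:8]),
           character(1)),
    sprintf("r%02d", 1:50))
  for (k in 1:6) {
    pat <- random_pattern(alphabet = AA20[1:8])
    mine <- scan_pattern(pat, seqs)
    oracle <- regex_scan(pat, seqs)
    expect_equal(mine[, c("id", "start", "end")],
                 oracle[, c("id", "start", "end")],
                 ignore_attr = TRUE, info = pat$text)
  }
})

test_that("widening a class never removes hits", {
  set.seed(10)
  seqs <- stats::setNames(
    vapply(1:30, function(i) random_protein(40, alphabet = AA20[1:6]),
           character(1)), sprintf("w%02d", 1:30))
  pat <- prosite_pattern(list(
    list(type = "class", residues = c("A", "C")),
    list(type = "x", min = 1, max = 3),
    list(type = "class", residues = "D")))
  wide <- prosite_pattern(list(
    list(type = "class", residues = c("A", "C", "E", "F")),
    list(type = "x", min = 1, max = 3),
    list(type = "class", residues = c("D", "G"))))
  h1 <- scan_pattern(pat, seqs)
  h2 <- scan_pattern(wide, seqs)
  k1 <- paste(h1$id, h1$start)
  k2 <- paste(h2$id, h2$start)
  expect_true(all(k1 %in% k2))
})

test_that("taxonomic profiles tally hits and specificity", {
  hits <- data.frame(id = c("a1", "a2", "b1"), start = 1L, end = 2L)
  labs <- c(a1 = "gA", a2 = "gA", b1 = "gB")
  tp <- profile_hits(hits, labs, target_group = "gA")
  expect_equal(tp$total, 3L)
  expect_equal(sum(tp$counts$hits), tp$total)
  expect_equal(tp$specificity, 2 / 3)
  tp1 <- profile_hits(hits[hits$id != "b1", ], labs, target_group = "gA")
  expect_equal(tp1$specificity, 1.0)
  empty <- profile_hits(hits[0, ], labs, target_group = "gA")
  expect_equal(empty$total, 0L)
  expect_true(is.na(empty$specificity))
})

test_that("refinement reaches a fixed point and keeps seed members", {
  models <- demo_segment_models(c("gA", "gB"))
  db <- generate_scan_db(10, models, decoy_count = 5, seed = 17)
  pat <- model_pattern(models$gA)
  ref <- refine_pattern(pat, db$seqs, rounds = 4)
  expect_equal(ref$status, "fixed_point")
  # refined pattern still hits every in-group member
  hits <- scan_pattern(ref$pattern, db$seqs)
  members <- db$truth$id[db$truth$group == "gA"]
  expect_true(all(members %in% hits$id))
  # determinism
  ref2 <- refine_pattern(pat, db$seqs, rounds = 4)
  expect_identical(ref$pattern$text, ref2$pattern$text)
  # zero hits warns and keeps the pattern
  nohit <- prosite_pattern(list(list(type = "class", residues = "W"),
                                list(type = "class", residues = "W"),
                                list(type = "class", residues = "W")))
  db_small <- seq_set("z", "ACDEACDE")
  expect_warning(r0 <- refine_pattern(nohit, db_small, rounds = 2), "no hits")
  expect_equal(r0$status, "no_hits")
  expect_equal(r0$pattern$text, nohit$text)
})
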