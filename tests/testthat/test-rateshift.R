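mk2 <- function(rows1, rows2) {
  rows <- c(rows1, rows2)
  ss <- seq_set(sprintf("s%02d", seq_along(rows)), rows, aligned = TRUE)
  grouped_alignment(ss, stats::setNames(
    rep(c("g1", "g2"), c(length(rows1), length(rows2))), ss$id),
    c("g1", "g2"))
}

test_that("conservation profile matches the per-column tally oracle", {
  a <- mk2(c("DA", "DC", "DA"), c("RA", "RC", "RG"))
  prof <- conservation_profile(a)
  p <- prof[prof$column == 1 & prof$group == "g1", ]
  expect_equal(p$modal, "D"); expect_equal(p$freq, 1.0)
  # alphabetical tie-break on (A, C)
  tie <- mk2(c("A", "C"), c("D", "D"))
  pt <- conservation_profile(tie)
  expect_equal(pt$modal[pt$group == "g1"], "A")
  expect_equal(pt$freq[pt$group == "g1"], 0.5)
  expect_error(conservation_profile(a, groups = "nope"), "unknown group")

  set.seed(3)
  m <- matrix(sample(c(AA20, "-"), 12 * 40, TRUE), 12, 40)
  ss <- seq_set(sprintf("r%02d", 1:12), apply(m, 1, paste, collapse = ""),
                aligned = TRUE)
  ga <- grouped_alignment(ss, stats::setNames(rep(c("g1", "g2"), each = 6),
                                              ss$id), c("g1", "g2"))
  prof <- conservation_profile(ga)
  for (j in sample(40, 8)) {
    for (g in c("g1", "g2")) {
      col <- m[ga$labels == g, j]
      usable <- col[col %in% AA20]
      row <- prof[prof$column == j & prof$group == g, ]
      if (length(usable)) {
        tab <- sort(table(usable), decreasing = TRUE)
        best <- sort(names(tab)[tab == max(tab)])[1]
        expect_equal(row$modal, best)
        expect_equal(row$freq, max(tab) / length(usable))
      } else {
        expect_true(is.na(row$modal))
      }
      expect_equal(row$gap_fraction, mean(col == "-"))
    }
  }
})

test_that("site classification follows the type I/II definitions", {
  # conserved D vs conserved R: radical (Grantham 96) -> type II
  expect_gte(grantham("D", "R"), 60)
  a <- mk2(rep("D", 5), rep("R", 5))
  expect_equal(classify_site(a, 1)$type, "II")
  # conserved vs variable -> type I
  b <- mk2(rep("A", 8), c("A", "A", "C", "C", "D", "D", "E", "E"))
  expect_equal(classify_site(b, 1)$type, "I")
  # both conserved, same residue -> none
  expect_equal(classify_site(mk2(rep("A", 5), rep("A", 5)), 1)$type, "none")
  # both conserved, differing but similar residues (D/E, Grantham 45) -> I/II
  expect_lt(grantham("D", "E"), 60)
  expect_equal(classify_site(mk2(rep("D", 5), rep("E", 5)), 1)$type, "I_II")
  # one conserved, other intermediate with differing modal -> I/II
  d <- mk2(rep("D", 8), c("R", "R", "R", "R", "R", "R", "A", "C"))
  expect_equal(classify_site(d, 1)$type, "I_II")
  # uncallable: too gappy
  e <- mk2(c("-", "-", "-", "D"), rep("D", 4))
  cs <- classify_site(e, 1)
  expect_equal(cs$type, "none")
  expect_equal(cs$reason, "uncallable")
  # symmetric in group order up to relabeling
  expect_equal(classify_site(a, 1, groups = c("g2", "g1"))$type, "II")
  expect_equal(classify_site(b, 1, groups = c("g2", "g1"))$type, "I")
})

test_that("permutation p-values behave at degenerate and planted columns", {
  mono <- mk2(rep("A", 6), rep("A", 6))
  expect_equal(permutation_test(mono, 1, B = 99)$p, 1.0)
  # p never below 1/(B+1)
  pl <- mk2(rep("D", 10), rep("R", 10))
  pt <- permutation_test(pl, 1, B = 99, seed = 4)
  expect_gte(pt$p, 1 / 100)
  expect_lte(pt$p, 0.05)
  expect_equal(pt$D, 2)
  # planted type II columns are significant across seeds
  for (sd in 1:10) {
    sp <- synthetic_spec(c("g1", "g2"), sizes = 20, length = 10,
      planted_sites = list(plant_typeII(5, c(g1 = "D", g2 = "R"))),
      seed = sd)
    g <- generate_msa(sp)
    expect_lte(permutation_test(g$aln, 5, B = 999, seed = sd)$p, 0.01)
  }
})

test_that("null columns give super-uniform permutation p-values", {
  # 200 null columns: rejection at 0.05 stays within 0.05 + 3*SE
  ps <- numeric(0)
  for (sd in 1:2) {
    sp <- synthetic_spec(c("g1", "g2"), sizes = 15, length = 100, seed = sd)
    g <- generate_msa(sp)
    calls <- rate_shift_calls(g$aln, B = 199, seed = sd)
    ps <- c(ps, calls$p[calls$callable])
  }
  frac <- mean(ps <= 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("fixation stages trace the ordered succession", {
  rows <- c("D", "D",  # G1
            "D", "D",  # G2
            "D", "D")  # G3
  ss <- seq_set(sprintf("s%d", 1:6), rows, aligned = TRUE)
  ga <- grouped_alignment(ss, stats::setNames(
    rep(c("G1", "G2", "G3"), each = 2), ss$id), c("G1", "G2", "G3"))
  f <- fixation_stage(ga, 1)
  expect_equal(f$stage, "G1")  # present since the outgroup
  expect_equal(f$residue, "D")

  rows2 <- c("A", "C", "D", "D", "D", "D")
  ss2 <- seq_set(sprintf("s%d", 1:6), rows2, aligned = TRUE)
  ga2 <- grouped_alignment(ss2, stats::setNames(
    rep(c("G1", "G2", "G3"), each = 2), ss2$id), c("G1", "G2", "G3"))
  expect_equal(fixation_stage(ga2, 1)$stage, "G2")

  rows3 <- c("A", "C", "D", "D", "E", "E")
  ss3 <- seq_set(sprintf("s%d", 1:6), rows3, aligned = TRUE)
  ga3 <- grouped_alignment(ss3, stats::setNames(
    rep(c("G1", "G2", "G3"), each = 2), ss3$id), c("G1", "G2", "G3"))
  expect_equal(fixation_stage(ga3, 1)$stage, "G3")

  # raising c_hi never moves a stage earlier
  sp <- synthetic_spec(paste0("G", 1:4), sizes = 6, length = 30,
    planted_sites = lapply(1:8, function(i)
      plant_conserved(i * 3, paste0("G", (i %% 4) + 1), "K")),
    gap_rate = 0.03, seed = 12)
  g <- generate_msa(sp)
  ord <- c(g$aln$group_order, "unfixed")
  for (j in g$truth$sites$column) {
    lo <- fixation_stage(g$aln, j, c_hi = 0.7)$stage
    hi <- fixation_stage(g$aln, j, c_hi = 0.95)$stage
    expect_gte(match(hi, ord), match(lo, ord))
  }
})

test_that("planted fixation stages are recovered exactly", {
  sp <- synthetic_spec(paste0("G", 1:5), sizes = 8, length = 60,
    planted_sites = lapply(1:15, function(i)
      plant_conserved(i * 4 - 2, paste0("G", (i %% 5) + 1), AA20[i])),
    gap_rate = 0.05, seed = 77)
  g <- generate_msa(sp)
  sdf <- fixation_stages(g$aln, columns = g$truth$sites$column)
  expect_equal(sdf$stage, g$truth$sites$stage)
})

test_that("coevolution collections partition by stage and spatial component", {
  calls <- data.frame(column = c(10, 20, 30, 40),
                      type = c("II", "II", "I", "none"),
                      D = 2, p = 0.001, q = c(0.01, 0.01, 0.01, 0.8),
                      callable = TRUE)
  stages <- data.frame(column = c(10, 20, 30, 40),
                       stage = c("MB", "MB", "MA", "MA"),
                       residue = "D")
  coll <- collect_coevolved(calls, stages)
  expect_equal(nrow(coll), 2L)  # one per stage; column 40 not significant
  expect_setequal(coll$stage, c("MB", "MA"))

  # a network that splits stage MB's two sites
  net <- list(nodes = c(10, 20), edges = data.frame(a = numeric(0),
                                                    b = numeric(0),
                                                    dist = numeric(0)))
  coll2 <- collect_coevolved(calls, stages, network = net)
  expect_equal(sum(coll2$stage == "MB"), 2L)
  # fully connected -> single collection again
  net2 <- list(nodes = c(10, 20),
               edges = data.frame(a = 10, b = 20, dist = 5))
  coll3 <- collect_coevolved(calls, stages, network = net2)
  expect_equal(sum(coll3$stage == "MB"), 1L)
})

test_that("planted spatial clusters split one stage into two collections", {
  st <- generate_structures(c(3, 3), seed = 21)
  sites <- unlist(st$truth$clusters)
  net <- neighbor_network(st$A, NULL, sites, cutoff = 10)
  calls <- data.frame(column = sites, type = "II", D = 2, p = 0.001,
                      q = 0.001, callable = TRUE)
  stages <- data.frame(column = sites, stage = "MB", residue = "D")
  coll <- collect_coevolved(calls, stages, network = net)
  expect_equal(nrow(coll), 2L)
  expect_setequal(lapply(coll$columns, as.numeric),
                  lapply(st$truth$clusters, as.numeric))
})
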