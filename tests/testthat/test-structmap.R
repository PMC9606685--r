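test_that("PDB CA round-trip preserves order and coordinates to 3 decimals", {
  st <- generate_structures(c(3), seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ca(st$A, f)
  back <- read_pdb_ca(f)
  expect_equal(back$resno, st$A$resno)
  expect_equal(back$xyz, st$A$xyz, tolerance = 1e-3, ignore_attr = TRUE)

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 3.8, 7.6), c(0, 0, 0), c(0, 0, 0)),
    "END"), f3)
  m <- read_pdb_ca(f3)
  expect_equal(length(m$resno), 3L)
  expect_equal(m$xyz[, 1], c(0, 3.8, 7.6), ignore_attr = TRUE)
  expect_equal(m$resid, rep("A", 3))

  fh <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 MN    MN A 501      10.000  10.000  10.000  1.00  0.00          MN",
    "END"), fh)
  expect_error(read_pdb_ca(fh), "no CA atoms")
})

test_that("column-residue maps walk gapped rows correctly", {
  m <- map_columns("ACDE", "ACDE")
  expect_equal(unname(m$map), 1:4)
  expect_equal(names(m$map), as.character(1:4))

  m2 <- map_columns("A-CDE", "AKCDE")
  expect_false("2" %in% names(m2$map))
  expect_equal(unname(m2$map[c("1", "3", "5")]), c(1, 3, 5))

  # mismatched letters are reported, not dropped
  m3 <- map_columns("ACDE", "ACKE")
  expect_equal(m3$mismatches$column, 3)

  # random gapped pair vs a per-position coordinate walk
  set.seed(14)
  for (rep in 1:10) {
    L <- 40
    q <- sample(c(AA20, "-"), L, TRUE, prob = c(rep(0.045, 20), 0.1))
    s <- sample(c(AA20, "-"), L, TRUE, prob = c(rep(0.045, 20), 0.1))
    mm <- map_columns(paste(q, collapse = ""), paste(s, collapse = ""))
    ridx <- 0
    for (k in seq_len(L)) {
      if (s[k] != "-") ridx <- ridx + 1
      if (q[k] != "-" && s[k] != "-") {
        expect_equal(unname(mm$map[as.character(k)]), ridx)
      } else {
        expect_false(as.character(k) %in% names(mm$map))
      }
    }
  }
})

test_that("neighbor networks edge by CA distance and respect rigid motion", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0))
  mod <- structure_model("m", 1:3, c("A", "A", "A"), xyz)
  net <- neighbor_network(mod, NULL, sites = 1:3, cutoff = 10)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(c(net$edges$a, net$edges$b), c(1, 2))
  expect_equal(net$edges$dist, 5)
  net0 <- neighbor_network(mod, NULL, sites = 1:3, cutoff = 0)
  expect_equal(nrow(net0$edges), 0L)

  # unmapped sites are excluded and listed
  cmap <- stats::setNames(c(1L, 2L), c("10", "20"))
  netp <- neighbor_network(mod, cmap, sites = c(10, 20, 30), cutoff = 10)
  expect_equal(netp$unmapped, 30)
  expect_equal(netp$nodes, c(10, 20))

  # invariance under global rigid motion
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  modR <- structure_model("mr", 1:3, c("A", "A", "A"),
                          xyz %*% t(R) + matrix(rep(c(1, 2, 3), each = 3), 3))
  netR <- neighbor_network(modR, NULL, sites = 1:3, cutoff = 10)
  expect_equal(netR$edges$a, net$edges$a)
  expect_equal(netR$edges$dist, net$edges$dist, tolerance = 1e-10)
})

test_that("planted clusters are recovered as connected components", {
  st <- generate_structures(c(4, 4, 3), seed = 31)
  sites <- unlist(st$truth$clusters)
  net <- neighbor_network(st$A, NULL, sites, cutoff = 10)
  comps <- network_components(net)
  expect_equal(length(comps), 3L)
  expect_setequal(lapply(comps, as.numeric),
                  lapply(st$truth$clusters, as.numeric))
})

test_that("conformation comparison flags only sites near the moved helices", {
  st <- generate_structures(c(4, 4), seed = 7)
  sites <- unlist(st$truth$clusters)
  netA <- neighbor_network(st$A, NULL, sites, 10)
  netB <- neighbor_network(st$B, NULL, sites, 10)
  cmp <- compare_conformations(netA, netB)
  expect_true(any(cmp$rearranged))
  # flagged sites are confined to the cluster on the moved helix pair
  moved_cluster <- st$truth$clusters[[2]]
  expect_true(all(cmp$site[cmp$rearranged] %in% moved_cluster))
  # identical structures: nothing flagged
  same <- compare_conformations(netA, netA)
  expect_false(any(same$rearranged))
  # symmetric in (A, B)
  ba <- compare_conformations(netB, netA)
  expect_equal(cmp$jaccard, ba$jaccard)
})

test_that("Kabsch RMSD is zero under rigid motion and optimal vs bio3d", {
  set.seed(9)
  X <- matrix(rnorm(150), 50, 3)
  expect_equal(kabsch_rmsd(X, X), 0)
  th <- 0.6
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  Y <- X %*% t(R) + matrix(rep(c(-4, 2, 9), each = 50), 50)
  expect_lte(kabsch_rmsd(X, Y), 1e-9)
  expect_lte(abs(kabsch_rmsd(X, Y) - kabsch_rmsd(Y, X)), 1e-9)
  expect_error(kabsch_rmsd(X[1:2, ], Y[1:3, ]), "differ")

  # random pairs: agreement with bio3d superposition as independent oracle
  for (i in 1:10) {
    A <- matrix(rnorm(150), 50, 3)
    B <- matrix(rnorm(150), 50, 3)
    fitted <- bio3d::fit.xyz(as.numeric(t(A)), as.numeric(t(B)),
                             fixed.inds = 1:150, mobile.inds = 1:150)
    Bfit <- matrix(fitted, ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((A - Bfit)^2)))
    expect_lt(abs(kabsch_rmsd(A, B) - oracle), 1e-6)
  }
})

test_that("classical MDS is exact on rank-2 Euclidean matrices and orders morphs", {
  # direct check on a planar point configuration
  set.seed(16)
  P <- cbind(rnorm(8), rnorm(8))
  D <- as.matrix(stats::dist(P))
  emb <- mds_embed(D, k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(emb$points)) - D)), 1e-6)
  expect_true(all(emb$eig >= -1e-8))

  # isotropic scaling morphs: pairwise RMSDs are exactly colinear
  st <- generate_structures(c(4), seed = 3)
  X <- sweep(st$A$xyz, 2, colMeans(st$A$xyz))
  ts <- c(0, 0.15, 0.4, 0.65, 1)
  models <- lapply(ts, function(t) (1 + t) * X)
  names(models) <- c("refA", "m1", "m2", "m3", "refB")
  e <- mds_map(models, references = c("refA", "refB"))
  D2 <- as.matrix(stats::dist(e$points[, c("x", "y")]))
  dimnames(D2) <- dimnames(e$D)
  expect_lt(max(abs(D2 - e$D)), 1e-6)
  xs <- e$points$x
  expect_true(!is.unsorted(xs) || !is.unsorted(rev(xs)))
  # model identical to a reference is labeled with it at distance 0
  expect_equal(e$points$nearest_ref[1], "refA")
  expect_equal(e$points$ref_dist[1], 0)
  expect_error(mds_map(models[1:2], "refA"), ">= 3")
})
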