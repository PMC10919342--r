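test_that("alpha diversity matches hand-computed Shannon and Pielou values", {
  m <- rbind(uniform = c(25, 25, 25, 25, 0),
             single = c(100, 0, 0, 0, 0),
             skewed = c(50, 25, 25, 0, 0))
  colnames(m) <- paste0("a", 1:5)
  a <- alpha_diversity(m)
  expect_equal(a$richness, c(4, 1, 3))
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$pielou[1], 1)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$pielou[2]))
  expect_equal(a$shannon[3], 1.5 * log(2))   # (0.5, 0.25, 0.25)
  expect_equal(a$pielou[3], 1.5 * log(2) / log(3))
  expect_error(alpha_diversity(rbind(c(0, 0))), "empty")
})

test_that("Shannon is bounded by log richness with equality only when uniform", {
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(rpois(1 * 30, 5), 1, 30,
                dimnames = list("s", paste0("a", 1:30)))
    if (sum(m) == 0) next
    a <- alpha_diversity(m)
    expect_lte(a$shannon, log(a$richness) + 1e-12)
  }
})

test_that("Faith's PD follows the rooted minimal-subtree convention", {
  tr <- read_newick_tree(text = "((A:1,B:2):0.5,C:3);")
  m <- rbind(ab = c(A = 1, B = 2, C = 0),
             c_only = c(A = 0, B = 0, C = 4),
             all = c(A = 1, B = 1, C = 1))
  p <- faith_pd(m, tr)
  expect_equal(p$faith_pd, c(3.5, 3, 6.5))
  expect_equal(p$richness, c(2, 1, 3))
  m2 <- cbind(m, D = c(1, 0, 0))
  expect_error(faith_pd(m2, tr), "D")
})

test_that("Faith's PD agrees with the brute-force edge-union oracle", {
  set.seed(21)
  for (rep in 1:10) {
    tr <- ape::rtree(20, br = stats::rexp)
    comm <- matrix(0, 20, 20, dimnames = list(paste0("s", 1:20),
                                              tr$tip.label))
    subsets <- vector("list", 20)
    for (i in 1:20) {
      k <- sample(1:20, 1)
      subsets[[i]] <- sample(tr$tip.label, k)
      comm[i, subsets[[i]]] <- 1
    }
    p <- faith_pd(comm, tr)
    oracle <- vapply(subsets, function(s) pd_oracle(tr, s), numeric(1))
    expect_equal(p$faith_pd, oracle, tolerance = 1e-10)
  }
})

test_that("PD scales linearly with branch lengths", {
  set.seed(22)
  tr <- ape::rtree(12, br = stats::rexp)
  comm <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
                 dimnames = list(paste0("s", 1:5), tr$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  p1 <- faith_pd(comm, tr)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3.5
  p2 <- faith_pd(comm, tr2)
  expect_equal(p2$faith_pd, p1$faith_pd * 3.5, tolerance = 1e-10)
})

test_that("proportion of active taxa is the DNA-detected intersection rate", {
  dna <- rbind(s1 = c(a = 1, b = 2, c = 3, d = 4, e = 0),
               s2 = c(a = 1, b = 1, c = 0, d = 0, e = 0),
               s3 = c(a = 0, b = 0, c = 0, d = 0, e = 0))
  rna <- rbind(s1 = c(a = 0, b = 5, c = 0, d = 1, e = 9),
               s2 = c(a = 1, b = 1, c = 0, d = 0, e = 0),
               s3 = c(a = 0, b = 0, c = 0, d = 0, e = 1))
  p <- pair_tables(asv_table(dna, "DNA"), asv_table(rna, "RNA"))
  expect_warning(res <- proportion_active(p), "s3")
  # phantom e is in neither numerator nor denominator
  expect_equal(res$prop_active[1], 0.5)
  expect_equal(res$prop_active[2], 1)
  expect_true(is.na(res$prop_active[3]))
  rna0 <- rna; rna0[] <- 0
  p0 <- pair_tables(asv_table(dna[1:2, ], "DNA"), asv_table(rna0[1:2, ], "RNA"))
  expect_equal(proportion_active(p0)$prop_active, c(0, 0))
})

test_that("Mann-Whitney exact mode reproduces enumeration on all splits of 8 values", {
  vals <- c(3.2, -1, 0.5, 7, 2.2, 9.9, -4, 5)
  for (k in 1:7) {
    splits <- utils::combn(8, k)
    take <- splits[, seq(1, ncol(splits), by = max(1, floor(ncol(splits) / 12))),
                   drop = FALSE]
    for (j in seq_len(ncol(take))) {
      x <- vals[take[, j]]
      y <- vals[-take[, j]]
      expect_equal(mann_whitney(x, y)$p_value, mw_oracle(x, y),
                   tolerance = 1e-12,
                   label = paste("split", k, j))
    }
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney(1, 2)$p_value, 1)
  expect_warning(r <- mann_whitney(c(2, 2), c(2, 2)), "identical")
  expect_equal(r$p_value, 1)
})

test_that("Kruskal-Wallis/Dunn detects separated groups and pins rank arithmetic", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn(v, g)
  expect_lt(res$p_value, 0.05)
  # hand rank arithmetic: mean ranks 2, 5, 8; s2 = N(N+1)/12 = 7.5
  z_ab <- (2 - 5) / sqrt(7.5 * (2 / 3))
  expect_equal(res$posthoc$z[res$posthoc$group1 == "a" &
                             res$posthoc$group2 == "b"], z_ab)
  # disjoint ranges, n = 5 each
  set.seed(31)
  v2 <- c(runif(5, 0, 1), runif(5, 10, 11), runif(5, 20, 21))
  expect_lt(kruskal_dunn(v2, rep(c("a", "b", "c"), each = 5))$p_value, 0.01)
  expect_error(kruskal_dunn(v[1:5], c("a", "a", "b", "b", "c")), "size < 2")
  expect_error(kruskal_dunn(v[1:6], rep(c("a", "b"), 3)), "3 groups")
})

test_that("a single shifted group is flagged only in its own Dunn pairs", {
  set.seed(32)
  v <- c(rnorm(12), rnorm(12), rnorm(12) + 30)
  g <- rep(c("a", "b", "c"), each = 12)
  res <- kruskal_dunn(v, g)
  ph <- res$posthoc
  hit_c <- ph$p[ph$group1 == "c" | ph$group2 == "c"]
  hit_ab <- ph$p[ph$group1 != "c" & ph$group2 != "c"]
  expect_true(all(hit_c < 0.01))
  expect_true(all(hit_ab > 0.01))
})
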