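make_assoc_tables <- function(A, C, classes) {
  list(abund = make_abund(A), comp = make_comp(C, classes))
}

test_that("pairwise associations reproduce a rank-then-Pearson oracle", {
  samples <- paste0("s", 1:6)
  A <- rbind(tax1 = c(1, 4, 2, 6, 5, 3))
  colnames(A) <- samples
  C <- rbind(cmpA = c(2, 3, 1, 6, 5, 4))
  colnames(C) <- samples
  tb <- make_assoc_tables(A, C, "ester")
  res <- pairwise_association(tb$abund, tb$comp)
  expect_equal(res$rho, spearman_oracle(A[1, ], C[1, ]), tolerance = 1e-12)

  # perfect monotone and degenerate cases
  A2 <- rbind(t1 = c(1, 2, 3, 4), t2 = c(2, 2, 2, 2))
  colnames(A2) <- paste0("s", 1:4)
  C2 <- rbind(c1 = c(10, 20, 30, 40), c2 = c(5, 5, 5, 5))
  colnames(C2) <- paste0("s", 1:4)
  tb2 <- make_assoc_tables(A2, C2, c("ester", "acid"))
  r2 <- pairwise_association(tb2$abund, tb2$comp)
  expect_equal(r2$rho[r2$taxon == "t1" & r2$compound == "c1"], 1)
  deg <- r2[r2$compound == "c2" | r2$taxon == "t2", ]
  expect_true(all(deg$degenerate))
  expect_true(all(deg$rho == 0 & deg$p == 1))
})

test_that("fewer than 4 shared samples is fatal", {
  A <- matrix(1:9, 3, 3, dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  C <- matrix(1:3, 1, 3, dimnames = list("c1", paste0("s", 1:3)))
  tb <- make_assoc_tables(A, C, "ester")
  expect_error(pairwise_association(tb$abund, tb$comp), "4 shared samples")
})

test_that("BH adjustment is applied per compound-class family", {
  set.seed(21)
  A <- matrix(runif(8 * 10), 8, 10,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  C <- matrix(runif(6 * 10), 6, 10,
              dimnames = list(paste0("c", 1:6), paste0("s", 1:10)))
  classes <- c("ester", "ester", "acid", "amino_acid", "amino_acid", "amino_acid")
  tb <- make_assoc_tables(A, C, classes)
  res <- pairwise_association(tb$abund, tb$comp)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$q <= 1))
  for (cl in unique(classes)) {
    idx <- res$compound_class == cl
    expect_equal(res$q[idx], bh_oracle(res$p[idx]), tolerance = 1e-12)
    # step-up monotonicity within the family
    o <- order(res$p[idx])
    expect_true(all(diff(res$q[idx][o]) >= -1e-15))
  }
})

test_that("group assignment matches brute-force filtering oracles", {
  set.seed(31)
  n_s <- 12
  A <- matrix(runif(10 * n_s), 10, n_s,
              dimnames = list(sprintf("t%02d", 1:10), paste0("s", 1:n_s)))
  C <- matrix(runif(6 * n_s), 6, n_s,
              dimnames = list(paste0("c", 1:6), paste0("s", 1:n_s)))
  classes <- c("ester", "ester", "organic_acid", "acid", "amino_acid", "amino_acid")
  tb <- make_assoc_tables(A, C, classes)
  res <- pairwise_association(tb$abund, tb$comp)
  # permissive thresholds so the sets are non-trivial on random data
  alpha <- 0.9; rho_min <- 0.1
  ok <- res$rho >= rho_min & res$q < alpha & !res$degenerate
  est_taxa <- unique(res$taxon[ok & res$compound_class == "ester"])
  acid_taxa <- unique(res$taxon[ok & res$compound_class %in% c("acid", "organic_acid")])
  expect_setequal(assign_flavor_group(res, alpha, rho_min),
                  intersect(est_taxa, acid_taxa))
  amino_counts <- table(res$taxon[ok & res$compound_class == "amino_acid"])
  expect_setequal(assign_amino_acid_group(res, alpha, rho_min, min_hits = 2),
                  names(amino_counts)[amino_counts >= 2])
  # explicit small cases
  res2 <- data.frame(
    taxon = c("A", "A", "B"), compound = c("E1", "L1", "E2"),
    compound_class = c("ester", "organic_acid", "ester"),
    rho = c(0.9, 0.8, 0.95), p = c(0.001, 0.002, 0.001),
    q = c(0.001, 0.002, 0.001), n = 10, degenerate = FALSE)
  expect_identical(assign_flavor_group(res2), "A")
  res3 <- res2; res3$compound_class <- c("ester", "ester", "ester")
  expect_error(assign_flavor_group(res3), "acid")
})

test_that("major group uses a strict mean-abundance threshold", {
  m <- rbind(border = c(0.002, 0.000), high = c(0.05, 0.05),
             low = c(0.0001, 0.0001))
  rest <- 1 - colSums(m)
  m <- rbind(m, filler = rest)
  colnames(m) <- c("s1", "s2")
  ab <- make_abund(m)
  mg <- assign_major_group(ab)
  expect_false("border" %in% mg)   # mean exactly 0.001 is excluded
  expect_true(all(c("high", "filler") %in% mg))
  expect_false("low" %in% mg)

  set.seed(5)
  m2 <- matrix(rexp(20 * 6), 20, 6,
               dimnames = list(sprintf("t%02d", 1:20), paste0("s", 1:6)))
  ab2 <- to_relative_abundance(make_abund(m2))
  expect_setequal(assign_major_group(ab2, 0.04),
                  rownames(m2)[rowMeans(ab2$values) > 0.04])
})

test_that("group assignment is invariant to taxon and sample ordering", {
  ds <- generate_dataset(syncom_config(seed = 12, n_bacteria = 8, n_fungi = 4,
                                       n_hubs = 1, n_producers = 2))
  abund <- to_relative_abundance(ds$abundance)
  assoc <- pairwise_association(abund, ds$compounds)
  perm_t <- sample(rownames(abund$values))
  perm_s <- sample(colnames(abund$values))
  ab_p <- abundance_table(abund$values[perm_t, perm_s], abund$kingdom[perm_t])
  cp_p <- compound_table(ds$compounds$values[, perm_s], ds$compounds$compound_class)
  assoc_p <- pairwise_association(ab_p, cp_p)
  expect_setequal(assign_flavor_group(assoc), assign_flavor_group(assoc_p))
  expect_setequal(assign_amino_acid_group(assoc), assign_amino_acid_group(assoc_p))
  expect_setequal(assign_major_group(abund), assign_major_group(ab_p))
})

test_that("distance matrices follow the stated formulas", {
  x <- c(0.5, 0.5, 0); y <- c(0.25, 0.25, 0.5)
  m <- cbind(s1 = x, s2 = y, s3 = x)
  rownames(m) <- paste0("t", 1:3)
  d_bc <- distance_matrix(make_abund(m), "bray_curtis")
  expect_equal(d_bc$values["s1", "s2"], bray_oracle(x, y), tolerance = 1e-12)
  expect_equal(d_bc$values["s1", "s3"], 0)
  d_j <- distance_matrix(make_abund(m), "jaccard")
  expect_equal(d_j$values["s1", "s2"], jaccard_oracle(x, y), tolerance = 1e-12)
  # disjoint supports
  m2 <- cbind(s1 = c(1, 0), s2 = c(0, 1)); rownames(m2) <- c("a", "b")
  ab2 <- to_relative_abundance(make_abund(m2))
  expect_equal(distance_matrix(ab2, "bray_curtis")$values["s1", "s2"], 1)
  expect_equal(distance_matrix(ab2, "jaccard")$values["s1", "s2"], 1)
  # symmetry, zero diagonal, bounds
  expect_true(isSymmetric(d_bc$values, tol = 1e-12))
  expect_true(all(diag(d_bc$values) == 0))
  expect_true(all(d_bc$values >= 0 & d_bc$values <= 1))
})

test_that("mantel test recovers identity and respects the exhaustive oracle", {
  set.seed(17)
  n <- 5
  m1 <- as.matrix(dist(matrix(runif(n * 2), n)))
  m2 <- as.matrix(dist(matrix(runif(n * 2), n)))
  colnames(m1) <- rownames(m1) <- colnames(m2) <- rownames(m2) <- paste0("s", 1:n)
  d1 <- make_dm(m1); d2 <- make_dm(m2)
  expect_equal(mantel_test(d1, d1, exhaustive = TRUE)$r, 1)
  # pearson invariance under positive affine transforms
  d3 <- make_dm(2.5 * m1 + 0.3); diag(d3$values) <- 0
  expect_equal(mantel_test(d1, d3, method = "pearson", exhaustive = TRUE)$r, 1,
               tolerance = 1e-12)
  # exhaustive p equals an independent enumeration oracle
  got <- mantel_test(d1, d2, method = "spearman", exhaustive = TRUE)
  v1 <- rank(m1[upper.tri(m1)])
  r_of <- function(perm) {
    mp <- m2[perm, perm]
    cor(v1, rank(mp[upper.tri(mp)]))
  }
  # note: ranks of d2 permute with the labels, so rank-after-permute is valid
  rs <- vapply(perms_oracle(n), function(p) r_of(p), numeric(1))
  expect_equal(got$p, mean(rs >= got$r - 1e-12))
  expect_equal(got$permutations, factorial(n))
  # agreement with vegan on the statistic
  vg <- suppressMessages(vegan::mantel(as.dist(m1), as.dist(m2),
                                       method = "spearman", permutations = 0))
  expect_equal(got$r, unname(vg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(d1, make_dm(m2[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)])),
               "label")
})

test_that("mantel p-values are near-uniform under the null", {
  set.seed(23)
  n <- 6
  ps <- replicate(200, {
    m1 <- as.matrix(dist(matrix(runif(n * 3), n)))
    m2 <- as.matrix(dist(matrix(runif(n * 3), n)))
    colnames(m1) <- rownames(m1) <- colnames(m2) <- rownames(m2) <- paste0("s", 1:n)
    mantel_test(make_dm(m1), make_dm(m2), permutations = 99,
                seed = sample.int(1e6, 1))$p
  })
  rate <- mean(ps <= 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), bound + 1e-12)
})

test_that("anosim matches closed forms and a mean-rank oracle", {
  # perfect separation: both within-distances below all between-distances
  m <- matrix(c(0, 1, 5, 6,
                1, 0, 6, 5,
                5, 6, 0, 1,
                6, 5, 1, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  a <- anosim_test(make_dm(m), c("A", "A", "B", "B"), exhaustive = TRUE)
  expect_equal(a$R, 1)           # (4.5 - 1.5) / 3
  # exhaustive p oracle: proportion of label permutations with R >= 1
  ranks <- matrix(0, 4, 4); ranks[upper.tri(ranks)] <- rank(m[upper.tri(m)])
  ranks <- ranks + t(ranks)
  R_of <- function(lab) {
    same <- outer(lab, lab, "=="); ut <- upper.tri(m)
    (mean(ranks[ut & !same]) - mean(ranks[ut & same])) / (4 * 3 / 4)
  }
  labs <- c("A", "A", "B", "B")
  Rs <- vapply(perms_oracle(4), function(p) R_of(labs[p]), numeric(1))
  expect_equal(a$p, mean(Rs >= 1 - 1e-12))
  # centering: permutation distribution of R has mean ~ 0
  expect_lt(abs(mean(Rs)), 1e-10)

  # 6-sample random matrix vs independent oracle and vegan
  set.seed(41)
  m6 <- as.matrix(dist(matrix(runif(18), 6)))
  colnames(m6) <- rownames(m6) <- paste0("s", 1:6)
  lab6 <- c("A", "A", "A", "B", "B", "B")
  got <- anosim_test(make_dm(m6), lab6, permutations = 99, seed = 2)
  r6 <- matrix(0, 6, 6); r6[upper.tri(r6)] <- rank(m6[upper.tri(m6)])
  r6 <- r6 + t(r6)
  same <- outer(lab6, lab6, "=="); ut <- upper.tri(m6)
  oracle <- (mean(r6[ut & !same]) - mean(r6[ut & same])) / (6 * 5 / 4)
  expect_equal(got$R, oracle, tolerance = 1e-12)
  vg <- suppressMessages(vegan::anosim(as.dist(m6), factor(lab6),
                                       permutations = 0))
  expect_equal(got$R, unname(vg$statistic), tolerance = 1e-12)
  expect_true(got$R >= -1 && got$R <= 1)
  expect_error(anosim_test(make_dm(m6), c("A", rep("B", 5))), "single member")
})

test_that("alpha diversity follows the entropy formulas", {
  m <- cbind(s1 = rep(0.25, 4), s2 = c(1, 0, 0, 0), s3 = c(0.5, 0.3, 0.2, 0))
  rownames(m) <- paste0("t", 1:4)
  ad <- alpha_diversity(make_abund(m))
  expect_equal(ad$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(ad$pielou[1], 1, tolerance = 1e-12)
  expect_equal(ad$observed, c(4L, 1L, 3L))
  expect_equal(ad$shannon[2], 0)
  expect_equal(ad$pielou[2], 0)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(ad$shannon[3], -sum(p * log(p)), tolerance = 1e-12)
  # vegan cross-check
  expect_equal(ad$shannon, unname(vegan::diversity(t(m))), tolerance = 1e-12)
})
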