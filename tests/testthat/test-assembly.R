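saturated_table <- function(n_taxa = 5, n_samples = 6) {
  m <- matrix(1, n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  make_abund(m)
}

test_that("saturated pool gives RC exactly 0 under the half-weight tie rule", {
  rc <- raup_crick(saturated_table(), reps = 99, seed = 1)
  expect_true(all(rc$values == 0))
  ex <- raup_crick_exact(saturated_table())
  expect_true(all(abs(ex$values) < 1e-12))
})

test_that("raup_crick is deterministic, symmetric and bounded", {
  set.seed(81)
  m <- matrix(rbinom(10 * 8, 1, 0.55), 10, 8,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  m[, colSums(m) == 0] <- 1
  ab <- make_abund(m)
  r1 <- raup_crick(ab, reps = 199, seed = 3)
  r2 <- raup_crick(ab, reps = 199, seed = 3)
  expect_identical(r1, r2)
  expect_identical(r1$values, t(r1$values))
  expect_true(all(diag(r1$values) == 0))
  expect_true(all(r1$values >= -1 & r1$values <= 1))
  r3 <- raup_crick(ab, reps = 199, seed = 4)
  expect_false(identical(r1$values, r3$values))
})

test_that("Monte Carlo RC agrees with exhaustive enumeration on a small pool", {
  set.seed(82)
  S <- 8
  m <- replicate(4, {
    v <- numeric(S); v[sample.int(S, sample(3:4, 1))] <- 1; v
  })
  rownames(m) <- paste0("sp", 1:S); colnames(m) <- paste0("s", 1:4)
  ab <- make_abund(m)
  ex <- raup_crick_exact(ab)
  mc <- raup_crick(ab, reps = 9999, seed = 5)
  expect_lt(max(abs(mc$values - ex$values)), 0.05)
})

test_that("a pair sharing all its rare species is flagged strongly deterministic", {
  # 10 species, each in exactly one of 5 samples, except 4 species shared by
  # the first pair: far more sharing than weighted draws expect
  S <- 14
  m <- matrix(0, S, 5, dimnames = list(paste0("sp", 1:S), paste0("s", 1:5)))
  m[1:4, 1] <- 1; m[1:4, 2] <- 1
  m[5:7, 3] <- 1; m[8:10, 4] <- 1; m[11:14, 5] <- 1
  rc <- raup_crick(make_abund(m), reps = 9999, seed = 6)
  expect_lt(rc$values["s1", "s2"], -0.9)
})

test_that("pool frequencies can be supplied for an external species pool", {
  set.seed(83)
  S <- 12
  w <- setNames(rexp(S) + 0.1, paste0("sp", 1:S))
  m <- matrix(0, S, 2, dimnames = list(names(w), c("a", "b")))
  m[sample.int(S, 5, prob = w), 1] <- 1
  m[sample.int(S, 6, prob = w), 2] <- 1
  rc <- raup_crick(make_abund(m), reps = 99, seed = 1, pool_freq = w)
  expect_true(abs(rc$values["a", "b"]) <= 1)
  expect_identical(unname(rc$pool_frequencies), unname(w))
  expect_error(raup_crick(make_abund(m), pool_freq = unname(w)), "named")
})

test_that("null-generated community pairs give RC centred on 0", {
  set.seed(84)
  S <- 25
  w <- setNames(rexp(S) + 0.2, sprintf("sp%02d", 1:S))
  kingdom <- setNames(rep("bacteria", S), names(w))
  rcs <- vapply(1:40, function(i) {
    set.seed(5000 + i)
    m <- matrix(0, S, 2, dimnames = list(names(w), c("a", "b")))
    m[sample.int(S, sample(6:12, 1), prob = w), 1] <- 1
    m[sample.int(S, sample(6:12, 1), prob = w), 2] <- 1
    raup_crick(abundance_table(m, kingdom), reps = 199, seed = i,
               pool_freq = w)$values[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rcs)), 0.15)
})

test_that("NMDS embeds exact planar configurations with near-zero stress", {
  set.seed(85)
  pts <- matrix(runif(10), 5, 2)
  d <- make_dm(as.matrix(dist(pts)))
  fit <- nmds(d, k = 2, restarts = 8, tol = 1e-9, seed = 1)
  expect_lt(fit$stress, 1e-3)
  # ordinal invariance: any monotone transform embeds equally well
  d2 <- d; d2$values <- d$values^1.7
  fit2 <- nmds(d2, k = 2, restarts = 8, tol = 1e-9, seed = 1)
  expect_lt(fit2$stress, 1e-3)
  # coordinates centred at the origin
  expect_true(all(abs(colMeans(fit$coordinates)) < 1e-10))
})

test_that("reported stress matches an isotonic-regression oracle", {
  set.seed(86)
  m <- as.matrix(dist(matrix(runif(18), 6)))
  d <- make_dm(m)
  fit <- nmds(d, k = 2, restarts = 5, seed = 2)
  expect_lt(abs(fit$stress - kruskal_stress(d, fit$coordinates)), 1e-8)
})

test_that("stress does not increase with embedding dimension", {
  set.seed(87)
  m <- matrix(runif(49), 7, 7); m <- (m + t(m)) / 2; diag(m) <- 0
  d <- make_dm(m)
  s2 <- nmds(d, k = 2, restarts = 10, seed = 3)$stress
  s3 <- nmds(d, k = 3, restarts = 10, seed = 3)$stress
  expect_lte(s3, s2 + 1e-6)
})

test_that("RC matrices are mapped monotonically before embedding", {
  set.seed(88)
  m <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:8)))
  m[, colSums(m) == 0] <- 1
  rc <- raup_crick(make_abund(m), reps = 99, seed = 1)
  fit <- nmds(rc, k = 2, restarts = 5, seed = 1)
  expect_true(is.finite(fit$stress))
  expect_equal(dim(fit$coordinates), c(8, 2))
  bad <- rc; bad$values[1, 2] <- bad$values[2, 1] <- NaN
  expect_error(nmds(bad), "non-finite")
})

test_that("assembly summaries equal a direct aggregation oracle", {
  labs <- c("CK_d0_r1", "CK_d0_r2", "CK_d3_r1", "Lp_d0_r1", "Lp_d0_r2")
  v <- matrix(0, 5, 5, dimnames = list(labs, labs))
  v["CK_d0_r1", "CK_d0_r2"] <- -1
  v["CK_d0_r1", "CK_d3_r1"] <- -0.2
  v["CK_d0_r2", "CK_d3_r1"] <- 0.4
  v["Lp_d0_r1", "Lp_d0_r2"] <- 0
  v <- v + t(v)
  rc <- structure(list(values = v, reps = 99, seed = 1), class = "rc_matrix")
  meta <- sample_metadata(data.frame(
    sample_id = labs, group = c("CK", "CK", "CK", "Lp", "Lp"),
    day = c(0, 0, 3, 0, 0), replicate = c(1, 2, 1, 1, 2)))
  s <- assembly_summary(rc, meta)
  ck_all <- s[s$group == "CK" & is.na(s$day), ]
  expect_equal(ck_all$mean_rc, mean(c(-1, -0.2, 0.4)))
  expect_equal(ck_all$frac_deterministic, 1 / 3)
  expect_equal(ck_all$frac_neutral, 2 / 3)
  lp_d0 <- s[s$group == "Lp" & !is.na(s$day), ]
  expect_equal(lp_d0$mean_rc, 0)
  expect_equal(lp_d0$frac_neutral, 1)
  expect_equal(lp_d0$frac_deterministic, 0)
  ck_d0 <- s[s$group == "CK" & s$day %in% 0, ]
  expect_equal(ck_d0$n_pairs, 1)
  expect_equal(ck_d0$mean_rc, -1)
})
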