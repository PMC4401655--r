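test_that("Raup-Crick separates identical from disjoint units", {
  # background units fix near-equal occurrence frequencies over the pool
  bg <- matrix(1L, 4, 200)
  m <- rbind(bg,
             a = c(rep(1L, 10), rep(0L, 190)),
             b = c(rep(1L, 10), rep(0L, 190)),
             c = c(rep(0L, 190), rep(1L, 10)))
  rownames(m) <- c(paste0("bg", 1:4), "a", "b", "c")
  colnames(m) <- paste0("O", 1:200)
  rc <- as.matrix(raup_crick(m, n_null = 999, seed = 1))
  expect_lt(rc["a", "b"], 0.5)
  expect_gt(rc["a", "c"], 0.5)
  # exact hypergeometric oracle for an equal-frequency pool: identical
  # richness-10 units share more than the null essentially always, and the
  # disjoint pair's null-tie mass 0.5 * P(shared = 0) keeps it above 0.5
  p_all_shared <- 1 - stats::phyper(9, 10, 190, 10)
  expect_lt(p_all_shared, 1e-8)
  p_zero <- stats::dhyper(0, 10, 190, 10)
  expect_gt(1 - 0.5 * p_zero, 0.5)
  # bounds, symmetry, zero diagonal
  expect_true(all(rc >= 0 & rc <= 1))
  expect_equal(rc, t(rc))
  expect_true(all(diag(rc) == 0))
  # degenerate inputs
  expect_error(raup_crick(m[1, , drop = FALSE]), "two units")
  m0 <- m; m0["a", ] <- 0L
  expect_error(raup_crick(m0, n_null = 9), "no OTUs")
  expect_error(raup_crick(m, n_null = 9, freq = c(1, rep(0, 199))),
               "exceeds the OTU pool")
})

test_that("Raup-Crick ranks agree with the vegan construction", {
  set.seed(2)
  m <- matrix(rbinom(20 * 60, 1, 0.25), 20, 60,
              dimnames = list(paste0("u", 1:20), paste0("O", 1:60)))
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  ours <- raup_crick(m, n_null = 499, seed = 3)
  set.seed(4)
  theirs <- vegan::raupcrick(m, null = "r1", nsimul = 499, chase = FALSE)
  # same null model and statistic; conventions differ only in tie handling,
  # so the orderings must agree strongly
  expect_gt(cor(as.vector(ours), as.vector(theirs), method = "spearman"),
            0.9)
})

test_that("Mantel statistic and p-value behave at the boundaries", {
  set.seed(5)
  d1 <- rand_dist(8)
  r <- mantel_test(d1, d1, n_perm = 199, seed = 6)
  expect_equal(r$statistic, 1)
  expect_equal(r$p.value, 1 / 200)        # smallest achievable with add-one
  # invariant to label order of the second matrix
  sh <- sample(8)
  d2 <- rand_dist(8)
  r1 <- mantel_test(d1, d2, n_perm = 99, seed = 7)
  r2 <- mantel_test(d1, d2[sh, sh], n_perm = 99, seed = 7)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
  # vegan cross-check of the statistic
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                      permutations = 99)
  expect_equal(r1$statistic, unname(vg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(d1[1:3, 1:3], d1[1:3, 1:3]), "at least 4")
  dc <- matrix(1, 8, 8); diag(dc) <- 0
  dimnames(dc) <- dimnames(d1)
  expect_error(mantel_test(d1, dc), "constant lower triangle")
})

test_that("exhaustive permutations at n = 4 equal full enumeration", {
  set.seed(8)
  d1 <- rand_dist(4)
  d2 <- rand_dist(4)
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  res <- mantel_test(d1, d2, permutations = perms)
  # oracle: enumerate the 24 relabelings directly
  v1 <- d1[lower.tri(d1)]
  r_all <- apply(perms, 1, function(p) {
    cor(v1, d2[p, p][lower.tri(d2)], method = "spearman")
  })
  r_obs <- cor(v1, d2[lower.tri(d2)], method = "spearman")
  expect_equal(res$statistic, r_obs)
  expect_equal(res$p.value, mean(r_all >= r_obs - 1e-12))
  # and the sampled add-one p with many draws approaches the exact p
  res2 <- mantel_test(d1, d2, n_perm = 4999, seed = 9)
  expect_lt(abs(res2$p.value - res$p.value), 0.05)
})

test_that("partial Mantel matches the closed formula and its limits", {
  set.seed(10)
  d1 <- rand_dist(5); d2 <- rand_dist(5); dc <- rand_dist(5)
  pm <- partial_mantel_test(d1, d2, dc, n_perm = 99, seed = 11)
  lt <- lower.tri(d1)
  r12 <- cor(d1[lt], d2[lt], method = "spearman")
  r13 <- cor(d1[lt], dc[lt], method = "spearman")
  r23 <- cor(d2[lt], dc[lt], method = "spearman")
  expect_equal(pm$statistic,
               (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2)))
  expect_error(partial_mantel_test(d1, d1, d1, n_perm = 9),
               "degenerate control")
  # an independent control barely changes the plain Mantel statistic
  set.seed(12)
  e1 <- rand_dist(30); e2 <- e1 + rand_dist(30) * 2; ec <- rand_dist(30)
  plain <- mantel_test(e1, e2, n_perm = 99, seed = 13)$statistic
  part <- partial_mantel_test(e1, e2, ec, n_perm = 99, seed = 13)$statistic
  expect_lt(abs(plain - part), 0.02)
  # vegan cross-check of the partial statistic
  vg <- vegan::mantel.partial(as.dist(e1), as.dist(e2), as.dist(ec),
                              method = "spearman", permutations = 99)
  expect_equal(part, unname(vg$statistic), tolerance = 1e-12)
})

test_that("Moran's I detects alternation and matches hand arithmetic", {
  x <- 0:9
  v <- rep(c(1, -1), 5)
  mi <- morans_i(v, x)
  expect_lt(mi$I, mi$expected)               # negative autocorrelation
  expect_equal(mi$expected, -1 / 9)
  # n = 5 hand-worked case
  v5 <- c(2, 4, 1, 5, 3); x5 <- c(0, 1, 2, 3, 5)
  w <- 1 / abs(outer(x5, x5, "-")); diag(w) <- 0
  z <- v5 - mean(v5)
  byhand <- (5 / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
  mi5 <- morans_i(v5, x5)
  expect_equal(mi5$I, byhand)
  # randomization oracle: permuting the values reproduces the formula's
  # null mean and standard deviation
  set.seed(99)
  Ip <- vapply(1:4000, function(k) {
    vp <- sample(v5); zp <- vp - mean(vp)
    (5 / sum(w)) * sum(w * outer(zp, zp)) / sum(zp^2)
  }, numeric(1))
  expect_lt(abs(mean(Ip) - mi5$expected), 3 * stats::sd(Ip) / sqrt(4000))
  expect_lt(abs(stats::sd(Ip) - mi5$sd), 0.1 * mi5$sd)
  # null-expectation calibration over simulated position-independent values
  set.seed(14)
  n <- 30
  Is <- vapply(1:300, function(k) morans_i(rnorm(n), 0:(n - 1))$I, numeric(1))
  se <- stats::sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 2 * se + 0.01)
  expect_error(morans_i(rep(1, 10), 1:10), "constant")
  expect_error(morans_i(rnorm(4), c(1, 1, 2, 3)), "duplicate coordinates")
})

test_that("host splitting partitions samples and errors on empty subsets", {
  occ <- make_occ(matrix(rbinom(40, 1, 0.5), 10, 4))
  hosts <- make_hosts(rep(1:2, each = 5), dip = c(TRUE, FALSE))
  sp <- split_by_host(occ, hosts)
  expect_equal(nrow(sp$dipterocarp) + nrow(sp$non_dipterocarp), 10)
  expect_setequal(c(rownames(sp$dipterocarp), rownames(sp$non_dipterocarp)),
                  rownames(occ))
  hosts_all_dip <- make_hosts(rep(1, 10), dip = TRUE)
  expect_error(split_by_host(occ, hosts_all_dip), "non-dipterocarp subset")
})

test_that("pooling by plant OTU and geographic distances aggregate samples", {
  occ <- make_occ(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0)))
  hosts <- make_hosts(c(1, 1, 2, 2))
  u <- pool_by_plant_otu(occ, hosts, "99.8")
  expect_equal(unname(u["P998.001", ]), c(1, 1, 0))
  expect_equal(unname(u["P998.002", ]), c(1, 1, 1))
  expect_equal(unname(attr(u, "n_samples")), c(2L, 2L))
  g <- geographic_distance(hosts, c(0, 2, 10, 20), "99.8")
  expect_equal(g["P998.001", "P998.002"], 14)   # |mean(0,2) - mean(10,20)|
})
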