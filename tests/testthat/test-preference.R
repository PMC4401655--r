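test_that("Dirichlet prior follows the sampling-effort formula", {
  Tj <- c(p1 = 10L, p2 = 30L, p3 = 60L)
  y <- rbind(c(2L, 1L, 2L), c(0L, 3L, 7L))
  a <- compute_alpha(make_assoc(y, Tj))
  expect_equal(unname(a[1, ]), c(0.5, 1.5, 3.0))
  # row sums equal N_i, prior mean equals T / sum(T) for every fungus
  expect_equal(unname(rowSums(a)), unname(rowSums(y)), tolerance = 1e-9)
  expect_equal(unname(a[2, ] / sum(a[2, ])), c(0.1, 0.3, 0.6))
  expect_true(all(a > 0))
  expect_error(compute_alpha(make_assoc(y[, 1, drop = FALSE], Tj[1])),
               "single host taxon")
})

test_that("conjugate posterior matches the closed-form Dirichlet moments", {
  Tj <- c(a = 20L, b = 20L, c = 10L)
  y <- matrix(c(12L, 2L, 1L), 1, 3)
  assoc <- make_assoc(y, Tj)
  prior <- compute_alpha(assoc)
  post <- sample_posterior(assoc, draws = 50000, seed = 42)
  a_post <- unclass(prior) + y
  exact_mean <- a_post[1, ] / sum(a_post[1, ])
  # Dirichlet mean (alpha + y) / 2N ; MC standard error from exact variance
  expect_equal(sum(a_post[1, ]), 2 * sum(y))
  mc_se <- sqrt(exact_mean * (1 - exact_mean) / (sum(a_post) + 1) / 50000)
  expect_true(all(abs(colMeans(post$pi[[1]]) - exact_mean) < 4 * mc_se))
  # heavily data-dominated row shrinks to the prior mean within O(1/N)
  yb <- matrix(c(100L, 300L, 600L), 1, 3)
  Tb <- c(a = 100L, b = 300L, c = 600L)
  pb <- sample_posterior(make_assoc(yb, Tb), draws = 5000, seed = 1)
  expect_true(all(abs(colMeans(pb$pi[[1]]) - c(0.1, 0.3, 0.6)) < 0.01))
  expect_error(sample_posterior(assoc, draws = 0), "positive")
  expect_error(sample_posterior(assoc, mode = "gibbs", burn_in = 2e5),
               "burn_in")
})

test_that("gibbs sampler agrees with the conjugate posterior", {
  set.seed(15)
  Tj <- c(a = 25L, b = 15L, c = 10L)
  y <- t(vapply(1:5, function(i) draw_y_row(sample(8:20, 1), Tj),
                integer(3)))
  assoc <- make_assoc(y, Tj)
  pc <- sample_posterior(assoc, draws = 20000, seed = 3)
  pg <- sample_posterior(assoc, mode = "gibbs", iterations = 60000,
                         burn_in = 10000, thin = 5, seed = 4)
  for (i in 1:5) {
    expect_true(all(abs(colMeans(pc$pi[[i]]) - colMeans(pg$pi[[i]])) < 0.01))
  }
})

test_that("D-bar draws are centred, unit-norm deviation vectors", {
  Tj <- c(a = 30L, b = 30L, c = 30L)
  y <- rbind(c(30L, 0L, 0L), c(10L, 10L, 10L))
  assoc <- make_assoc(y, Tj)
  post <- sample_posterior(assoc, draws = 2000, seed = 7)
  pref <- compute_D(post, keep_draws = TRUE)
  for (i in 1:2) {
    Db <- pref$D_bar[[i]]
    expect_true(all(abs(rowSums(Db)) < 1e-8))
    expect_true(all(abs(sqrt(rowSums(Db^2)) - 1) < 1e-8))
    expect_true(all(Db >= -1 - 1e-12 & Db <= 1 + 1e-12))
  }
  # CI bounds ordered and inside [-1, 1]
  expect_true(all(pref$ci95_lo <= pref$ci95_hi))
  expect_true(all(pref$ci99_lo <= pref$ci95_lo + 1e-9 |
                    pref$ci99_lo <= pref$ci99_hi))
  expect_true(all(pref$ci99_lo >= -1 & pref$ci99_hi <= 1))
})

test_that("exclusive-host fungi get significant positive preference", {
  Tj <- c(a = 30L, b = 30L, c = 30L)
  y <- matrix(c(30L, 0L, 0L), 1, 3)
  assoc <- make_assoc(y, Tj)
  pref <- compute_D(sample_posterior(assoc, draws = 100000, seed = 9))
  expect_gt(pref$D_hat[1, 1], 0)
  expect_true(pref$sig99[1, 1])
  expect_gt(pref$ci99_lo[1, 1], 0)
  # independent high-precision Dirichlet oracle for the D-hat value
  a_post <- unclass(compute_alpha(assoc)) + y
  set.seed(10)
  g <- matrix(rgamma(1e6 * 3, shape = rep(a_post[1, ], each = 1e6)), 1e6, 3)
  pi_draws <- g / rowSums(g)
  dev <- sweep(pi_draws, 2, c(1, 1, 1) / 3)
  oracle <- mean(dev[, 1] / sqrt(rowSums(dev^2)))
  expect_lt(abs(pref$D_hat[1, 1] - oracle), 0.005)
})

test_that("null data leave D-hat centred on zero", {
  Tj <- c(a = 25L, b = 25L, c = 25L, d = 25L)
  y <- matrix(c(5L, 5L, 5L, 5L), 1, 4)
  pref <- compute_D(sample_posterior(make_assoc(y, Tj), draws = 20000,
                                     seed = 11))
  expect_true(all(abs(pref$D_hat) < 0.05))
  expect_false(any(pref$sig95))
})

test_that("degenerate deviation draws are rejected with an error past 1%", {
  Tj <- c(a = 10L, b = 10L)
  fake <- structure(list(
    pi = list(F001 = matrix(0.5, 200, 2,
                            dimnames = list(NULL, c("a", "b")))),
    chain = rep(1L, 200), T = Tj, N = c(F001 = 4),
    a_post = matrix(2, 1, 2), settings = list(mode = "conjugate")),
    class = "posterior_draws")
  expect_error(compute_D(fake), "rejected")
  # a single degenerate draw among many is dropped and counted
  set.seed(12)
  g <- matrix(rgamma(2000 * 2, shape = 2), 2000, 2)
  pi_ok <- g / rowSums(g)
  pi_ok[1, ] <- c(0.5, 0.5)
  fake2 <- fake
  fake2$pi$F001 <- pi_ok
  colnames(fake2$pi$F001) <- c("a", "b")
  pref <- compute_D(fake2)
  expect_equal(unname(pref$n_rejected["F001"]), 1L)
})

test_that("monotonicity: more occurrences on a host never lower its D-hat", {
  Tj <- c(a = 30L, b = 30L, c = 30L)
  dh <- vapply(0:10, function(k) {
    y <- matrix(c(k, 5L, 5L), 1, 3)
    compute_D(sample_posterior(make_assoc(y, Tj), draws = 50000,
                               seed = 100 + k))$D_hat[1, 1]
  }, numeric(1))
  expect_true(all(diff(dh) > -0.01))
  expect_gt(dh[11], dh[1])
})

test_that("D-hat-max is the signed maximum, with abs-mismatch flagged", {
  D <- rbind(o1 = c(0.1, -0.5, 0.3), o2 = c(0.9, -0.1, 0.0),
             o3 = c(-0.7, -0.2, -0.1))
  dm <- compute_Dmax(D)
  expect_equal(unname(dm), c(0.3, 0.9, -0.1), ignore_attr = TRUE)
  expect_equal(unname(attr(dm, "abs_differs")), c(TRUE, FALSE, TRUE))
  # a single dominant host drives D-hat-max towards its D-hat
  Tj <- c(a = 40L, b = 40L, c = 40L)
  y <- matrix(c(40L, 0L, 0L), 1, 3)
  pref <- compute_D(sample_posterior(make_assoc(y, Tj), draws = 5000,
                                     seed = 13))
  expect_equal(unname(compute_Dmax(pref)), pref$D_hat[1, 1],
               ignore_attr = TRUE)
})

test_that("Gelman-Rubin follows the pooled-variance formula", {
  ch <- cbind(rnorm(1000), rnorm(1000))
  ch_copy <- cbind(ch[, 1], ch[, 1])
  # exact copies: B = 0, so the statistic hits its floor sqrt((n-1)/n) ~ 1
  expect_equal(gelman_rubin(ch_copy), sqrt(999 / 1000))
  expect_lt(abs(gelman_rubin(ch_copy) - 1), 1e-3)
  set.seed(14)
  far <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(far), 5)                   # far-apart chains
  # hand-sized case: chains (1,2,3,4) and (3,4,5,6) x 10 reps for length >= 10
  c1 <- rep(c(1, 2, 3, 4), length.out = 12)
  c2 <- rep(c(3, 4, 5, 6), length.out = 12)
  W <- (var(c1) + var(c2)) / 2
  B <- 12 * var(c(mean(c1), mean(c2)))
  byhand <- sqrt(((12 - 1) / 12 * W + B / 12) / W)
  expect_equal(gelman_rubin(list(c1, c2)), byhand)
  expect_error(gelman_rubin(cbind(rep(1, 20), rep(1, 20))),
               "zero within-chain variance")
  expect_error(gelman_rubin(matrix(rnorm(8), 4, 2)), "length >= 10")
  expect_error(gelman_rubin(matrix(rnorm(20), 20, 1)), "2 chains")
  # posterior method: near-1 for a well-mixed gibbs run
  Tj <- c(a = 20L, b = 20L)
  y <- matrix(c(6L, 2L), 1, 2)
  pg <- sample_posterior(make_assoc(y, Tj), mode = "gibbs",
                         iterations = 8000, burn_in = 2000, thin = 2,
                         seed = 15)
  expect_true(all(abs(gelman_rubin(pg) - 1) < 0.02))
})

test_that("signed-rank enumeration matches hand values and wilcox.test", {
  w <- wilcoxon_signed_rank(1:6, (1:6) + 1)
  expect_true(w$exact)
  expect_equal(w$p.value, 2 / 64)                   # all-tied |d| case
  expect_warning(w0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(w0$p.value, 1)
  # tie-free cases agree with the exact stats::wilcox.test oracle
  set.seed(16)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(wilcoxon_signed_rank(x, y)$p.value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # Holm worked example
  expect_equal(p.adjust(c(0.01, 0.02, 0.02, 0.5, 0.6, 0.9), "holm"),
               c(0.06, 0.10, 0.10, 1, 1, 1))
})

test_that("level comparison flags differences and letters groups", {
  set.seed(17)
  base <- runif(10, 0.2, 0.6)
  dmax <- cbind(`99.8` = base, `99` = base, `98` = base + 0.4,
                `97` = base + 0.4)
  # the two identical-column pairs warn (all-zero differences) by contract
  cmp <- suppressWarnings(compare_Dmax_levels(dmax))
  same <- cmp[(cmp$level_a == "99.8" & cmp$level_b == "99") |
                (cmp$level_a == "98" & cmp$level_b == "97"), ]
  expect_true(all(same$p == 1))
  diffp <- cmp[cmp$level_a == "99.8" & cmp$level_b == "98", ]
  expect_true(diffp$significant)
  lt <- attr(cmp, "letters")
  expect_equal(lt[["99.8"]], lt[["99"]])
  expect_equal(lt[["98"]], lt[["97"]])
  expect_false(lt[["99.8"]] == lt[["98"]])
  # identical columns: every pair p = 1, one shared letter
  dmax2 <- cbind(a = base, b = base, c = base)
  cmp2 <- suppressWarnings(compare_Dmax_levels(dmax2))
  expect_true(all(cmp2$p == 1))
  expect_equal(unname(attr(cmp2, "letters")), rep("a", 3))
  expect_error(compare_Dmax_levels(dmax[1:4, ]), "at least 6")
})
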