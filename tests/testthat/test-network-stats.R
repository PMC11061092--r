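test_that("functional degree averages off-diagonal connectivity", {
  m <- matrix(0.4, 5, 5); diag(m) <- 0
  expect_equal(functional_degree(m)$degree, rep(0.4, 5))

  m3 <- matrix(0, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 0.2
  m3[1, 3] <- m3[3, 1] <- 0.4
  expect_equal(functional_degree(m3)$degree[1], 0.3)

  # diagonal is excluded from the summary
  md <- m3; diag(md) <- 99
  expect_equal(functional_degree(md)$degree, functional_degree(m3)$degree)
})

test_that("hub disruption index matches closed-form least squares", {
  h0 <- hub_disruption_index(c(1, 2, 5, 3), c(1, 2, 5, 3))
  expect_equal(h0$slope, 0)
  expect_equal(h0$offset, 0)

  # differences (2, 0, -2) on x = (1, 2, 3): exact line delta = 4 - 2x
  h <- hub_disruption_index(c(1, 2, 3), c(3, 2, 1))
  expect_equal(h$slope, -2)
  expect_equal(h$offset, 4)
  expect_equal(h$r_squared, 1)
  expect_equal(h$df_num, 1L)
  expect_equal(h$df_den, 1L)

  # adding a constant to the perturbed profile shifts only the offset
  ref <- c(0.2, 0.5, 0.9, 1.4, 0.7)
  per <- c(0.1, 0.6, 0.5, 1.0, 0.8)
  h1 <- hub_disruption_index(ref, per)
  h2 <- hub_disruption_index(ref, per + 0.25)
  expect_equal(h2$slope, h1$slope)
  expect_equal(h2$offset, h1$offset + 0.25)

  expect_error(hub_disruption_index(rep(1, 5), c(1, 2, 3, 4, 5)),
               class = "eidyn_error_zero_variance")
})

test_that("HDI internal consistency: F = R^2 (N-2) / (1 - R^2)", {
  for (seed in 1:6) {
    n <- 10 + 5 * seed
    ref <- with_seed(seed, runif(n, 0.1, 1))
    per <- with_seed(seed + 100, ref * 0.7 + rnorm(n, 0, 0.1))
    h <- hub_disruption_index(ref, per)
    expect_equal(h$f_stat, h$r_squared * (n - 2) / (1 - h$r_squared),
                 tolerance = 1e-9)
    # and the reported p agrees with the t-test on the slope
    expect_equal(h$p_value, tidy(h)$p.value[2], tolerance = 1e-12)
    expect_equal(glance(h)$hdi, h$slope)
  }
})

test_that("t-test reports pooled-variance statistics and Cohen's d", {
  a <- c(1, 2, 3, 4)
  tt <- independent_t_test(a, a)
  expect_equal(tt$t, 0)
  expect_equal(tt$cohens_d, 0)

  # two-point groups with pooled SD exactly 1 and mean difference 1
  d <- sqrt(2) / 2
  tt2 <- independent_t_test(c(1 - d, 1 + d), c(-d, d))
  expect_equal(tt2$cohens_d, 1)

  expect_error(independent_t_test(c(1, 1), c(2, 2)),
               class = "eidyn_error_zero_variance")

  # permutation oracle: enumerate all group reassignments
  x <- c(0.3, 1.2, 0.8, 2.1)
  y <- c(-0.4, 0.6, -1.0, 0.1)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  splits <- utils::combn(8, 4)
  perm_p <- mean(apply(splits, 2, function(idx) {
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  }))
  expect_equal(independent_t_test(x, y)$p_value, perm_p, tolerance = 0.1)
})

test_that("pearson_r matches the direct summation formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  px <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  py <- c(0.7, 2.9, 1.1, 4.2, 4.4)
  direct <- sum((px - mean(px)) * (py - mean(py))) /
    sqrt(sum((px - mean(px))^2) * sum((py - mean(py))^2))
  expect_equal(pearson_r(px, py)$r, direct)

  expect_error(pearson_r(rep(1, 5), 1:5), class = "eidyn_error_zero_variance")
})

test_that("Mann-Whitney U agrees with pairwise counting and exact enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$u, 9 / 2)

  # exact combinatorial oracle for tie-free samples
  a <- c(0.1, 2.3, 1.7, 3.2, 0.9)
  b <- c(1.1, 4.0, 2.8, 3.9)
  u_count <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  res <- mann_whitney_u(a, b)
  expect_equal(res$u, u_count)

  pool <- c(a, b)
  splits <- utils::combn(9, 5)
  u_null <- apply(splits, 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], ">"))
  })
  p_exact <- min(1, 2 * min(mean(u_null <= res$u), mean(u_null >= res$u)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
})

test_that("two-stage FDR matches an independently coded reference", {
  expect_true(all(fdr_bky(rep(1e-6, 78))))
  expect_false(any(fdr_bky(rep(1, 78))))
  expect_error(fdr_bky(c(0.5, 1.2)), class = "eidyn_error_pvalues")

  # reference implementation written directly from the two-stage recipe:
  # BH at q/(1+q), estimate m0, BH again at the inflated level
  bky_reference <- function(p, q) {
    m <- length(p)
    bh_reject <- function(p, level) {
      o <- order(p)
      thr <- level * seq_len(m) / m
      passed <- which(p[o] <= thr)
      rej <- rep(FALSE, m)
      if (length(passed)) rej[o[seq_len(max(passed))]] <- TRUE
      rej
    }
    q1 <- q / (1 + q)
    stage1 <- bh_reject(p, q1)
    r1 <- sum(stage1)
    if (r1 == 0) return(rep(FALSE, m))
    if (r1 == m) return(rep(TRUE, m))
    bh_reject(p, q1 * m / (m - r1))
  }

  mixed <- c(with_seed(20, runif(10, 0, 1e-4)), with_seed(21, runif(68)))
  for (q in c(0.01, 0.05, 0.2)) {
    expect_identical(fdr_bky(mixed, q), bky_reference(mixed, q))
  }
  for (seed in 1:5) {
    p <- with_seed(seed + 300, runif(40)^2)
    expect_identical(fdr_bky(p, 0.05), bky_reference(p, 0.05))
  }
})
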