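# NB differential-expression engine.

nb_mat <- function(n, mu, size, ncol = 6, prefix = "f") {
  matrix(rnbinom(n * ncol, mu = mu, size = size), n, ncol,
         dimnames = list(sprintf("%s%04d", prefix, seq_len(n)),
                         paste0("s", seq_len(ncol))))
}
grp6 <- rep(c("control", "treatment"), each = 3)

test_that("median-of-ratios size factors behave like the definition", {
  set.seed(41)
  m <- nb_mat(50, 200, 10)
  # identical columns -> unit factors
  same <- matrix(rep(m[, 1], 4), ncol = 4,
                 dimnames = list(rownames(m), paste0("s", 1:4)))
  expect_equal(unname(size_factors_median_ratio(same)), rep(1, 4))
  # scale equivariance: quadrupling one sample quadruples its factor
  # relative to every other sample's
  m4 <- m
  m4[, 2] <- m[, 2] * 4
  sf <- size_factors_median_ratio(m)
  sf4 <- size_factors_median_ratio(m4)
  expect_equal(unname(sf4[2] / sf4[-2]), unname(4 * sf[2] / sf[-2]),
               tolerance = 1e-8)
  # step-by-step spreadsheet recomputation
  keep <- rowSums(m > 0) == 6
  geo <- apply(m[keep, ], 1, function(x) prod(x)^(1 / 6))
  manual <- vapply(1:6, function(j) median(m[keep, j] / geo), double(1))
  expect_equal(unname(sf), manual, tolerance = 1e-8)
  # every feature has a zero somewhere -> total-count fallback
  mz <- rbind(a = c(0, 10, 10, 10, 10, 10), b = c(10, 0, 10, 10, 10, 10))
  colnames(mz) <- paste0("s", 1:6)
  expect_warning(sfz <- size_factors_median_ratio(mz), "falling back")
  expect_true(all(sfz > 0))
})

test_that("method-of-moments dispersion recovers known regimes", {
  set.seed(42)
  # Poisson data: alpha pinned near the floor
  dp <- estimate_dispersion_mom(nb_mat(1000, 100, Inf, ncol = 50))
  expect_lt(median(dp$dispersion), 0.02)
  # NB alpha = 0.1 with many samples
  dn <- estimate_dispersion_mom(nb_mat(500, 300, 10, ncol = 200))
  expect_gt(mean(dn$dispersion), 0.05)
  expect_lt(mean(dn$dispersion), 0.15)
  # constant feature -> floor; all-zero feature -> untestable
  m <- rbind(c5 = rep(5, 6), z = rep(0, 6))
  colnames(m) <- paste0("s", 1:6)
  d <- estimate_dispersion_mom(m)
  expect_equal(unname(d$dispersion[d$feature_id == "c5"]), 1e-8)
  expect_false(d$testable[d$feature_id == "z"])
  # within-group variant ignores the condition effect
  set.seed(43)
  shifted <- cbind(nb_mat(300, 100, 10, 3), nb_mat(300, 400, 10, 3))
  colnames(shifted) <- paste0("s", 1:6)
  d_pool <- estimate_dispersion_mom(shifted)
  d_grp <- estimate_dispersion_mom(shifted, groups = grp6)
  expect_lt(mean(d_grp$dispersion), mean(d_pool$dispersion))
})

test_that("the Wald test is antisymmetric in the contrast", {
  set.seed(44)
  m <- cbind(nb_mat(40, 150, 10, 3), nb_mat(40, 300, 10, 3))
  colnames(m) <- paste0("s", 1:6)
  fwd <- wald_test(m, rep(1, 6), 0.1, grp6, c("treatment", "control"))
  rev <- wald_test(m, rep(1, 6), 0.1, grp6, c("control", "treatment"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(rev$se, fwd$se)
})

test_that("permuting samples within groups leaves results unchanged", {
  set.seed(45)
  m <- cbind(nb_mat(30, 200, 10, 3), nb_mat(30, 200, 10, 3))
  colnames(m) <- paste0("s", 1:6)
  perm <- m[, c(3, 1, 2, 6, 4, 5)]
  r1 <- wald_test(m, rep(1, 6), 0.1, grp6, c("treatment", "control"))
  r2 <- wald_test(perm, rep(1, 6), 0.1, grp6, c("treatment", "control"))
  expect_equal(r1$log2fc, r2$log2fc)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("DE calls use inclusive boundaries and partition the features", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(0.5, 0.49, -0.7, 2),
    p_value = c(0.05, 0.049, 0.01, 0.051))
  called <- call_de(res)
  expect_equal(called$call, c("up", "ns", "down", "ns"))
  expect_true(all(table(called$call) >= 0))
  s <- de_sets(called)
  expect_equal(s$up, "a")
  expect_equal(s$down, "c")
})

test_that("untestable features are flagged, not dropped", {
  m <- rbind(live = c(5, 8, 6, 30, 25, 28), dead = rep(0, 6))
  colnames(m) <- paste0("s", 1:6)
  r <- wald_test(m, rep(1, 6), 0.1, grp6, c("treatment", "control"))
  expect_equal(nrow(r), 2)
  expect_equal(r$p_value[r$feature_id == "dead"], 1)
  expect_equal(r$call[r$feature_id == "dead"], "ns")
  g <- glance(r)
  expect_equal(g$n_features, 2)
  expect_equal(g$n_testable, 1)
})
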