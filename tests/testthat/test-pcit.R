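test_that("correlation_matrix reproduces hand-computed product-moment values", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  r <- correlation_matrix(x)
  expect_equal(r["a", "b"], 0.8)          # hand evaluation: cov 4/3, sd^2 5/3
  y <- rbind(u = c(1, 2, 3, 4), v = 2 * c(1, 2, 3, 4) + 1)
  expect_equal(correlation_matrix(y)["u", "v"], 1)   # affine invariance
  z <- rbind(u = c(1, 2, 3, 4), v = -c(1, 2, 3, 4))
  expect_equal(correlation_matrix(z)["u", "v"], -1)
})

test_that("correlation_matrix rejects degenerate input", {
  x <- rbind(flat = c(2, 2, 2, 2), ok = c(1, 2, 3, 4))
  err <- expect_error(correlation_matrix(x), class = "mitonet_zero_variance")
  expect_match(conditionMessage(err), "flat")
  expect_error(correlation_matrix(x[, 1:2, drop = FALSE]), "3 samples")
})

test_that("the worked trio yields the hand-derived tolerance and elimination pattern", {
  # independent arithmetic, straight from the partial-correlation formulas
  r_xy <- 0.9; r_xz <- 0.8; r_yz <- 0.6
  p_xy <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  p_xz <- (r_xz - r_xy * r_yz) / sqrt((1 - r_xy^2) * (1 - r_yz^2))
  p_yz <- (r_yz - r_xy * r_xz) / sqrt((1 - r_xy^2) * (1 - r_xz^2))
  eps_hand <- (abs(p_xy / r_xy) + abs(p_xz / r_xz) + abs(p_yz / r_yz)) / 3
  expect_equal(p_xy, 0.875)
  expect_lt(abs(trio_tolerance(r_xy, r_xz, r_yz) - eps_hand), 1e-9)

  r <- matrix(c(1, r_xy, r_xz, r_xy, 1, r_yz, r_xz, r_yz, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (fit in list(pcit_significance(r), pcit_brute_force(r))) {
    expect_true(fit$significant["x", "y"])
    expect_true(fit$significant["x", "z"])
    expect_false(fit$significant["y", "z"])  # 0.6 <= eps*0.9 and eps*0.8
    expect_false(any(diag(fit$significant)))
  }
})

test_that("an all-zero correlation structure leaves every pair significant", {
  r <- diag(4)
  dimnames(r) <- list(letters[1:4], letters[1:4])
  fit <- pcit_significance(r)
  expect_true(all(fit$significant[upper.tri(fit$significant)]))
  expect_identical(fit$significant, pcit_brute_force(r)$significant)
  # ...and thresholding removes them all downstream
  expect_equal(nrow(threshold_edges(fit, 0.7)), 0)
})

test_that("with two genes no trio exists and the pair is vacuously significant", {
  r <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit <- pcit_significance(r)
  expect_true(fit$significant["a", "b"])
  expect_identical(fit$significant, pcit_brute_force(r)$significant)
})

test_that("perfectly collinear genes are rejected", {
  r <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcit_significance(r), class = "mitonet_collinear")
  expect_error(pcit_brute_force(r), class = "mitonet_collinear")
})

test_that("vectorized mask equals the brute-force oracle on random instances", {
  for (s in 1:25) {
    n <- 3 + (s %% 23)
    r <- random_corr(n, seed = 1000 + s)
    expect_identical(pcit_significance(r)$significant,
                     pcit_brute_force(r)$significant,
                     info = sprintf("seed %d, n %d", 1000 + s, n))
  }
})

test_that("the significance mask is permutation-equivariant", {
  r <- random_corr(12, seed = 7)
  fit <- pcit_significance(r)
  for (s in 1:5) {
    set.seed(s)
    p <- sample(nrow(r))
    rp <- r[p, p]
    fitp <- pcit_significance(rp)
    expect_identical(fitp$significant, fit$significant[p, p])
  }
})

test_that("threshold_edges honors the cutoff boundary and monotonicity", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.69
  r[1, 3] <- r[3, 1] <- 0.71
  r[2, 3] <- r[3, 2] <- -0.90
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- pcit_significance(r)
  fit$significant[] <- TRUE; diag(fit$significant) <- FALSE  # isolate thresholding
  e <- threshold_edges(fit, cutoff = 0.7)
  expect_setequal(paste(e$gene_a, e$gene_b), c("a c", "b c"))
  expect_true(all(abs(e$weight) >= 0.7))
  # inclusive boundary
  e2 <- threshold_edges(fit, cutoff = 0.71)
  expect_true("a c" %in% paste(e2$gene_a, e2$gene_b))
  expect_equal(nrow(threshold_edges(fit, cutoff = 0.71, inclusive = FALSE)), 1)
  # negative edges survive on magnitude unless dropped
  expect_true(any(e$weight < 0))
  expect_false(any(threshold_edges(fit, 0.7, keep_negative = FALSE)$weight < 0))
  # raising the cutoff never adds edges
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.95), function(ct)
    nrow(threshold_edges(fit, ct)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # empty mask -> empty edge list
  fit$significant[] <- FALSE
  expect_equal(nrow(threshold_edges(fit, 0.7)), 0)
  expect_error(threshold_edges(fit, 1.2), "between 0 and 1")
})

test_that("pcit() front end ties correlation and significance together", {
  set.seed(42)
  x <- matrix(rnorm(8 * 30), nrow = 8,
              dimnames = list(sprintf("g%d", 1:8), NULL))
  fit <- pcit(x)
  expect_s3_class(fit, "pcit")
  expect_equal(fit$correlation, correlation_matrix(x))
  expect_true(isSymmetric(fit$significant))
  expect_output(print(fit), "PCIT")
  s <- summary(fit)
  expect_output(print(s), "pairs")
  expect_identical(coef(fit), fit$correlation)
})
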