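test_that("penalty spectrum has the stated limits and floor", {
  l1 <- 2; l2 <- 3
  # literal: s = 0 leaves the direction analytically unpenalized -> floor
  expect_equal(penalty_spectrum(0, l1, l2, "literal"), 1e-10 * l2)
  # kernel-span: s = 0 collapses to the plain independent ridge
  expect_equal(penalty_spectrum(0, l1, l2, "kernel-span"), l2)
  s <- c(0.3, 1, 2.5)
  expect_equal(penalty_spectrum(s, l1, l2, "literal"),
               l1 * l2 * s^2 / (l2 + l1 * s^2))
  expect_equal(penalty_spectrum(s, l1, l2, "kernel-span"),
               l1 * l2 / (l1 + l2 * s^2))
  expect_error(penalty_spectrum(1, -1, 1), "positive")
})

test_that("penalty spectrum equals a scalar brute-force split search", {
  # 1 gene / 1 regulator / 1 spot with P = 1: min over the split of
  # 0.5 (a - y)^2 + penalty(a) should match the omega formula
  y <- 1.7; s <- 0.8; l1 <- 1.3; l2 <- 0.6
  for (mode in c("literal", "kernel-span")) {
    omega <- penalty_spectrum(s, l1, l2, mode)
    a_hat <- y / (1 + omega)
    grid <- seq(-2, 2, length.out = 40001)
    vals <- vapply(grid, function(a_sd) {
      pen_sd <- if (mode == "literal") 0.5 * l1 * (a_sd * s)^2
                else 0.5 * l1 * (a_sd / s)^2
      a_si <- a_hat - a_sd
      0.5 * (a_hat - y)^2 + pen_sd + 0.5 * l2 * a_si^2
    }, numeric(1))
    # analytic objective at the solved total activity
    obj_analytic <- 0.5 * (a_hat - y)^2 + 0.5 * omega * a_hat^2
    expect_equal(min(vals), obj_analytic, tolerance = 1e-6)
  }
})

test_that("spectral solver matches the generic convex minimizer in both modes", {
  for (mode in c("literal", "kernel-span")) {
    for (seed in 1:3) {
      inst <- random_instance(seed = seed + ifelse(mode == "literal", 0, 50))
      l1 <- 10^runif(1, -1, 1); l2 <- 10^runif(1, -1, 1)
      fit <- spotact(inst$Y, inst$prior, inst$kernel, l1, l2, mode)
      oracle <- oracle_minimum(inst$Y, inst$P, inst$kernel$K, l1, l2, mode)
      expect_lt(abs(fit$objective - oracle) / oracle, 1e-6)
      expect_gte(oracle, fit$objective * (1 - 1e-9))
    }
  }
})

test_that("zero expression yields zero activities and objective", {
  inst <- random_instance(seed = 4)
  Y0 <- inst$Y * 0
  fit <- spotact(Y0, inst$prior, inst$kernel, 1, 1)
  expect_equal(max(abs(fit$A)), 0)
  expect_equal(max(abs(fit$A_sd)), 0)
  expect_equal(fit$objective, 0)
})

test_that("decomposition identity and objective invariant hold", {
  for (mode in c("literal", "kernel-span")) {
    inst <- random_instance(seed = 7)
    fit <- spotact(inst$Y, inst$prior, inst$kernel, 0.5, 2, mode)
    expect_equal(fit$A, fit$A_sd + fit$A_si, tolerance = 1e-12)
    recomputed <- spotact:::spotact_objective(
      inst$Y, inst$P, fit$A_sd, fit$A_si, inst$kernel, 0.5, 2, mode, fit$B)
    expect_lt(abs(recomputed - fit$objective) / fit$objective, 1e-8)
    # perturbing the split can only raise the objective
    set.seed(1)
    D <- matrix(rnorm(length(fit$A_sd), sd = 0.05), nrow(fit$A_sd))
    perturbed <- spotact:::spotact_objective(
      inst$Y, inst$P, fit$A_sd + D, fit$A_si - D, inst$kernel, 0.5, 2, mode,
      if (mode == "kernel-span") {
        # B consistent with the perturbed A_sd (spectral pseudo-inverse)
        inv_s <- ifelse(inst$kernel$values > 1e-12, 1 / inst$kernel$values, 0)
        ((fit$A_sd + D) %*% inst$kernel$vectors) %*%
          (inv_s * t(inst$kernel$vectors))
      } else NULL)
    expect_gte(perturbed, fit$objective - 1e-9)
  }
})

test_that("analytic limits: ridge at huge lambda1, vanishing A_si, K = I closed form", {
  inst <- random_instance(seed = 11, bandwidth = 0.25)
  R <- ncol(inst$P)
  # literal, lambda1 -> inf with well-conditioned K: plain ridge(lambda2)
  fit <- spotact(inst$Y, inst$prior, inst$kernel, 1e8, 0.7, "literal")
  ridge <- solve(crossprod(inst$P) + 0.7 * diag(R), crossprod(inst$P, inst$Y))
  expect_lt(max(abs(fit$A - ridge)), 1e-4)
  expect_lt(norm(fit$A_sd, "F"), 1e-3)
  # lambda2 -> inf drives the independent component to zero (literal)
  fit2 <- spotact(inst$Y, inst$prior, inst$kernel, 1, 1e8, "literal")
  expect_lt(norm(fit2$A_si, "F") / norm(fit2$A, "F"), 1e-3)
  # kernel-span, lambda1 -> inf drives the spatial component to zero
  fit3 <- spotact(inst$Y, inst$prior, inst$kernel, 1e8, 1, "kernel-span")
  expect_lt(norm(fit3$A_sd, "F") / norm(fit3$A, "F"), 1e-3)
  # K = I in kernel-span equals ridge with penalty l1 l2 / (l1 + l2)
  kid <- identity_kernel(colnames(inst$Y))
  fit4 <- spotact(inst$Y, inst$prior, kid, 2, 3, "kernel-span")
  ridge4 <- solve(crossprod(inst$P) + (2 * 3 / (2 + 3)) * diag(R),
                  crossprod(inst$P, inst$Y))
  expect_equal(unname(fit4$A), unname(ridge4), tolerance = 1e-8)
})

test_that("joint spot permutation of Y and kernel re-permutes A exactly", {
  inst <- random_instance(seed = 13)
  set.seed(2)
  perm <- sample(ncol(inst$Y))
  fit <- spotact(inst$Y, inst$prior, inst$kernel, 1.5, 0.8)
  kp <- rbf_kernel(inst$F[perm, , drop = FALSE], bandwidth = 0.4, rank = "full")
  fitp <- spotact(inst$Y[, perm], inst$prior, kp, 1.5, 0.8)
  expect_equal(fitp$A[, colnames(fit$A)], fit$A, tolerance = 1e-10)
})

test_that("fitted/predict/residual methods follow the linear model algebra", {
  inst <- random_instance(seed = 17)
  fit <- spotact(inst$Y, inst$prior, inst$kernel, 1, 1)
  expect_equal(fitted(fit), inst$P %*% fit$A, tolerance = 1e-12)
  expect_equal(residuals(fit, inst$Y), inst$Y - inst$P %*% fit$A,
               tolerance = 1e-12)
  # single-regulator prior: every target row of Y_hat equals the activity row
  P1 <- matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "r1"))
  ids <- colnames(inst$Y)[1:5]
  kid <- identity_kernel(ids)
  Y1 <- matrix(rnorm(10), 2, 5, dimnames = list(c("g1", "g2"), ids))
  f1 <- spotact(Y1, prior_mat(P1, "tf"), kid, 1, 1)
  yh <- fitted(f1)
  expect_equal(yh["g1", ], yh["g2", ], tolerance = 1e-12)
  expect_equal(yh["g1", ], f1$A["r1", ], tolerance = 1e-12)
})

test_that("held-out prediction: duplicated spot recovers training activity", {
  inst <- random_instance(seed = 19)
  fit <- spotact(inst$Y, inst$prior, inst$kernel, 1, 1, "kernel-span")
  # a test spot with exactly a training spot's features duplicates its K column
  Kc <- rbf_cross(inst$F, inst$F[c(3, 8), , drop = FALSE], inst$kernel$sigma)
  pred <- predict(fit, Kc)
  expect_equal(unname(pred[, 1]), unname(fit$A_sd[, 3]), tolerance = 1e-8)
  expect_equal(unname(pred[, 2]), unname(fit$A_sd[, 8]), tolerance = 1e-8)
  # expression-scale prediction is P times the activity prediction
  expect_equal(predict(fit, Kc, type = "expression"), inst$P %*% pred,
               tolerance = 1e-12)
})

test_that("held-out prediction is zero when the spatial component is zero", {
  inst <- random_instance(seed = 23)
  # lambda1 huge in kernel-span: A_sd ~ 0 so held-out activities ~ 0
  fit <- spotact(inst$Y, inst$prior, inst$kernel, 1e8, 1, "kernel-span")
  Kc <- rbf_cross(inst$F, inst$F[1:4, , drop = FALSE], inst$kernel$sigma)
  expect_lt(max(abs(predict(fit, Kc))), 1e-6)
  # literal-mode smoother: a column of the normalized cross kernel is a
  # convex combination, so predictions stay within the training range
  fitl <- spotact(inst$Y, inst$prior, inst$kernel, 1, 1, "literal")
  predl <- predict(fitl, Kc)
  expect_true(all(predl <= apply(fitl$A_sd, 1, max) + 1e-12))
  expect_true(all(predl >= apply(fitl$A_sd, 1, min) - 1e-12))
})

test_that("shape mismatches and non-finite input are rejected", {
  inst <- random_instance(seed = 29)
  bad <- inst$Y; bad[1, 1] <- NA
  expect_error(spotact(bad, inst$prior, inst$kernel), "non-finite")
  kid <- identity_kernel(paste0("zz", 1:4))
  expect_error(spotact(inst$Y, inst$prior, kid), "different spots")
})

test_that("truncated-rank fits agree with full-rank fits to the spectrum tail", {
  pos <- sim_grid(7, 7)
  F <- standardize_features(spot_features(pos))
  kf <- rbf_kernel(F, bandwidth = 0.6, rank = "full")
  kt <- rbf_kernel(F, bandwidth = 0.6, rank = 30)
  set.seed(31)
  P <- matrix(rbinom(40 * 5, 1, 0.3), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40), paste0("r", 1:5)))
  Y <- matrix(rnorm(40 * 49), 40, 49, dimnames = list(rownames(P), rownames(F)))
  ff <- spotact(Y, prior_mat(P, "tf"), kf, 1, 1)
  ft <- spotact(Y, prior_mat(P, "tf"), kt, 1, 1)
  tail_mass <- sum(kf$values[31:49]^2) / sum(kf$values^2)
  expect_lt(norm(ff$A - ft$A, "F") / norm(ff$A, "F"), 0.05 + 10 * tail_mass)
})
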