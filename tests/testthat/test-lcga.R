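make_hand_params <- function() {
  b <- basis_spec("logarithmic")
  lcga_params(b, 2L, rbind(c(6.5, -0.1), c(9.0, -0.4)),
              theta = log(0.6 / 0.4), sigma = 0.5)
}

hand_data <- function() {
  # 3 subjects x 2 measurements, values chosen by hand
  data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    weeks = c(0, 50, 0, 100, 10, 200),
    hba1c = c(6.4, 6.2, 9.1, 7.3, 6.9, 6.0))
}

test_that("mixture log-likelihood matches a brute-force density product", {
  params <- make_hand_params()
  d <- hand_data()
  # independent oracle: plain loops and prod(dnorm)
  pi_k <- c(0.6, 0.4)
  ll_oracle <- 0
  for (id in c("a", "b", "c")) {
    rows <- d[d$subject_id == id, ]
    lik <- 0
    for (k in 1:2) {
      mu <- params$beta[k, 1] + params$beta[k, 2] * log(rows$weeks + 1)
      lik <- lik + pi_k[k] * prod(dnorm(rows$hba1c, mu, 0.5))
    }
    ll_oracle <- ll_oracle + log(lik)
  }
  expect_equal(lcga_loglik(d, params), ll_oracle, tolerance = 1e-10)
})

test_that("single-component and degenerate mixtures reduce to the Gaussian fit", {
  d <- hand_data()
  b <- basis_spec("logarithmic")
  beta1 <- rbind(c(7.0, -0.2))
  p1 <- lcga_params(b, 1L, beta1, numeric(0), 0.6)
  mu <- 7.0 - 0.2 * log(d$weeks + 1)
  expect_equal(lcga_loglik(d, p1), sum(dnorm(d$hba1c, mu, 0.6, log = TRUE)))

  # two identical components split 50/50 equal the k = 1 value
  p2 <- lcga_params(b, 2L, rbind(beta1, beta1), theta = 0, sigma = 0.6)
  expect_equal(lcga_loglik(d, p2), lcga_loglik(d, p1), tolerance = 1e-12)
  # ... and give uniform posteriors
  expect_true(all(abs(lcga_e_step(d, p2) - 0.5) < 1e-12))

  expect_true(all(lcga_e_step(d, p1) == 1))
})

test_that("posterior rows sum to one and separate well-separated subjects", {
  params <- make_hand_params()
  d <- hand_data()
  post <- lcga_e_step(d, params)
  expect_equal(unname(rowSums(post)), rep(1, 3), tolerance = 1e-9)

  # subject exactly on component 1's curve, components > 5 sigma apart
  b <- basis_spec("logarithmic")
  far <- lcga_params(b, 2L, rbind(c(6, 0), c(12, 0)), theta = 0, sigma = 0.5)
  d1 <- data.frame(subject_id = "s", weeks = c(0, 50, 100),
                   hba1c = c(6, 6, 6))
  expect_gt(lcga_e_step(d1, far)[1, 1], 0.999)
})

test_that("e-step survives long series without underflow", {
  b <- basis_spec("logarithmic")
  params <- lcga_params(b, 2L, rbind(c(6, 0), c(10, 0)), theta = 0, sigma = 0.5)
  d <- data.frame(subject_id = "s", weeks = seq(0, 280, by = 20),
                  hba1c = rep(6, 15))
  post <- lcga_e_step(d, params)
  expect_equal(sum(post), 1)
  expect_gt(post[1, 1], 1 - 1e-12)
})

test_that("M-step with one-hot posteriors equals per-class least squares", {
  fx <- make_traj_data(40, c(6.5, 9), c(-0.1, -0.4), sd = 0, seed = 3)
  b <- basis_spec("logarithmic")
  onehot <- cbind(fx$class == 1, fx$class == 2) * 1
  params <- lcga_m_step(fx$data, onehot, b)
  for (k in 1:2) {
    sub <- fx$data[fx$data$subject_id %in%
                     sprintf("T%04d", which(fx$class == k)), ]
    X <- basis_matrix(sub$weeks, b)
    ols <- drop(solve(crossprod(X), crossprod(X, sub$hba1c)))
    expect_equal(unname(params$beta[k, ]), ols, tolerance = 1e-10)
  }
})

test_that("M-step with uniform posteriors collapses to the global fit", {
  fx <- make_traj_data(30, c(6.5, 9), c(-0.1, -0.4), sd = 0.3, seed = 4)
  b <- basis_spec("logarithmic")
  unif <- matrix(0.5, length(unique(fx$data$subject_id)), 2)
  params <- lcga_m_step(fx$data, unif, b)
  X <- basis_matrix(fx$data$weeks, b)
  ols <- drop(solve(crossprod(X), crossprod(X, fx$data$hba1c)))
  expect_equal(unname(params$beta[1, ]), ols, tolerance = 1e-10)
  expect_equal(unname(params$beta[2, ]), ols, tolerance = 1e-10)
})

test_that("an E+M sweep never decreases the log-likelihood", {
  fx <- make_traj_data(50, c(6.5, 8.5), c(-0.1, -0.3), sd = 0.4, seed = 5)
  b <- basis_spec("logarithmic")
  params <- lcga_params(b, 2L, rbind(c(7.2, -0.05), c(7.9, -0.5)),
                        theta = 0.4, sigma = 0.8)
  for (it in 1:12) {
    ll_before <- lcga_loglik(fx$data, params)
    post <- lcga_e_step(fx$data, params)
    params <- lcga_m_step(fx$data, post, b)
    expect_gte(lcga_loglik(fx$data, params), ll_before - 1e-9)
  }
})

test_that("rank-deficient weighted designs raise an error naming the class", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                  weeks = rep(10, 6), hba1c = rnorm(6, 7))
  onehot <- rbind(c(1, 0), c(0, 1))
  expect_error(lcga_m_step(d, onehot, basis_spec("cubic")),
               "class 1", class = "hba1ctraj_rank_error")
})

test_that("k = 1 fit is the closed-form least-squares solution with its BIC", {
  fx <- make_traj_data(40, 7.5, -0.2, sd = 0.3, seed = 6)
  b <- basis_spec("linear")
  fit <- fit_lcga(fx$data, b, 1)
  X <- basis_matrix(fx$data$weeks, b)
  ols <- drop(solve(crossprod(X), crossprod(X, fx$data$hba1c)))
  expect_equal(unname(drop(fit$params$beta)), ols, tolerance = 1e-10)
  # linear basis: d = 2, so k = 1 has 3 free parameters
  expect_equal(fit$bic, -2 * fit$loglik + 3 * log(fit$n_subjects))
  expect_identical(fit$modal_class, rep(1L, fit$n_subjects))
})

test_that("BIC formula and parameter counting are as documented", {
  expect_equal(bic_value(-100, 5, 100), 200 + 5 * log(100))
  expect_error(bic_value(-100, 5, 0))
})

test_that("well-separated three-class data is recovered almost perfectly", {
  fx <- make_traj_data(600, c(6, 8, 10), c(0, 0, 0), sd = 0.3, n_obs = 6,
                       seed = 7)
  fit <- fit_lcga(fx$data, basis_spec("logarithmic"), 3, n_starts = 5, seed = 1)
  # canonical order is descending level: fitted 1 = true 3, etc.
  remap <- c(3L, 2L, 1L)[fit$modal_class]
  expect_gte(mean(remap == fx$class), 0.99)
  expect_true(all(fit$appa > 0.95))
  expect_equal(fit$params$sigma, 0.3, tolerance = 0.1)
})

test_that("fits are deterministic given the seed and ordered by mean level", {
  fx <- make_traj_data(80, c(6.5, 9), c(-0.1, -0.4), sd = 0.4, seed = 8)
  f1 <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 4, seed = 3)
  f2 <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 4, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$posterior, f2$posterior)
  g <- colMeans(class_curves(f1, seq(0, 250, by = 10)))
  expect_true(all(diff(g) <= 0))
})

test_that("subject order does not affect the fitted model", {
  fx <- make_traj_data(60, c(6.5, 9), c(-0.1, -0.4), sd = 0.4, seed = 9)
  f1 <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 3, seed = 2)
  set.seed(11)
  ids <- unique(fx$data$subject_id)
  shuf <- sample(ids)
  d2 <- fx$data[order(match(fx$data$subject_id, shuf)), ]
  f2 <- fit_lcga(d2, basis_spec("logarithmic"), 2, n_starts = 3, seed = 2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-7)
  expect_equal(f1$posterior[shuf[1], ], f2$posterior[shuf[1], ],
               tolerance = 1e-9)
})

test_that("EM burn-in traces are monotone across every start", {
  fx <- make_traj_data(80, c(6.5, 8.5), c(-0.1, -0.3), sd = 0.4, seed = 10)
  fit <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 6, seed = 4)
  for (tr in fit$burn_trace) expect_true(all(diff(tr) >= -1e-8))
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("APPA matches hand-computed values and flags empty classes", {
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  modal <- c(1L, 1L, 2L)
  expect_equal(appa(post, modal), c(0.75, 0.8))
  onehot <- diag(3)
  expect_equal(appa(onehot, 1:3), c(1, 1, 1))
  expect_warning(res <- appa(post, c(1L, 1L, 1L)), "no modal members")
  expect_true(is.na(res[2]))
})

test_that("scaled entropy spans its [0, 1] contract", {
  expect_equal(scaled_entropy(diag(4)), 1)
  expect_equal(scaled_entropy(matrix(1 / 3, 5, 3)), 0)
  expect_equal(scaled_entropy(rbind(c(1, 0), c(0.5, 0.5))), 0.5)
  expect_true(is.na(scaled_entropy(matrix(1, 4, 1))))
})

test_that("posterior prediction reproduces training posteriors and handles ties", {
  fx <- make_traj_data(60, c(6.5, 9), c(-0.1, -0.4), sd = 0.4, seed = 12)
  fit <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 3, seed = 2)
  pred <- posterior_predict_lcga(fx$data, fit)
  expect_equal(pred$posterior[fit$subject_ids, ], unname(fit$posterior),
               tolerance = 1e-12, ignore_attr = TRUE)

  # one measurement equidistant from both curves: posterior ratio = pi ratio
  b <- basis_spec("logarithmic")
  params <- lcga_params(b, 2L, rbind(c(8, 0), c(6, 0)),
                        theta = log(0.7 / 0.3), sigma = 0.5)
  d1 <- data.frame(subject_id = "tie", weeks = 0, hba1c = 7)
  post <- posterior_predict_lcga(d1, params)$posterior
  expect_equal(unname(post[1, 1] / post[1, 2]), 0.7 / 0.3, tolerance = 1e-12)

  # subjects with no measurements are reported, not dropped silently
  pred2 <- posterior_predict_lcga(d1, params, subject_ids = c("tie", "empty"))
  expect_identical(pred2$excluded, "empty")
})

test_that("fitted models serialize to JSON and CSV", {
  fx <- make_traj_data(30, c(6.5, 9), c(-0.1, -0.4), sd = 0.4, seed = 13)
  fit <- fit_lcga(fx$data, basis_spec("logarithmic"), 2, n_starts = 2, seed = 1)
  dir <- withr::local_tempdir()
  write_lcga_fit(fit, dir)
  meta <- jsonlite::fromJSON(file.path(dir, "lcga_fit.json"))
  expect_equal(meta$k, 2)
  expect_equal(meta$sigma, fit$params$sigma)
  post <- utils::read.csv(file.path(dir, "posterior.csv"))
  expect_equal(nrow(post), fit$n_subjects)
  expect_equal(post$p_1 + post$p_2, rep(1, nrow(post)), tolerance = 1e-9)
})
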