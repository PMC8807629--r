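test_that("geometric-mean transform: identities, scaling, and expectation", {
  expect_equal(transform_likelihood(0.3), 0.3)           # d = 1 identity
  expect_equal(transform_likelihood(rep(0.07, 123)), 0.07)
  expect_error(transform_likelihood(c(0.5, 0)), "positive")
  expect_error(transform_likelihood(numeric(0)), "at least one")

  # multiplicativity: common factor passes through, so posteriors built from
  # the transform are invariant to a joint rescaling of both classes
  l1 <- runif(40); l2 <- runif(40)
  c0 <- 3.7
  expect_equal(transform_likelihood(c0 * l1), c0 * transform_likelihood(l1))
  p <- function(a, b) a / (a + b)
  expect_equal(
    p(transform_likelihood(l1), transform_likelihood(l2)),
    p(transform_likelihood(c0 * l1), transform_likelihood(c0 * l2)))

  # E[(prod u_i)^(1/d)] = 1/(1+1/d)^d for u ~ U(0,1) i.i.d.
  u <- sample_uniform_likelihoods(10, 1e5, seed = 7)
  mc <- mean(exp(rowMeans(log(u))))
  expect_lt(abs(mc - (1 + 1/10)^-10), 0.005)
})

test_that("per-gene Gaussian likelihoods are correct and floored", {
  model <- structure(list(
    classes = c("A", "B"), priors = c(0.5, 0.5), gene_ids = c("g1", "g2"),
    means = matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("A", "B"))),
    vars = matrix(1, 2, 2), d = 2L, log_offset = 1), class = "gnb_model")
  expect_equal(gaussian_likelihood(model, c(0, 0), "A"),
               rep(1 / sqrt(2 * pi), 2))
  # standard normal density table: phi(1) = 0.2420, phi(2) = 0.0540
  expect_equal(gaussian_likelihood(model, c(1, 2), "A"),
               c(0.2420, 0.0540), tolerance = 1e-3)
  expect_error(gaussian_likelihood(model, c(1, 2, 3), "A"), "dimension")
  expect_error(gaussian_likelihood(model, c(1, 2), "C"), "unknown class")

  # symmetric classes evaluated at the midpoint give identical vectors
  model$means[, "A"] <- 2; model$means[, "B"] <- -2
  expect_equal(gaussian_likelihood(model, c(0, 0), "A"),
               gaussian_likelihood(model, c(0, 0), "B"))
})

make_model <- function(d, delta = 0.5, priors = c(0.5, 0.5)) {
  g <- sprintf("g%04d", seq_len(d))
  structure(list(
    classes = c("A", "B"), priors = priors, gene_ids = g,
    means = matrix(c(rep(delta, d), rep(-delta, d)), d, 2,
                   dimnames = list(g, c("A", "B"))),
    vars = matrix(1, d, 2), d = as.integer(d), log_offset = 1),
    class = "gnb_model")
}

test_that("posterior is normalized, Bayes-consistent, and underflow-proof", {
  m1 <- make_model(1)
  # d = 1, priors equal, likelihoods 0.2 vs 0.6 -> posterior (0.25, 0.75):
  # pick x where dnorm(x, +-0.5) gives that 1:3 ratio via direct evaluation
  expect_equal(unname(posterior(m1, 0)), c(0.5, 0.5), ignore_attr = TRUE)
  # at d = 1 the transform is the identity, so Bayes' rule applies directly:
  # likelihood ratio 1:3 (x = log(1/3) gives dnorm ratio exp(x)) -> (0.25, 0.75)
  expect_equal(unname(posterior(m1, log(1/3))), c(0.25, 0.75),
               ignore_attr = TRUE)

  withr::local_seed(11)
  for (rep in 1:20) {
    d <- sample(1:30, 1)
    pr <- runif(1, 0.1, 0.9)
    m <- make_model(d, delta = runif(1, 0, 1), priors = c(pr, 1 - pr))
    x <- rnorm(d)
    p <- posterior(m, x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }

  # transcriptome dimension: raw product underflows, posterior does not
  d <- 1408L
  m <- make_model(d)
  withr::local_seed(12)
  x <- rnorm(d) + 0.5  # a class-A sample
  raw <- prod(gaussian_likelihood(m, x, "A"))
  expect_identical(raw, 0)  # double precision underflow
  p <- posterior(m, x)
  expect_true(all(p > 1e-6 & p < 1 - 1e-6))  # no saturation
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("classify agrees with the exact log-space naive Bayes oracle", {
  withr::local_seed(13)
  for (rep in 1:30) {
    d <- sample(1:50, 1)
    pr <- runif(1, 0.1, 0.9)
    m <- make_model(d, delta = runif(1, 0, 0.3), priors = c(pr, 1 - pr))
    x <- rnorm(d)
    oracle_scores <- c(
      log(m$priors[1]) + sum(dnorm(x, m$means[, 1], 1, log = TRUE)),
      log(m$priors[2]) + sum(dnorm(x, m$means[, 2], 1, log = TRUE)))
    oracle <- m$classes[which.max(oracle_scores)]
    expect_identical(classify(m, x), oracle)
  }
  # exact tie goes to the first class
  m <- make_model(3)
  expect_identical(classify(m, c(0, 0, 0)), "A")
})

test_that("high-separation classification is near perfect", {
  fp <- two_class_fpkm(60, 200, effect = 2, seed = 14)
  labels <- rep(c("A", "B"), each = 200)
  model <- fit_gnb(fp, labels, rownames(fp), use_soft_weights = FALSE)
  pred <- classify(model, log2(fp + 1))
  expect_gte(mean(pred == labels), 0.95)
})

test_that("logistic link matches the equal-variance Gaussian derivation", {
  # class means 100 (long) and 20 (short), pooled biased variance 400
  y <- c(80, 120, 0, 40)
  labels <- c("L", "L", "S", "S")
  link <- fit_logistic_link(y, labels, classes = c("L", "S"))
  expect_equal(link$a, -0.2)
  expect_equal(link$b, 60)
  expect_equal(link_prob(link, 100), 1 / (1 + exp(-0.2 * 40)))
  expect_equal(link_prob(link, 100), 0.99966, tolerance = 1e-4)
  expect_equal(link_prob(link, link$b), 0.5)

  # swapping class order negates the slope; memberships complement
  link2 <- fit_logistic_link(y, labels, classes = c("S", "L"))
  expect_equal(link2$a, 0.2)
  expect_equal(link_prob(link, 75) + link_prob(link2, 75), 1)

  expect_error(fit_logistic_link(c(5, 5, 5, 5), labels), "zero pooled")
})

test_that("weighted parameter estimation follows the fixed-weight formulas", {
  wp <- weighted_class_params(c(1, 3), c(0.25, 0.75))
  expect_equal(wp$mean, 2.5)
  expect_equal(wp$var, 0.75)  # 0.25*1.5^2 + 0.75*0.5^2

  # hard indicator weights recover the class mean and biased variance
  x <- c(2, 4, 9, 1, 7)
  w <- c(1, 1, 0, 0, 0) / 2
  wp2 <- weighted_class_params(x, w)
  expect_equal(wp2$mean, 3)
  expect_equal(wp2$var, mean((c(2, 4) - 3)^2))

  # uniform weights give the global mean / biased variance
  wp3 <- weighted_class_params(x, rep(0.2, 5))
  expect_equal(wp3$mean, mean(x))
  expect_equal(wp3$var, mean((x - mean(x))^2))

  expect_warning(wp4 <- weighted_class_params(x, c(1, 0, 0, 0, 0)),
                 "floored")
  expect_true(wp4$floored)
  expect_error(weighted_class_params(x, rep(0.3, 5)), "sum to 1")
})

test_that("fit_gnb: priors, soft/hard limit, and parameter recovery", {
  fp <- two_class_fpkm(10, 200, effect = 1, seed = 15)
  labels <- rep(c("A", "B"), each = 200)
  labels[1:100] <- "A"  # 300 A / 100 B split below
  labels <- c(rep("A", 300), rep("B", 100))
  model <- fit_gnb(fp, labels, rownames(fp), use_soft_weights = FALSE)
  expect_equal(model$priors, c(0.75, 0.25))

  # nearly separated y: soft weights converge to hard indicators
  labels <- rep(c("A", "B"), each = 200)
  y <- c(rnorm(200, 1000, 1), rnorm(200, 1, 0.1))
  soft <- fit_gnb(fp, labels, rownames(fp), y = y, use_soft_weights = TRUE)
  hard <- fit_gnb(fp, labels, rownames(fp), use_soft_weights = FALSE)
  expect_equal(soft$means, hard$means, tolerance = 1e-6)
  expect_equal(soft$vars, hard$vars, tolerance = 1e-6)

  # planted 1-sd effect, n = 500/class, hard labels: per-gene difference
  # estimator has sd sqrt(2/500) ~ 0.063, so mean |error| < 0.1 and nearly
  # all genes within +-0.2
  fp2 <- two_class_fpkm(60, 500, effect = 1, seed = 16)
  labels2 <- rep(c("A", "B"), each = 500)
  m2 <- fit_gnb(fp2, labels2, rownames(fp2), use_soft_weights = FALSE)
  err <- abs((m2$means[, 1] - m2$means[, 2]) - 1)
  expect_lt(mean(err), 0.1)
  expect_gte(mean(err < 0.2), 0.9)

  # constant gene: variance floored with a warning
  fp3 <- rbind(fp2[1:3, ], flat = 7)
  expect_warning(m3 <- fit_gnb(fp3, labels2, rownames(fp3),
                               use_soft_weights = FALSE),
                 "floored")
  expect_equal(unname(m3$vars["flat", ]), c(1e-6, 1e-6))
})
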