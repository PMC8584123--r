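test_that("fit_groups reproduces hand-computed means and pooled variance", {
  mat <- tiny_matrix(list(c(1, 3, 2, 2, 5, 5, 0, 4)))
  fit <- fit_groups(mat)
  expect_equal(unname(fit$means[1, ]), c(2, 2, 5, 2))
  # pooled SS = 2 + 0 + 0 + 8 over df = 8 - 4
  expect_equal(unname(fit$s2), 2.5)
  expect_equal(fit$df, 4L)
  # one-line brute force: residuals from group means
  g <- rep(group_levels(), each = 2)
  y <- c(1, 3, 2, 2, 5, 5, 0, 4)
  expect_equal(unname(fit$s2), sum((y - ave(y, g))^2) / 4)
})

test_that("constant input gives zero variance and df 4", {
  mat <- tiny_matrix(list(rep(3.5, 8), rep(-1, 8)))
  fit <- fit_groups(mat)
  expect_equal(unname(fit$s2), c(0, 0))
  expect_equal(fit$df, 4L)
})

test_that("prior estimator: identical variances give d0 = Inf", {
  pr <- estimate_prior(rep(0.02, 100), df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.02)
})

test_that("prior estimator recovers generating values and matches limma", {
  set.seed(42)
  d0 <- 4; s0 <- 0.01; df <- 4
  sigma2 <- s0 * d0 / rchisq(20000, d0)
  s2 <- sigma2 * rchisq(20000, df) / df
  pr <- estimate_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.25)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)
  skip_if_not_installed("limma")
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(pr$d0, ref$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("two disjoint variance populations give a finite positive d0
           whose implied moments match the empirical ones", {
  set.seed(1)
  s2 <- c(rchisq(500, 4) / 4 * 0.01, rchisq(500, 4) / 4 * 0.5)
  pr <- estimate_prior(s2, df = 4)
  expect_true(is.finite(pr$d0) && pr$d0 > 0)
  # returned prior reproduces the matched moment of log s2
  e <- log(s2) - digamma(2) + log(2)
  expect_equal(log(pr$s0_sq) - digamma(pr$d0 / 2) + log(pr$d0 / 2),
               mean(e), tolerance = 1e-8)
  expect_equal(trigamma(pr$d0 / 2), var(e) - trigamma(2), tolerance = 1e-6)
})

test_that("prior estimator rejects degenerate variance fields", {
  expect_error(estimate_prior(rep(0, 100), 4), "degenerate")
  expect_error(estimate_prior(rep(0.1, 10), 4), ">= 50")
})

test_that("posterior variance interpolates and shrinks toward the prior", {
  fit <- fit_groups(tiny_matrix(list(c(1, 3, 2, 2, 5, 5, 0, 4),
                                     rep(2, 8))))
  m <- moderate_variances(fit, list(d0 = 4, s0_sq = 0.5))
  expect_equal(unname(m$s2_tilde[1]), (4 * 0.5 + 4 * 2.5) / 8)
  # shrinkage direction: s2 above prior moves down, below moves up
  expect_lt(m$s2_tilde[1], fit$s2[1])
  expect_gt(m$s2_tilde[2], fit$s2[2])
  expect_true(all(m$s2_tilde > pmin(0.5, fit$s2) - 1e-12))
  # strict monotonicity in s2 for fixed prior
  s2_grid <- seq(0, 3, by = 0.1)
  post <- (4 * 0.5 + 4 * s2_grid) / 8
  expect_true(all(diff(post) > 0))
})

test_that("moderated contrast: zero logFC gives t = 0, p = 1; the d0 = Inf
           limit is the known-variance z-test", {
  mat <- tiny_matrix(list(c(1, 3, 1, 3, 5, 5, 0, 4)))
  fit <- moderate_variances(fit_groups(mat), list(d0 = Inf, s0_sq = 0.04))
  bpa <- moderated_contrast(fit, "BPA")
  expect_equal(bpa$logFC, 0)
  expect_equal(bpa$t, 0)
  expect_equal(bpa$p, 1)
  rad <- moderated_contrast(fit, "RAD")
  z <- (5 - 2) / sqrt(0.04 * (1 / 2 + 1 / 2))
  expect_equal(rad$t, z)
  expect_equal(rad$p, 2 * stats::pnorm(-abs(z)))
})

test_that("d0 = 0 reproduces the ordinary pooled-error t-test", {
  set.seed(7)
  y <- rnorm(8, rep(c(5, 6, 5.2, 7), each = 2), 0.4)
  mat <- tiny_matrix(list(y))
  fit <- moderate_variances(fit_groups(mat), list(d0 = 0, s0_sq = 1))
  ours <- moderated_contrast(fit, "BPA")
  g <- factor(rep(group_levels(), each = 2), levels = group_levels())
  ref <- summary(stats::lm(y ~ g))$coefficients["gBPA", ]
  expect_equal(ours$logFC, unname(ref["Estimate"]), tolerance = 1e-12)
  expect_equal(ours$t, unname(ref["t value"]), tolerance = 1e-12)
  expect_equal(ours$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("zero posterior variance with nonzero logFC warns and gives p = 0", {
  mat <- tiny_matrix(list(c(1, 1, 2, 2, 1, 1, 1, 1)))
  fit <- moderate_variances(fit_groups(mat), list(d0 = 4, s0_sq = 0))
  expect_warning(res <- moderated_contrast(fit, "BPA"), "zero posterior")
  expect_equal(res$p, 0)
  expect_equal(suppressWarnings(moderated_contrast(fit, "RAD"))$p, 1)
})

test_that("full moderated route agrees with the limma oracle", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(sim_config(n_genes = 500, seed = 13))
  mat <- sim$matrix
  design <- stats::model.matrix(~ 0 + mat$group)
  colnames(design) <- levels(mat$group)
  lfit <- limma::lmFit(mat$values, design)
  cm <- limma::makeContrasts(BPA - CTL, RAD - CTL, BPA_RAD - CTL,
                             levels = design)
  lfit <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  de <- run_de(mat, prior = list(d0 = lfit$df.prior,
                                 s0_sq = lfit$s2.prior))
  expect_equal(de$tables$BPA$logFC, unname(lfit$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(de$tables$BPA$t, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(de$tables$BPA_RAD$p, unname(lfit$p.value[, 3]),
               tolerance = 1e-8)
  # and our own estimated prior agrees with limma's
  expect_equal(de$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(de$prior$s0_sq, lfit$s2.prior, tolerance = 1e-6)
})

test_that("DEG filter applies the printed inclusive cutoffs", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    logFC = c(0.5, 0.49, -0.7, 2),
                    p = c(0.05, 1e-9, 0.04, 0.051))
  got <- filter_degs(tab)
  expect_identical(got$gene_id, c("a", "c"))
})

test_that("type-I rate of the moderated test on true nulls is nominal", {
  sim <- simulate_expression(sim_config(n_genes = 4000, frac_de_bpa = 0.1,
                                        frac_de_rad = 0.1, seed = 31))
  de <- run_de(sim$matrix)
  nulls <- sim$truth$true_class == "null"
  frac <- mean(de$tables$BPA$p[nulls] <= 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("deg_overlap matches brute-force set arithmetic", {
  expect_error(deg_overlap(list(A = c("x", "x"), B = "y")), "duplicate")
  same <- deg_overlap(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$count[same$region == "A&B"], 5L)
  expect_equal(sum(same$count), 5L)
  disj <- deg_overlap(list(A = letters[1:3], B = letters[4:6]))
  expect_equal(disj$count[disj$region == "A&B"], 0L)
  expect_equal(sum(disj$count), 6L)

  set.seed(99)
  lists <- list(A = sample(letters, 12), B = sample(letters, 8),
                C = sample(letters, 15))
  got <- deg_overlap(lists)
  expect_equal(sum(got$count), length(unique(unlist(lists))))
  only_ab <- setdiff(intersect(lists$A, lists$B), lists$C)
  expect_equal(got$count[got$region == "A&B"], length(only_ab))
  abc <- Reduce(intersect, lists)
  expect_equal(got$count[got$region == "A&B&C"], length(abc))
  only_c <- setdiff(lists$C, union(lists$A, lists$B))
  expect_equal(got$count[got$region == "C"], length(only_c))
})
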