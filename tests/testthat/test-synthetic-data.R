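test_that("zero-effect config yields an all-null truth table", {
  cfg <- sim_config(n_genes = 400, frac_de_bpa = 0, frac_de_rad = 0,
                    planted_set_size = 0, seed = 3)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$truth$true_class == "null"))
  expect_true(all(sim$truth$beta_bpa == 0))
  expect_true(all(sim$truth$beta_rad == 0))
  expect_true(all(sim$truth$beta_combo == 0))
  # group means differ only by noise: spread of group means around the
  # gene mean is on the noise scale, not the effect scale
  fit <- fit_groups(sim$matrix)
  gap <- apply(fit$means, 1, function(m) max(m) - min(m))
  expect_lt(stats::median(gap), 0.5)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_genes = 300, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c <- simulate_expression(sim_config(n_genes = 300, seed = 12))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("truth table satisfies the class-definition invariants", {
  cfg <- sim_config(n_genes = 4000, frac_de_bpa = 0.15, frac_de_rad = 0.15,
                    seed = 5)
  tr <- simulate_expression(cfg)$truth
  nul <- tr$true_class == "null"
  expect_true(all(tr$beta_bpa[nul] == 0 & tr$beta_rad[nul] == 0 &
                    tr$beta_combo[nul] == 0))
  s <- tr$beta_bpa + tr$beta_rad
  add <- tr$true_class == "additive"
  expect_equal(tr$beta_combo[add], s[add])
  pot <- tr$true_class == "potentiation"
  expect_equal(abs(tr$beta_combo[pot] / s[pot]),
               rep(cfg$potentiation_factor, sum(pot)))
  ant <- tr$true_class == "antagonism"
  expect_equal(abs(tr$beta_combo[ant] / s[ant]),
               rep(cfg$antagonism_factor, sum(ant)))
  unx <- tr$true_class == "unexpected"
  expect_true(all(sign(tr$beta_combo[unx]) != sign(s[unx])))
  # DE fractions near their settings (binomial tolerance, ~4 sd)
  non_planted <- !tr$set_membership
  p_hat <- mean(tr$beta_bpa[non_planted] != 0)
  expect_lt(abs(p_hat - 0.15), 4 * sqrt(0.15 * 0.85 / sum(non_planted)))
})

test_that("planted set has the exact configured median shift in truth", {
  cfg <- sim_config(n_genes = 2000, seed = 8)
  tr <- simulate_expression(cfg)$truth
  expect_equal(sum(tr$set_membership), 200)
  expect_identical(stats::median(tr$beta_combo[tr$set_membership]), -0.5)
  expect_true(all(tr$beta_combo[tr$set_membership] < 0))
})

test_that("baseline mean and variance prior are honoured", {
  cfg <- sim_config(n_genes = 8000, frac_de_bpa = 0, frac_de_rad = 0,
                    planted_set_size = 0, baseline_mean = 7,
                    baseline_sd = 1.5, seed = 21)
  sim <- simulate_expression(cfg)
  fit <- fit_groups(sim$matrix)
  grand <- rowMeans(fit$means)
  se <- 1.5 / sqrt(length(grand))
  expect_lt(abs(mean(grand) - 7), 3 * se)
  # gene variances follow the scaled inverse-chi-square prior: d0*s0/sigma^2
  # should look chi-square(d0)
  q <- stats::ks.test(cfg$d0 * cfg$s0_sq / sim$truth$sigma_sq,
                      stats::pchisq, df = cfg$d0)
  expect_gt(q$p.value, 0.01)
})

test_that("config validation rejects malformed settings", {
  expect_error(sim_config(n_reps_per_group = 0), "n_reps_per_group")
  expect_error(sim_config(interaction_mix = c(additive = 0.5,
                                              potentiation = 0.5,
                                              antagonism = 0.2,
                                              unexpected = -0.2)),
               "sum to 1")
  expect_error(sim_config(effect_size_range = c(0.2, 2)), "cutoff")
  expect_error(sim_config(potentiation_factor = 1.1), "potentiation_factor")
})

test_that("endpoint table generator is seeded and exact at zero noise", {
  means <- c(CTL = 10, BPA = 12, RAD = 9, BPA_RAD = 11)
  tab <- simulate_endpoint_table(2, means, group_sd = 0, seed = 4)
  got <- vapply(group_levels(), function(g)
    unique(tab$value[sample_group(tab$factor_bpa, tab$factor_rad) == g]),
    numeric(1))
  expect_equal(got, means)
  a <- simulate_endpoint_table(5, means, 1, seed = 9)
  b <- simulate_endpoint_table(5, means, 1, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_endpoint_table(1, means, 1, seed = 1), ">= 2")
})

test_that("endpoint generator calibration: null ANOVA p-values uniform, and
           a RAD-only effect is detected without inflating the BPA factor", {
  n_rep <- 300
  p_bpa <- p_rad <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    null_tab <- simulate_endpoint_table(4, rep(5, 4), 1, seed = 1000 + i)
    res <- two_way_anova_tukey(null_tab)
    p_bpa[i] <- res$anova$p[res$anova$term == "BPA"]
    p_rad[i] <- res$anova$p[res$anova$term == "RAD"]
  }
  expect_gt(stats::ks.test(p_bpa, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p_rad <= 0.05) - 0.05), 0.05)

  hit_rad <- hit_bpa <- logical(100)
  for (i in 1:100) {
    tab <- simulate_endpoint_table(6, c(CTL = 5, BPA = 5, RAD = 8,
                                        BPA_RAD = 8), 1, seed = 2000 + i)
    res <- two_way_anova_tukey(tab)
    hit_rad[i] <- res$anova$p[res$anova$term == "RAD"] <= 0.05
    hit_bpa[i] <- res$anova$p[res$anova$term == "BPA"] <= 0.05
  }
  expect_gt(mean(hit_rad), 0.95)      # 3-sigma effect, n = 6: near-sure
  expect_lt(mean(hit_bpa), 0.15)      # nominal type-I rate
})
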