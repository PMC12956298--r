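test_that("REML fit recovers truth exactly in the noiseless limit", {
  nodes <- generate_node_layout(24, 6, 160, seed = 11)
  subj <- generate_subject_table(3, seed = 11)
  truth <- oracle_truth("model1", seed = 11, sigma_e = 0, sigma_b = 0)
  coh <- simulate_oracle_cohort(nodes, subj, truth, clip = FALSE)
  fit <- fit_lmm(coh$design)
  expect_true(fit$converged)
  rel <- abs(fit$beta - truth$beta[fit$terms]) /
    pmax(abs(truth$beta[fit$terms]), 1e-3)
  expect_lt(max(rel), 1e-6)
})

test_that("with no subject variance the fit matches an exact OLS solve", {
  nodes <- generate_node_layout(24, 6, 160, seed = 12)
  subj <- generate_subject_table(3, seed = 12)
  truth <- oracle_truth("model1", seed = 12, sigma_e = 0.05, sigma_b = 0)
  coh <- simulate_oracle_cohort(nodes, subj, truth)
  fit <- fit_lmm(coh$design)
  beta_ols <- qr.coef(qr(coh$design$X), coh$design$y)
  expect_equal(unname(fit$beta), unname(beta_ols), tolerance = 1e-4)
  expect_lt(fit$sigma_b, 0.01)
})

test_that("profiled REML agrees with the lme4 reference implementation", {
  skip_if_not_installed("lme4")
  coh <- small_cohort(seed = 13)
  fit <- fit_lmm(coh$design)
  df <- data.frame(y = coh$design$y, subj = coh$design$subject,
                   coh$design$X[, -1], check.names = TRUE)
  form <- stats::reformulate(c(colnames(df)[-(1:2)], "(1 | subj)"),
                             response = "y")
  # lme4 warns about raw predictor scales (dist2 vs interaction products);
  # the package fitter equilibrates internally, so only the agreement matters
  ref <- suppressWarnings(lme4::lmer(form, data = df, REML = TRUE))
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_b, vc$sdcor[1], tolerance = 1e-3)
  expect_equal(fit$sigma_e, vc$sdcor[2], tolerance = 1e-3)
  expect_equal(sqrt(diag(fit$vcov)), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("rank-deficient designs fail loudly with the dependent column named", {
  coh <- small_cohort(seed = 13)
  d <- coh$design
  d$X <- cbind(d$X, dup_of_eff = d$X[, "eff"])
  d$terms <- colnames(d$X)
  expect_error(fit_lmm(d), "rank deficient.*dup_of_eff|dup_of_eff.*rank")
})

test_that("contrast vectors encode the group coding and location rules", {
  L <- group_contrast_vector("model1", "HIV+MJ-", "within", "clustering")
  expect_equal(sum(L != 0), 2)
  expect_equal(unname(L[c("hiv_x_clust", "hiv_x_clust_x_dmn_within")]), c(1, 1))

  L2 <- group_contrast_vector("model1", "HIV+MJ+", "within", "efficiency")
  expect_equal(sum(L2 != 0), 6)
  expect_true(all(L2[c("hiv_x_eff", "mj_x_eff", "hivmj_x_eff",
                       "hiv_x_eff_x_dmn_within", "mj_x_eff_x_dmn_within",
                       "hivmj_x_eff_x_dmn_within")] == 1))

  L3 <- group_contrast_vector("model1", "HIV+MJ+", "outside", "efficiency")
  expect_equal(sum(L3 != 0), 3)
  expect_true(all(L3[grep("dmn_within", names(L3))] == 0))

  L4 <- group_contrast_vector("model2", "HIV-MJ+", "within", "efficiency",
                              moderated_by_globalT = TRUE)
  expect_equal(names(which(L4 != 0)),
               c("globalT_x_mj_x_eff", "globalT_x_mj_x_eff_x_dmn_within"))
  expect_error(group_contrast_vector("model1", "HIV+MJ-", "within",
                                     "clustering", moderated_by_globalT = TRUE),
               "model2")
})

test_that("Wald tests follow the normal-approximation algebra", {
  fit <- fake_fit("model1", list(hiv = 2), vcov_scale = 1)
  res <- wald_test(fit, c(hiv = 1))
  expect_equal(res$z, 2)
  expect_equal(res$p, 2 * pnorm(-2), tolerance = 1e-10)  # ~0.0455

  expect_error(wald_test(fit, c(hiv = 0)), "zeros")
  expect_error(wald_test(fit, c(nope = 1)), "unknown")
})

test_that("Wald p-values agree with a likelihood-ratio refit", {
  coh <- small_cohort(seed = 14)
  fit_ml <- fit_lmm(coh$design, reml = FALSE)
  j <- which(fit_ml$terms == "hiv_x_eff_x_dmn_within")
  w <- wald_test(fit_ml, setNames(1, "hiv_x_eff_x_dmn_within"))
  d0 <- coh$design
  d0$X <- d0$X[, -j]; d0$terms <- d0$terms[-j]
  fit0 <- fit_lmm(d0, reml = FALSE)
  lrt <- 2 * (fit_ml$loglik - fit0$loglik)
  p_lrt <- pchisq(lrt, df = 1, lower.tail = FALSE)
  expect_lt(abs(w$p - p_lrt), 0.02)
})

test_that("two-stage adaptive FDR matches its hand-run definition", {
  expect_equal(sum(adaptive_fdr(c(1, 1, 1), q = 0.05)$reject), 0)

  # hand-run: stage 1 BH at 0.05/1.05 = 0.0476 rejects the three small
  # p-values; m0 = 3; stage 2 BH at 0.05 * 6/3 = 0.1 rejects the same three
  p <- c(0.001, 0.002, 0.003, 0.8, 0.9, 0.95)
  out <- adaptive_fdr(p, q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(out$p_adj[1:3] <= 0.05))
  expect_true(all(out$p_adj[4:6] > 0.05))

  expect_error(adaptive_fdr(c(0.5, 0)), "0, 1")
  expect_length(adaptive_fdr(numeric(0))$p_adj, 0)
})

test_that("adaptive FDR is monotone in q and step-up coherent", {
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(12)^sample(1:3, 1)
    qs <- c(0.01, 0.03, 0.05, 0.1, 0.2, 0.4)
    rejections <- vapply(qs, function(q) sum(adaptive_fdr(p, q)$reject),
                         numeric(1))
    expect_true(all(diff(rejections) >= 0))

    out <- adaptive_fdr(p, 0.05)
    if (any(out$reject)) {
      # never reject a hypothesis whose p exceeds that of an accepted one
      expect_lt(max(p[out$reject]), min(c(p[!out$reject], Inf)) + 1e-15)
      # adjusted p-values are the smallest q at which each is rejected
      expect_true(all(out$p_adj[out$reject] <= 0.05 + 1e-9))
    }
  }
})

test_that("collinearity diagnostic flags duplicates and clears the oracle design", {
  coh <- small_cohort(seed = 13)
  rep_check <- collinearity_check(coh$design)
  expect_false(any(rep_check$flagged))
  expect_lt(attr(rep_check, "max_abs_r"), 0.95)

  d <- coh$design
  d$X[, "clust_x_dmn_within"] <- d$X[, "clust"]  # exact duplicate
  dup <- collinearity_check(d)
  expect_true(dup$flagged[dup$term == "clust_x_dmn_within" &
                            dup$metric == "clust"])

  # a metric times a balanced centered binary is nearly orthogonal to it
  set.seed(5)
  x <- rnorm(4000); b <- rep(c(-0.5, 0.5), 2000)
  expect_lt(abs(cor(x, x * b)), 0.05)
})

test_that("contrast precision improves with more subjects per group", {
  se_for <- function(n_per_group) {
    nodes <- generate_node_layout(30, 8, 160, seed = 31)
    subj <- generate_subject_table(n_per_group, seed = 31)
    coh <- simulate_oracle_cohort(nodes, subj, oracle_truth("model1", seed = 31))
    fit <- fit_lmm(coh$design)
    wald_test(fit, group_contrast_vector("model1", "HIV+MJ+", "within",
                                         "efficiency"))$se
  }
  expect_lt(se_for(8), se_for(4))
})
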