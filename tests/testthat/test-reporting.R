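test_that("slope lines equal the Wald contrast estimates exactly", {
  coh <- small_cohort(seed = 13)
  fit <- fit_lmm(coh$design)
  sl <- slope_lines(fit)
  base <- sl$slope[sl$group == "HIV-MJ-" & sl$metric == "efficiency"]
  expect_equal(base, unname(fit$beta["eff"] + fit$beta["eff_x_dmn_within"]),
               tolerance = 1e-12)
  for (g in c("HIV+MJ-", "HIV-MJ+", "HIV+MJ+")) {
    w <- wald_test(fit, group_contrast_vector("model1", g, "within",
                                              "efficiency"))
    row <- sl[sl$group == g & sl$metric == "efficiency", ]
    expect_equal(row$slope - base, w$estimate, tolerance = 1e-12)
    expect_equal(row$contrast_estimate, w$estimate, tolerance = 1e-12)
  }
})

test_that("zero group interactions give four identical slope lines", {
  fit <- fake_fit("model1", list(clust = 0.2, clust_x_dmn_within = 0.05,
                                 eff = 0.1, eff_x_dmn_within = 0.02))
  sl <- slope_lines(fit)
  for (m in c("clustering", "efficiency")) {
    expect_equal(length(unique(sl$slope[sl$metric == m])), 1)
  }
  expect_error(slope_lines(fake_fit("model2")), "model1")
})

test_that("slope surfaces are affine in GlobalT with the exact moderation slope", {
  fit <- fake_fit("model2", list(
    eff = 0.1, eff_x_dmn_within = 0.02,
    globalT_x_eff = 0.003, globalT_x_eff_x_dmn_within = 0.002,
    globalT_x_hiv_x_eff = 0.001, globalT_x_hiv_x_eff_x_dmn_within = 0.004))
  surf <- slope_surfaces(fit, globalT_grid = seq(36, 64, by = 2))
  # second differences vanish: the surface is affine in T
  for (g in unique(surf$group)) {
    s <- surf$slope[surf$group == g & surf$metric == "efficiency"]
    expect_lt(max(abs(diff(diff(s)))), 1e-12)
  }
  # slope(60) - slope(38) = 22 * total moderation coefficient
  s38 <- slope_surfaces(fit, 38); s60 <- slope_surfaces(fit, 60)
  pick <- function(x, g) x$slope[x$group == g & x$metric == "efficiency"]
  expect_equal(pick(s60, "HIV-MJ-") - pick(s38, "HIV-MJ-"),
               22 * (0.003 + 0.002), tolerance = 1e-12)
  expect_equal(pick(s60, "HIV+MJ-") - pick(s38, "HIV+MJ-"),
               22 * (0.003 + 0.002 + 0.001 + 0.004), tolerance = 1e-12)

  # zero moderation -> flat surfaces equal to the base within-DMN slope
  flat <- fake_fit("model2", list(eff = 0.1, eff_x_dmn_within = 0.02))
  fs <- slope_surfaces(flat, c(38, 49, 60))
  expect_equal(unique(fs$slope[fs$metric == "efficiency"]), 0.12,
               tolerance = 1e-12)

  expect_error(slope_surfaces(fake_fit("model1")), "model2")
  expect_error(slope_surfaces(fit, c(40, 40)), "increasing")
})

test_that("representative networks follow the top-fraction rule and fitted slopes", {
  coh <- small_cohort("model2", seed = 17)
  fit <- fit_lmm(coh$design)
  net <- representative_network(fit, "HIV+MJ+", 47, coh, retain_fraction = 0.15)
  n_eligible <- length(unique(paste(coh$edge_table$node_i,
                                    coh$edge_table$node_j)))
  expect_equal(nrow(net$edges), as.integer(round(0.15 * n_eligible)))
  expect_equal(nrow(net$nodes), nrow(coh$nodes))
  expect_true(all(diff(net$edges$predicted_strength) <= 1e-12))

  # identical coefficients across groups -> identical representative networks
  flat <- fake_fit("model2", list(intercept = 0.4, eff = 0.3, clust = 0.1))
  na <- representative_network(flat, "HIV-MJ-", 47, coh)
  nb <- representative_network(flat, "HIV+MJ+", 47, coh)
  expect_equal(na$edges, nb$edges, tolerance = 1e-12)

  # a positive efficiency slope ranks high-efficiency edges on top
  eff_fit <- fake_fit("model2", list(intercept = 0.4, eff = 0.5))
  ne <- representative_network(eff_fit, "HIV-MJ-", 47, coh,
                               retain_fraction = 1)
  key <- paste(coh$edge_table$node_i, coh$edge_table$node_j)
  eff_mean <- tapply(coh$edge_table$eff, key, mean)
  ord <- match(paste(ne$edges$node_i, ne$edges$node_j), names(eff_mean))
  expect_gt(cor(ne$edges$predicted_strength, as.numeric(eff_mean)[ord],
                method = "spearman"), 0)

  expect_warning(representative_network(fit, "HIV+MJ+", 120, coh), "range")
})

test_that("group density comparison detects only real density differences", {
  nodes <- generate_node_layout(20, 6, 160, seed = 23)
  subj <- generate_subject_table(15, seed = 23)
  mk <- function(p_edge, seed) {
    set.seed(seed)
    w <- matrix(0, 20, 20)
    up <- which(upper.tri(w))
    on <- up[runif(length(up)) < p_edge]
    w[on] <- 0.5
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    dimnames(w) <- list(nodes$node_id, nodes$node_id)
    connectivity_matrix(w)
  }
  # identical matrices everywhere -> all p = 1
  same <- mk(0.5, 1)
  coh_same <- list(subjects = subj,
                   matrices = setNames(rep(list(same), 60), subj$subject_id))
  out <- group_density_comparison(coh_same)
  expect_true(all(out$tests$p == 1))

  # one group with systematically denser networks is detected at n = 15
  mats <- lapply(seq_len(60), function(i)
    mk(ifelse(subj$group[i] == "HIV+MJ+", 0.6, 0.5), 100 + i))
  coh_diff <- list(subjects = subj, matrices = setNames(mats, subj$subject_id))
  out2 <- group_density_comparison(coh_diff)
  expect_lt(out2$tests$p[out2$tests$group == "HIV+MJ+"], 0.05)
  expect_gt(min(out2$tests$p[out2$tests$group != "HIV+MJ+"]), 0.05)

  solo <- list(subjects = subj[subj$group == "HIV-MJ-", ],
               matrices = coh_same$matrices[1:15])
  expect_error(group_density_comparison(solo), "two groups")
})

test_that("report tables and networks write as plain TSV", {
  coh <- small_cohort("model2", seed = 17)
  fit <- fit_lmm(coh$design)
  td <- withr::local_tempdir()
  surf <- slope_surfaces(fit, c(38, 60))
  p1 <- file.path(td, "surf.tsv")
  write_report_table(surf, p1)
  expect_equal(nrow(read.delim(p1)), nrow(surf))
  net <- representative_network(fit, "HIV-MJ-", 50, coh)
  write_representative_network(net, file.path(td, "nodes.tsv"),
                               file.path(td, "edges.tsv"))
  expect_equal(nrow(read.delim(file.path(td, "edges.tsv"))), nrow(net$edges))
})
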