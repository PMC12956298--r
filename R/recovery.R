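#' Run a parameter-recovery experiment on an oracle cohort
#'
#' The package's end-to-end validation drive: generate an oracle cohort
#' whose generative contrast coefficients are known, fit the requested
#' model by REML, evaluate the twelve group contrasts (GlobalT-moderation
#' contrasts for the secondary model), and tabulate recovered estimates
#' against the generative truths.
#'
#' @param model `"model1"` (group contrasts) or `"model2"`
#'   (GlobalT-moderation contrasts).
#' @param seed cohort seed.
#' @param n_per_group subjects per group.
#' @param n_nodes,n_dmn network size.
#' @param sigma_e,sigma_b noise SDs.
#' @param contrasts generative contrast table ([default_contrast_truths()])
#'   or `"null"`.
#' @param q FDR level for the contrast table.
#' @return list: `cohort`, `fit`, `contrasts` (data.frame with estimate,
#'   se, p, p_adj, truth, z_error = (estimate - truth)/se).
#' @export
recovery_experiment <- function(model = c("model1", "model2"), seed = 42L,
                                n_per_group = 15, n_nodes = 80, n_dmn = 20,
                                sigma_e = 0.05, sigma_b = 0.02,
                                contrasts = default_contrast_truths(),
                                q = 0.05) {
  model <- match.arg(model)
  nodes <- generate_node_layout(n_nodes, n_dmn, 160, seed = seed)
  subjects <- generate_subject_table(n_per_group, seed = seed)
  truth <- oracle_truth(model, seed = seed, sigma_e = sigma_e,
                        sigma_b = sigma_b, contrasts = contrasts)
  cohort <- simulate_oracle_cohort(nodes, subjects, truth)
  fit <- fit_lmm(cohort$design)
  moderated <- model == "model2"
  tab <- evaluate_group_contrasts(fit, moderated_by_globalT = moderated,
                                  q = q)
  if (identical(contrasts, "null")) {
    tab$truth <- 0
  } else {
    want <- contrasts[contrasts$moderated == moderated, ]
    key <- function(d) paste(d$group, d$location, d$metric)
    tab$truth <- want$estimate[match(key(tab), key(want))]
  }
  tab$z_error <- (tab$estimate - tab$truth) / tab$se
  list(cohort = cohort, fit = fit, contrasts = tab)
}
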