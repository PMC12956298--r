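#' Ground truth for oracle-mode simulation
#'
#' Bundles the generative fixed-effect coefficients, the residual and
#' subject-random-intercept SDs, and the seed that freezes the whole
#' cohort.
#'
#' @param beta named numeric vector; names must match the fixed-effect
#'   terms of the target model ([model_terms()]).
#' @param sigma_e residual SD (> 0, or 0 for noiseless checks).
#' @param sigma_b subject random-intercept SD (>= 0).
#' @param seed integer seed.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(beta, sigma_e, sigma_b, seed) {
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("beta must be fully named")
  if (sigma_e < 0 || sigma_b < 0) stop("sigma_e and sigma_b must be >= 0")
  structure(list(beta = beta, sigma_e = sigma_e, sigma_b = sigma_b,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Reference group-contrast effect sizes
#'
#' The default generative truths for oracle cohorts: slope-difference
#' contrasts (vs the HIV-MJ- control) for each group, DMN location and
#' metric, on the connection-strength scale. The `moderated = FALSE` rows
#' are the primary (group) effects; `moderated = TRUE` rows are the
#' GlobalT-moderation effects used by the secondary model. The signs encode
#' the qualitative picture the package is built to detect: within the DMN,
#' strength depends less on clustering and more on efficiency in the
#' HIV/MJ groups (the HIV+MJ+ efficiency slope being steepest), with the
#' GlobalT moderation of those slopes attenuated relative to control.
#'
#' @return data.frame (group, location, metric, moderated, estimate).
#' @export
default_contrast_truths <- function() {
  g <- c("HIV+MJ-", "HIV-MJ+", "HIV+MJ+")
  grid <- expand.grid(group = g, location = c("within", "outside"),
                      metric = c("clustering", "efficiency"),
                      moderated = c(FALSE, TRUE), stringsAsFactors = FALSE)
  est <- c(
    -0.0015, -0.0116, -0.0179,   # group / within / clustering
     0.0036,  0.0037,  0.0025,   # group / outside / clustering
     0.0120,  0.0216,  0.0367,   # group / within / efficiency
    -0.0026, -0.0024, -0.0019,   # group / outside / efficiency
     0.0227,  0.0174,  0.0207,   # GlobalT-moderated / within / clustering
    -0.0064,  0.0011,  0.0031,   # GlobalT-moderated / outside / clustering
    -0.0208, -0.0160, -0.0214,   # GlobalT-moderated / within / efficiency
     0.0043, -0.0005, -0.0030)   # GlobalT-moderated / outside / efficiency
  grid$estimate <- est
  grid
}

## Baseline (non-contrast) generative coefficients: chosen once for
## realism of the simulated strengths (mean ~0.4, modest distance decay,
## DMN edges stronger, strength rising with both metrics; the control
## group's within-DMN slope shifts with GlobalT away from clustering and
## toward efficiency).
.default_base_beta <- function(model) {
  terms <- model_terms(model)
  beta <- setNames(rep(0, length(terms)), terms)
  beta["intercept"] <- 0.40
  beta[c("hiv", "mj", "hivmj")] <- c(-0.005, -0.005, 0.005)
  beta[c("clust", "eff")] <- c(0.10, 0.10)
  beta[c("dmn_within", "dmn_between")] <- c(0.08, 0.03)
  beta["dist"] <- -0.0010
  beta["dist2"] <- 1.5e-6
  beta["age"] <- -5e-4
  beta["sex"] <- 0.005
  beta["race"] <- 0.003
  beta["education"] <- 1e-3
  beta["rmd"] <- -0.2
  beta[c("hiv_x_dmn_within", "mj_x_dmn_within", "hivmj_x_dmn_within")] <-
    c(-0.01, -0.01, 0.005)
  beta[c("hiv_x_dmn_between", "mj_x_dmn_between", "hivmj_x_dmn_between")] <-
    c(-0.005, -0.005, 0.002)
  beta[c("clust_x_dmn_within", "eff_x_dmn_within")] <- c(0.05, 0.02)
  beta[c("clust_x_dmn_between", "eff_x_dmn_between")] <- c(0.01, 0.01)
  if (model == "model2") {
    beta["globalT"] <- 5e-4
    beta[paste0("globalT_x_", c("hiv", "mj", "hivmj"))] <- 5e-4
    beta[paste0("globalT_x_", c("dmn_within", "dmn_between"))] <- c(5e-4, 0)
    beta["globalT_x_clust_x_dmn_within"] <- -0.010
    beta["globalT_x_eff_x_dmn_within"] <- 0.010
  }
  beta
}

## Fold contrast effect sizes into coefficients. With the HIV/MJ/HIVMJ
## coding, the outside contrast of a group is the sum of its group-term x
## metric coefficients and the within contrast adds the x dmn_within
## coefficients, so the mapping is triangular and exact.
.fold_contrasts <- function(beta, contrasts, model) {
  est <- function(group, location, metric, moderated) {
    r <- contrasts$group == group & contrasts$location == location &
      contrasts$metric == metric & contrasts$moderated == moderated
    if (sum(r) != 1) stop("contrast table must have one row per cell")
    contrasts$estimate[r]
  }
  for (mod in unique(contrasts$moderated)) {
    if (mod && model != "model2")
      stop("GlobalT-moderated truths require model2")
    pfx <- if (mod) "globalT_x_" else ""
    for (m in c("clust", "eff")) {
      lab <- if (m == "clust") "clustering" else "efficiency"
      h <- paste0(pfx, "hiv_x_", m); mj <- paste0(pfx, "mj_x_", m)
      hm <- paste0(pfx, "hivmj_x_", m)
      hw <- paste0(h, "_x_dmn_within"); mw <- paste0(mj, "_x_dmn_within")
      hmw <- paste0(hm, "_x_dmn_within")
      beta[h] <- est("HIV+MJ-", "outside", lab, mod)
      beta[mj] <- est("HIV-MJ+", "outside", lab, mod)
      beta[hm] <- est("HIV+MJ+", "outside", lab, mod) - beta[h] - beta[mj]
      beta[hw] <- est("HIV+MJ-", "within", lab, mod) - beta[h]
      beta[mw] <- est("HIV-MJ+", "within", lab, mod) - beta[mj]
      beta[hmw] <- est("HIV+MJ+", "within", lab, mod) -
        (beta[h] + beta[mj] + beta[hm] + beta[hw] + beta[mw])
    }
  }
  beta
}

#' Construct an oracle ground truth
#'
#' Builds a [ground_truth()] whose contrast-relevant coefficients reproduce
#' a table of slope-difference effect sizes exactly (default:
#' [default_contrast_truths()]), on top of fixed baseline coefficients.
#' `contrasts = "null"` zeroes every group and GlobalT interaction, giving
#' the null generative model used for calibration checks.
#'
#' @param model `"model1"` or `"model2"`.
#' @param seed integer seed for the cohort.
#' @param sigma_e residual SD (default 0.05).
#' @param sigma_b subject random-intercept SD (default 0.02).
#' @param contrasts a data.frame like [default_contrast_truths()], or
#'   `"null"`.
#' @return a [ground_truth()].
#' @export
oracle_truth <- function(model = c("model1", "model2"), seed = 42L,
                         sigma_e = 0.05, sigma_b = 0.02,
                         contrasts = default_contrast_truths()) {
  model <- match.arg(model)
  beta <- .default_base_beta(model)
  if (identical(contrasts, "null")) {
    if (model == "model2") {
      beta["globalT_x_clust_x_dmn_within"] <- 0
      beta["globalT_x_eff_x_dmn_within"] <- 0
      beta[paste0("globalT_x_", c("hiv", "mj", "hivmj"))] <- 0
      beta[paste0("globalT_x_", c("dmn_within", "dmn_between"))] <- 0
    }
    return(ground_truth(beta, sigma_e, sigma_b, seed))
  }
  if (model == "model1")
    contrasts <- contrasts[!contrasts$moderated, , drop = FALSE]
  beta <- .fold_contrasts(beta, contrasts, model)
  ground_truth(beta, sigma_e, sigma_b, seed)
}

#' Default reference-network regime parameters
#'
#' The reference networks that supply the frozen metric covariates are
#' built from three node regimes, re-drawn per subject: *clique* nodes sit
#' in small strongly connected communities (high clustering), *hub* nodes
#' carry many strong long-range edges (high efficiency, low clustering),
#' and *peripheral* nodes are sparsely and weakly connected (low both).
#' This mixture gives the nodal metrics the broad, weakly correlated
#' spread needed for the interaction coefficients to be estimated with
#' useful precision at desk scale; real connectomes are far more
#' homogeneous (see the package vignette).
#'
#' @return named list of regime parameters: `p_types` (clique/hub/
#'   peripheral probabilities), `comm_size` (community size range),
#'   `clique_w`, `hub_w`, `bridge_w`, `weak_w` (uniform weight ranges),
#'   `keep_hub`, `keep_bridge`, `keep_weak` (background edge retention
#'   probabilities), `noise_sd` (log-normal weight jitter SD).
#' @export
reference_regimes <- function() {
  list(p_types = c(hub = 0.25, spoke = 0.22, bridge = 0.20,
                   clique = 0.18, isolate = 0.15),
       comm_size = c(3L, 6L),
       core_w = c(0.85, 0.95), clique_w = c(0.80, 0.95),
       bridge_w = c(0.85, 0.95), weak_w = c(0.02, 0.08),
       keep_hub_spoke = 0.95, keep_bridge_spoke = 0.6, keep_weak = 0.001,
       decay_floor = 0.9, noise_sd = 0.08)
}

## One subject's reference network. `miss` is the structural-missing mask,
## `decay` a mild distance attenuation on non-community edges. Pair rules:
##   hub-hub          always present, strong (rich-club core)
##   hub-spoke        dense, strong (spokes hang off the core)
##   bridge-spoke     sparse, strong (bridges tie non-adjacent spokes)
##   within community always present, strong (detached cliques)
##   anything else    rare and weak
## The regimes place nodes in distinct corners of the (clustering,
## efficiency) plane: spokes (high C via the interconnected core they hang
## on, mid E), hubs (mid C, high E), bridges (low C - their spoke
## neighbours do not interconnect - mid E), detached cliques (high C, low
## E), isolates (0, low E).
.reference_network <- function(nodes, miss, decay, regimes) {
  n <- nrow(nodes)
  type <- sample(names(regimes$p_types), n, replace = TRUE,
                 prob = regimes$p_types)
  ## partition clique nodes into communities, DMN and non-DMN separately
  comm <- integer(n)
  next_id <- 1L
  for (pool in list(which(type == "clique" & nodes$dmn),
                    which(type == "clique" & !nodes$dmn))) {
    pool <- sample(pool)
    while (length(pool) > 0) {
      k <- min(sample(regimes$comm_size[1]:regimes$comm_size[2], 1),
               length(pool))
      comm[pool[seq_len(k)]] <- next_id
      next_id <- next_id + 1L
      pool <- pool[-seq_len(k)]
    }
  }
  same_comm <- outer(comm, comm, "==") & comm > 0
  is_t <- function(tt) type == tt
  pair <- function(a, b) outer(is_t(a), is_t(b)) | outer(is_t(b), is_t(a))

  ru <- function(rng) matrix(runif(n * n, rng[1], rng[2]), n, n)
  keep_p <- matrix(regimes$keep_weak, n, n)
  w <- ru(regimes$weak_w)
  sel <- pair("bridge", "spoke")
  keep_p[sel] <- regimes$keep_bridge_spoke
  w[sel] <- ru(regimes$bridge_w)[sel]
  sel <- pair("hub", "spoke")
  keep_p[sel] <- regimes$keep_hub_spoke
  w[sel] <- ru(regimes$core_w)[sel]
  sel <- outer(is_t("hub"), is_t("hub"), "&")
  keep_p[sel] <- 1
  w[sel] <- ru(regimes$core_w)[sel]
  keep <- matrix(runif(n * n), n, n) < keep_p
  w <- w * keep * decay
  cw <- ru(regimes$clique_w)
  w[same_comm] <- cw[same_comm]
  ## symmetrize from the upper triangle, jitter, cap, apply exclusions
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  ln <- matrix(rnorm(n * n, 0, regimes$noise_sd), n, n)
  ln[lower.tri(ln)] <- t(ln)[lower.tri(ln)]
  w <- pmin(w * exp(ln), 0.95)
  diag(w) <- 0
  w[miss] <- 0
  dimnames(w) <- list(nodes$node_id, nodes$node_id)
  connectivity_matrix(w, miss)
}

#' Simulate an oracle-mode synthetic cohort
#'
#' Generates a cohort whose edge strengths are drawn from the package's own
#' linear predictor with known coefficients, so model fitting has
#' recoverable ground truth. Procedure, deterministic given `truth$seed`:
#'
#' 1. For each subject, build a heterogeneous reference network
#'    ([reference_regimes()]) with mild distance attenuation
#'    `0.5 + 0.5 exp(-d/lambda_mm)` on background edges; pairs closer than
#'    `min_dist_mm` are structurally excluded.
#' 2. Compute each subject's nodal clustering and efficiency on that
#'    reference network and freeze them as the design covariates.
#' 3. Assemble the edge design over every non-missing pair and draw
#'    strengths `S = X beta + b_subject + eps`, `b ~ N(0, sigma_b^2)`,
#'    `eps ~ N(0, sigma_e^2)`, then clip to \[0, 1\].
#' 4. Return matrices whose weights are the simulated strengths, the frozen
#'    covariates, and the truth echo.
#'
#' Because the covariates are frozen from the reference networks (not
#' recomputed from the simulated strengths), refitting the model on the
#' returned design recovers `truth$beta` in expectation ("oracle mode").
#' For endogenous analysis — metrics recomputed from the simulated
#' matrices, as with real data — run the returned matrices back through
#' [compute_nodal_metrics()] and [build_edge_table()].
#'
#' @param nodes a [node_table()].
#' @param subjects a subject table.
#' @param truth a [ground_truth()]; its coefficient names select the model.
#' @param lambda_mm distance-attenuation length scale for background
#'   reference edges.
#' @param regimes reference-network regime parameters
#'   ([reference_regimes()]).
#' @param min_dist_mm structural-exclusion distance threshold.
#' @param clip clip simulated strengths to \[0, 1\] (default TRUE).
#' @return list of class `oracle_cohort`: nodes, subjects, truth, matrices
#'   (simulated strengths), metrics (frozen), edge_table, design (with the
#'   simulated response), clip_fraction.
#' @export
simulate_oracle_cohort <- function(nodes, subjects, truth,
                                   lambda_mm = 60,
                                   regimes = reference_regimes(),
                                   min_dist_mm = 20, clip = TRUE) {
  model <- if ("globalT" %in% names(truth$beta)) "model2" else "model1"
  terms <- model_terms(model)
  missing <- setdiff(terms, names(truth$beta))
  extra <- setdiff(names(truth$beta), terms)
  if (length(missing) || length(extra))
    stop("ground-truth coefficient names do not match the ", model,
         " design; missing: [", paste(missing, collapse = ", "),
         "]; unknown: [", paste(extra, collapse = ", "), "]")

  set.seed(truth$seed)
  n <- nrow(nodes)
  d <- node_distances(nodes)
  miss <- d < min_dist_mm
  diag(miss) <- FALSE
  decay <- regimes$decay_floor + (1 - regimes$decay_floor) * exp(-d / lambda_mm)

  ref <- lapply(subjects$subject_id, function(sid)
    .reference_network(nodes, miss, decay, regimes))
  names(ref) <- subjects$subject_id
  metrics <- lapply(ref, compute_nodal_metrics)

  ## The design covers every non-missing pair: the reference network only
  ## supplies the frozen metrics, while the response is drawn from the
  ## linear predictor (strictly positive in practice, so the same rows
  ## would be retained by the real-data rule).
  ones <- matrix(1, n, n)
  diag(ones) <- 0
  ones[miss] <- 0
  dimnames(ones) <- list(nodes$node_id, nodes$node_id)
  full <- connectivity_matrix(ones, miss)
  tab <- build_edge_table(setNames(rep(list(full), nrow(subjects)),
                                   subjects$subject_id),
                          metrics, subjects, nodes)
  design <- assemble_design_matrix(tab, model)
  beta <- truth$beta[design$terms]

  subj_f <- factor(design$subject, levels = subjects$subject_id)
  b <- rnorm(nlevels(subj_f), 0, truth$sigma_b)
  eps <- rnorm(length(design$y), 0, truth$sigma_e)
  s <- drop(design$X %*% beta) + b[as.integer(subj_f)] + eps
  clip_fraction <- mean(s < 0 | s > 1)
  if (clip) s <- pmin(pmax(s, 0), 1)

  tab$strength <- s
  design$y <- s

  sims <- lapply(subjects$subject_id, function(sid) {
    w <- matrix(0, n, n, dimnames = list(nodes$node_id, nodes$node_id))
    rows <- tab$subject_id == sid
    i <- match(tab$node_i[rows], nodes$node_id)
    j <- match(tab$node_j[rows], nodes$node_id)
    w[cbind(i, j)] <- s[rows]
    w[cbind(j, i)] <- s[rows]
    connectivity_matrix(w, miss)
  })
  names(sims) <- subjects$subject_id

  structure(list(nodes = nodes, subjects = subjects, truth = truth,
                 model = model, matrices = sims, metrics = metrics,
                 edge_table = tab, design = design,
                 clip_fraction = clip_fraction),
            class = "oracle_cohort")
}

#' Write the ground truth as JSON
#' @param truth a [ground_truth()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(beta = as.list(truth$beta),
                            sigma_e = truth$sigma_e,
                            sigma_b = truth$sigma_b, seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
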