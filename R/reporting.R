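.group_levels <- c("HIV-MJ-", "HIV+MJ-", "HIV-MJ+", "HIV+MJ+")

.group_indicators <- function(group) {
  hiv <- as.integer(group %in% c("HIV+MJ-", "HIV+MJ+"))
  mj <- as.integer(group %in% c("HIV-MJ+", "HIV+MJ+"))
  list(hiv = hiv, mj = mj, hivmj = hiv * mj)
}

.metric_term <- function(metric) if (metric == "clustering") "clust" else "eff"

## Within-DMN slope pieces shared by slope_lines / slope_surfaces so the
## reported slopes agree with the Wald contrast estimates exactly.
.within_slope <- function(fit, group, metric, moderated = FALSE) {
  m <- .metric_term(metric)
  pfx <- if (moderated) "globalT_x_" else ""
  base <- unname(fit$beta[paste0(pfx, m)] +
                   fit$beta[paste0(pfx, m, "_x_dmn_within")])
  if (group == "HIV-MJ-") return(base)
  L <- group_contrast_vector(fit$model, group, "within", metric,
                             moderated_by_globalT = moderated)
  base + sum(L * fit$beta[names(L)])
}

#' Per-group within-DMN slope lines
#'
#' The quantitative content of the group slope-line figure: for each group
#' and metric, the within-DMN slope of connection strength on the
#' (centered) metric, and the line intercept at the metric mean. The
#' control group's slope is `beta_metric + beta_metric_x_dmn_within`; each
#' other group's slope adds its fitted contrast estimate, so slope
#' differences equal the Wald contrast estimates exactly.
#'
#' @param fit a primary-model (`model1`) `netlmm_fit`.
#' @return data.frame: group, metric, slope, intercept, contrast_estimate,
#'   contrast_se (NA for the control group).
#' @export
slope_lines <- function(fit) {
  if (!identical(fit$model, "model1"))
    stop("slope_lines needs a model1 fit")
  need <- c("clust", "clust_x_dmn_within", "eff", "eff_x_dmn_within")
  if (!all(need %in% fit$terms))
    stop("fit is missing slope terms: ",
         paste(setdiff(need, fit$terms), collapse = ", "))
  grid <- expand.grid(group = .group_levels,
                      metric = c("clustering", "efficiency"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    gr <- grid$group[i]; met <- grid$metric[i]
    ind <- .group_indicators(gr)
    icpt <- unname(fit$beta["intercept"] + fit$beta["dmn_within"] +
                     ind$hiv * (fit$beta["hiv"] + fit$beta["hiv_x_dmn_within"]) +
                     ind$mj * (fit$beta["mj"] + fit$beta["mj_x_dmn_within"]) +
                     ind$hivmj * (fit$beta["hivmj"] + fit$beta["hivmj_x_dmn_within"]))
    if (gr == "HIV-MJ-") {
      ce <- NA_real_; cse <- NA_real_
    } else {
      w <- wald_test(fit, group_contrast_vector(fit$model, gr, "within", met))
      ce <- w$estimate; cse <- w$se
    }
    data.frame(group = gr, metric = met,
               slope = .within_slope(fit, gr, met), intercept = icpt,
               contrast_estimate = ce, contrast_se = cse,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' GlobalT slope surfaces
#'
#' For each group and metric, the within-DMN strength-vs-metric slope
#' evaluated along a grid of GlobalT values:
#' `slope(group, T) = base + group contrast + (T - Tbar) * (GlobalT
#' moderation base + group moderation contrast)`, where `Tbar` is the
#' GlobalT centering constant stored with the design. Because the model is
#' linear, each surface is affine in T.
#'
#' @param fit a secondary-model (`model2`) `netlmm_fit`.
#' @param globalT_grid strictly increasing vector of GlobalT values
#'   (default 35 to 65).
#' @return data.frame of class `slope_surface`: group, metric, globalT,
#'   slope.
#' @export
slope_surfaces <- function(fit, globalT_grid = seq(35, 65, by = 1)) {
  if (!identical(fit$model, "model2"))
    stop("slope_surfaces needs a model2 fit")
  if (any(diff(globalT_grid) <= 0))
    stop("globalT_grid must be strictly increasing")
  tbar <- unname(fit$centers["globalT"])
  grid <- expand.grid(group = .group_levels,
                      metric = c("clustering", "efficiency"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    gr <- grid$group[i]; met <- grid$metric[i]
    s0 <- .within_slope(fit, gr, met, moderated = FALSE)
    s1 <- .within_slope(fit, gr, met, moderated = TRUE)
    data.frame(group = gr, metric = met, globalT = globalT_grid,
               slope = s0 + (globalT_grid - tbar) * s1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("slope_surface", "data.frame")
  out
}

#' Representative network for a group at a GlobalT level
#'
#' Predicts each eligible edge's strength from the fixed effects with
#' edge-level covariates at their cohort means, subject covariates at the
#' cohort mean, the group indicators set for the requested group, and
#' GlobalT at the requested value; the top `retain_fraction` of edges by
#' predicted strength form the representative network. Node attributes
#' carry the group-mean nodal metrics (for sizing) and the group's
#' within-DMN slopes at that GlobalT (for coloring).
#'
#' @param fit a model2 `netlmm_fit`.
#' @param group one of the four group labels.
#' @param globalT_value GlobalT at which to evaluate (values far outside
#'   the cohort range trigger a warning).
#' @param cohort an `oracle_cohort` (or compatible list with edge_table,
#'   metrics, subjects, nodes).
#' @param retain_fraction fraction of eligible edges retained.
#' @return list: `nodes` (node_id, dmn, clustering, efficiency,
#'   slope_clustering, slope_efficiency), `edges` (node_i, node_j,
#'   predicted_strength), `group`, `globalT`.
#' @export
representative_network <- function(fit, group, globalT_value, cohort,
                                   retain_fraction = 0.15) {
  if (!identical(fit$model, "model2"))
    stop("representative_network needs a model2 fit")
  group <- match.arg(group, .group_levels)
  rng <- fit$globalT_range
  if (!is.null(rng) && (globalT_value < rng[1] - 5 || globalT_value > rng[2] + 5))
    warning(sprintf("globalT %.1f is far outside the observed range [%.1f, %.1f]",
                    globalT_value, rng[1], rng[2]))
  tab <- cohort$edge_table
  key <- paste(tab$node_i, tab$node_j, sep = "|")
  agg <- function(v) tapply(v, key, mean)
  edges <- data.frame(
    clust = as.numeric(agg(tab$clust)), eff = as.numeric(agg(tab$eff)),
    dist = as.numeric(agg(tab$dist)), dist2 = as.numeric(agg(tab$dist2)),
    dmn_within = as.numeric(agg(tab$dmn_within)),
    dmn_between = as.numeric(agg(tab$dmn_between)),
    stringsAsFactors = FALSE)
  pair <- do.call(rbind, strsplit(names(agg(tab$clust)), "|", fixed = TRUE))
  ind <- .group_indicators(group)
  edges$hiv <- ind$hiv; edges$mj <- ind$mj; edges$hivmj <- ind$hivmj
  edges$globalT <- globalT_value - unname(fit$centers["globalT"])
  edges$age <- 0; edges$education <- 0; edges$rmd <- 0  # centered means
  edges$sex <- mean(tab$sex); edges$race <- mean(tab$race)
  X <- .term_columns(edges, fit$terms)
  pred <- drop(X %*% fit$beta)
  n_keep <- max(1L, as.integer(round(retain_fraction * length(pred))))
  top <- order(pred, decreasing = TRUE)[seq_len(n_keep)]
  edge_out <- data.frame(node_i = pair[top, 1], node_j = pair[top, 2],
                         predicted_strength = pred[top],
                         stringsAsFactors = FALSE)

  in_group <- cohort$subjects$subject_id[
    .group_indicators(group)$hiv == cohort$subjects$hiv &
      .group_indicators(group)$mj == cohort$subjects$mj]
  met <- cohort$metrics[in_group]
  cl <- rowMeans(sapply(met, function(m)
    m$clustering[match(cohort$nodes$node_id, m$node_id)]))
  ef <- rowMeans(sapply(met, function(m)
    m$efficiency[match(cohort$nodes$node_id, m$node_id)]))
  surf <- slope_surfaces(fit, globalT_grid = globalT_value)
  sl <- function(metric) surf$slope[surf$group == group & surf$metric == metric]
  nodes_out <- data.frame(node_id = cohort$nodes$node_id,
                          dmn = cohort$nodes$dmn,
                          clustering = cl, efficiency = ef,
                          slope_clustering = sl("clustering"),
                          slope_efficiency = sl("efficiency"),
                          stringsAsFactors = FALSE)
  list(nodes = nodes_out, edges = edge_out, group = group,
       globalT = globalT_value)
}

#' Group network-density comparison
#'
#' Per-subject network density ([network_density()]) summarized by group,
#' with Welch two-tailed t-tests of each group against the control. In a
#' well-calibrated cohort the densities should be nearly identical across
#' groups.
#'
#' @param cohort an `oracle_cohort` (or list with matrices + subjects).
#' @return list: `summary` (group, n, mean, sd), `tests` (group,
#'   diff_vs_control, t, p).
#' @export
group_density_comparison <- function(cohort) {
  subj <- cohort$subjects
  if (length(unique(subj$group)) < 2)
    stop("need at least two groups to compare densities")
  dens <- vapply(subj$subject_id,
                 function(sid) network_density(cohort$matrices[[sid]]),
                 numeric(1))
  groups <- unique(subj$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- dens[subj$group == g]
    if (length(v) < 2) stop("need >= 2 subjects per group")
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v),
               stringsAsFactors = FALSE)
  }))
  ctrl <- dens[subj$group == "HIV-MJ-"]
  tests <- do.call(rbind, lapply(setdiff(groups, "HIV-MJ-"), function(g) {
    v <- dens[subj$group == g]
    if (sd(v) == 0 && sd(ctrl) == 0) {
      p <- if (isTRUE(all.equal(mean(v), mean(ctrl)))) 1 else 0
      tt <- 0
    } else {
      ht <- t.test(v, ctrl)
      p <- ht$p.value; tt <- unname(ht$statistic)
    }
    data.frame(group = g, diff_vs_control = mean(v) - mean(ctrl),
               t = tt, p = p, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}

#' Write slope grids / representative networks as TSV
#' @param x a data.frame output (slope lines, slope surface).
#' @param path file path.
#' @export
write_report_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_table
#' @param net a [representative_network()] result.
#' @param node_path,edge_path output paths.
#' @export
write_representative_network <- function(net, node_path, edge_path) {
  write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(node_path)
}
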