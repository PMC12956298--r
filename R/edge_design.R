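## Canonical fixed-effect term naming: components joined by "_x_".
## Components: hiv, mj, hivmj (group indicators); clust, eff (endpoint-
## averaged, centered nodal metrics); dmn_within, dmn_between (edge-class
## indicators, outside-DMN edges are the reference); globalT (centered);
## confounders dist, dist2, age, sex, race, education, rmd.

.groups  <- c("hiv", "mj", "hivmj")
.metrics <- c("clust", "eff")
.dmn_ind <- c("dmn_within", "dmn_between")

.cross <- function(a, b) as.vector(t(outer(a, b, paste, sep = "_x_")))

#' Canonical fixed-effect term names
#'
#' Enumerates the fixed-effect columns of the two edge-level models. The
#' primary model (`model1`, 43 terms) contains the group indicators (HIV,
#' MJ, HIVMJ), the two network-metric covariates, the DMN edge-class
#' indicators, the confounders (distance, squared distance, age, sex, race,
#' education, head motion), and all group x metric, group x DMN,
#' metric x DMN and group x metric x DMN interactions. The secondary model
#' (`model2`, 79 terms) appends GlobalT and its products with every one of
#' those term families.
#'
#' @param model `"model1"` or `"model2"`.
#' @return character vector of term names, in canonical column order.
#' @export
model_terms <- function(model = c("model1", "model2")) {
  model <- match.arg(model)
  g <- .groups; m <- .metrics; i <- .dmn_ind
  base <- c("intercept", g, m, i, "dist", "dist2",
            "age", "sex", "race", "education", "rmd")
  gm <- .cross(g, m); gi <- .cross(g, i); mi <- .cross(m, i)
  gmi <- .cross(g, mi)
  terms <- c(base, gm, gi, mi, gmi)
  if (model == "model2")
    terms <- c(terms, "globalT",
               paste0("globalT_x_", c(g, m, i, mi, gm, gi, gmi)))
  terms
}

## Evaluate term columns from a data frame holding the base covariates
## (already centered where applicable). Interaction columns are products of
## their components.
.term_columns <- function(df, terms) {
  n <- nrow(df)
  X <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (tm in terms) {
    if (tm == "intercept") { X[, tm] <- 1; next }
    parts <- strsplit(tm, "_x_", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(df))
    if (length(miss))
      stop("term '", tm, "' needs missing covariate(s): ",
           paste(miss, collapse = ", "))
    X[, tm] <- Reduce(`*`, df[parts])
  }
  X
}

#' Assemble the long-format edge design table
#'
#' One row per (subject, retained edge): retained edges are the node pairs
#' that are not structurally missing and carry strictly positive strength.
#' Edge-level covariates are the endpoint-averaged nodal metrics, the
#' Euclidean centroid distance and its square (squared before centering),
#' and the edge class (within_dmn / between / outside). Subject covariates
#' are attached to every row. All continuous covariates — the network
#' metrics included — are centered by their grand mean over the rows;
#' binary indicators stay 0/1. Centering constants are stored in
#' `attr(, "centers")`.
#'
#' @param matrices named list of filtered [connectivity_matrix()] objects,
#'   names = subject ids.
#' @param metrics named list of [compute_nodal_metrics()] data frames,
#'   same names.
#' @param subjects subject table covering all matrix names.
#' @param nodes the shared [node_table()].
#' @return data.frame of class `edge_design_table`.
#' @export
build_edge_table <- function(matrices, metrics, subjects, nodes) {
  subj_ids <- names(matrices)
  if (is.null(subj_ids)) stop("matrices must be a named list (subject ids)")
  missing_m <- setdiff(subj_ids, names(metrics))
  if (length(missing_m))
    stop("no nodal metrics for subject(s): ", paste(missing_m, collapse = ", "))
  missing_s <- setdiff(subj_ids, subjects$subject_id)
  if (length(missing_s))
    stop("no covariates for subject(s): ", paste(missing_s, collapse = ", "))

  d <- node_distances(nodes)
  up <- which(upper.tri(d), arr.ind = TRUE)
  dmn <- nodes$dmn
  n_dmn_ends <- dmn[up[, 1]] + dmn[up[, 2]]
  edge_class_all <- c("outside", "between", "within_dmn")[n_dmn_ends + 1L]

  pieces <- lapply(subj_ids, function(sid) {
    cm <- matrices[[sid]]
    if (!identical(cm$nodes, nodes$node_id))
      stop("matrix node order mismatch for subject ", sid)
    met <- metrics[[sid]]
    met <- met[match(nodes$node_id, met$node_id), ]
    w <- cm$weights[up]
    keep <- !cm$structural_missing[up] & w > 0
    if (!any(keep)) return(NULL)
    i <- up[keep, 1]; j <- up[keep, 2]
    data.frame(
      subject_id = sid,
      node_i = nodes$node_id[i], node_j = nodes$node_id[j],
      strength = w[keep],
      clust = (met$clustering[i] + met$clustering[j]) / 2,
      eff = (met$efficiency[i] + met$efficiency[j]) / 2,
      dist = d[up][keep],
      dist2 = d[up][keep]^2,
      edge_class = edge_class_all[keep],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, pieces)
  if (is.null(tab) || nrow(tab) == 0) stop("no retained edges in any subject")

  si <- match(tab$subject_id, subjects$subject_id)
  tab$hiv <- subjects$hiv[si]
  tab$mj <- subjects$mj[si]
  tab$hivmj <- tab$hiv * tab$mj
  tab$globalT <- subjects$globalT[si]
  tab$age <- subjects$age[si]
  tab$sex <- subjects$sex[si]
  tab$race <- subjects$race[si]
  tab$education <- subjects$education[si]
  tab$rmd <- subjects$rmd[si]
  tab$dmn_within <- as.integer(tab$edge_class == "within_dmn")
  tab$dmn_between <- as.integer(tab$edge_class == "between")

  cont <- c("clust", "eff", "dist", "dist2", "globalT", "age",
            "education", "rmd")
  centers <- vapply(tab[cont], mean, numeric(1))
  for (v in cont) tab[[v]] <- tab[[v]] - centers[[v]]

  attr(tab, "centers") <- centers
  attr(tab, "globalT_range") <- range(subjects$globalT[si])
  rownames(tab) <- NULL
  class(tab) <- c("edge_design_table", "data.frame")
  tab
}

#' Assemble a fixed-effect design matrix
#'
#' Expands an edge design table into the named fixed-effect matrix of the
#' requested model ([model_terms()]). Interaction columns are products of
#' the already-centered parent columns, so the column order and values are
#' bit-reproducible from the same table.
#'
#' @param table an `edge_design_table` from [build_edge_table()].
#' @param model `"model1"` (43 columns) or `"model2"` (79 columns).
#' @return object of class `design_matrix`: list with `X` (matrix), `y`
#'   (strength response), `subject` (grouping vector), `terms`, `model`,
#'   `centers`, `globalT_range`.
#' @export
assemble_design_matrix <- function(table, model = c("model1", "model2")) {
  model <- match.arg(model)
  if (nrow(table) == 0) stop("edge table is empty")
  terms <- model_terms(model)
  X <- .term_columns(table, terms)
  rng <- apply(X[, terms != "intercept", drop = FALSE], 2,
               function(col) diff(range(col)))
  if (any(rng == 0))
    stop("constant design column(s): ",
         paste(names(rng)[rng == 0], collapse = ", "))
  structure(list(X = X, y = table$strength,
                 subject = table$subject_id, terms = terms, model = model,
                 centers = attr(table, "centers"),
                 globalT_range = attr(table, "globalT_range")),
            class = "design_matrix")
}

#' Write the edge design table as TSV (and its column manifest as JSON)
#' @param table edge design table.
#' @param path TSV path.
#' @param manifest_path optional JSON path for the design column manifest.
#' @param model model whose term list goes in the manifest.
#' @export
write_edge_table <- function(table, path, manifest_path = NULL,
                             model = "model1") {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(list(model = model, terms = model_terms(model),
                              centers = as.list(attr(table, "centers"))),
                         manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
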