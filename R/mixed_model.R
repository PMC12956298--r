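#' Fit the edge-level linear mixed model
#'
#' Fits `S = X beta + b_subject + eps` with a subject random intercept,
#' `b ~ N(0, sigma_b^2)` and `eps ~ N(0, sigma_e^2)`, by restricted maximum
#' likelihood (ML by flag). For this structure the marginal covariance is
#' block diagonal, `V_k = sigma_e^2 (I + theta J_k)` with
#' `theta = sigma_b^2 / sigma_e^2`, so the likelihood is profiled down to a
#' one-dimensional optimization over `theta` using Sherman–Morrison
#' identities on per-subject cross-products — exact, and fast enough for
#' hundreds of replicate fits. Fixed-effect covariance is
#' `sigma_e^2 (X' V^-1 X)^-1`.
#'
#' @param design a `design_matrix` from [assemble_design_matrix()] (or any
#'   list with `X`, `y`, `subject`, `terms`).
#' @param reml REML (default) or ML.
#' @param tol relative convergence tolerance for the profiled
#'   log-likelihood optimization.
#' @return object of class `netlmm_fit`: `beta` (named estimates), `vcov`,
#'   `sigma_e`, `sigma_b`, `theta`, `loglik` (restricted or full),
#'   `n_rows`, `n_subjects`, `terms`, `model`, `centers`,
#'   `globalT_range`, `converged`.
#' @export
fit_lmm <- function(design, reml = TRUE, tol = 1e-8) {
  X <- design$X; y <- design$y
  f <- factor(design$subject)
  N <- nrow(X); p <- ncol(X); K <- nlevels(f)
  if (K < 2) stop("need at least 2 subjects")

  ## Internal column scaling: covariate magnitudes span orders of
  ## magnitude (squared distances vs three-way interaction products), so
  ## the cross-products are equilibrated before factorization and the
  ## estimates unscaled afterwards.
  sc <- sqrt(colMeans(X^2))
  if (any(sc == 0))
    stop("design has all-zero column(s): ",
         paste(colnames(X)[sc == 0], collapse = ", "))
  X <- sweep(X, 2, sc, "/")

  XtX <- crossprod(X)
  qrX <- qr(XtX, tol = 1e-12)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  G <- rowsum(X, f)                      # K x p per-subject column sums
  gy <- rowsum(y, f)[, 1]
  nk <- tabulate(f)

  bad <- FALSE
  profile <- function(theta) {
    ck <- theta / (1 + theta * nk)
    A <- XtX - crossprod(G * sqrt(ck))
    u <- Xty - crossprod(G, ck * gy)
    yVy <- yty - sum(ck * gy^2)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), u))
    rss <- max(yVy - sum(beta * u), .Machine$double.xmin)
    logdetV <- sum(log1p(theta * nk))
    if (reml) {
      crit <- (N - p) * log(rss / (N - p)) + logdetV +
        2 * sum(log(diag(R)))
    } else {
      crit <- N * log(rss / N) + logdetV
    }
    list(crit = crit, beta = drop(beta), rss = rss, R = R)
  }
  obj <- function(ltheta) {
    pr <- profile(exp(ltheta))
    if (is.null(pr) || !is.finite(pr$crit)) { bad <<- TRUE; return(1e12) }
    pr$crit
  }

  opt <- optimize(obj, interval = c(-20, 10), tol = tol)
  theta <- exp(opt$minimum)
  pr <- profile(theta)
  pr0 <- profile(0)
  if (!is.null(pr0) && (is.null(pr) || pr0$crit <= pr$crit)) {
    theta <- 0; pr <- pr0
  }
  converged <- !bad && !is.null(pr) && is.finite(pr$crit)
  if (!converged)
    warning("profiled REML optimization did not converge cleanly; ",
            "estimates returned with converged = FALSE")

  dfree <- if (reml) N - p else N
  sigma_e2 <- pr$rss / dfree
  vcov <- sigma_e2 * chol2inv(pr$R) / tcrossprod(sc)
  beta <- pr$beta / sc
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  loglik <- -0.5 * (pr$crit + dfree * (1 + log(2 * pi)))

  structure(list(beta = beta, vcov = vcov,
                 sigma_e = sqrt(sigma_e2),
                 sigma_b = sqrt(theta * sigma_e2),
                 theta = theta, loglik = loglik, reml = reml,
                 n_rows = N, n_subjects = K,
                 terms = colnames(X),
                 model = design$model,
                 centers = design$centers,
                 globalT_range = design$globalT_range,
                 converged = converged),
            class = "netlmm_fit")
}

#' @export
print.netlmm_fit <- function(x, ...) {
  cat(sprintf("netlmm_fit (%s, %s): %d rows, %d subjects, %d fixed effects\n",
              if (is.null(x$model)) "custom design" else x$model,
              if (x$reml) "REML" else "ML",
              x$n_rows, x$n_subjects, length(x$beta)))
  cat(sprintf("  sigma_e = %.5f, sigma_b = %.5f, logLik = %.2f, converged = %s\n",
              x$sigma_e, x$sigma_b, x$loglik, x$converged))
  invisible(x)
}

#' Contrast vector for a group slope difference
#'
#' Builds the linear combination L of fixed effects whose estimate is a
#' group's slope difference vs the HIV-MJ- control, for one metric and DMN
#' location. With the HIV/MJ/HIVMJ coding, HIV+MJ- uses the hiv terms
#' only, HIV-MJ+ the mj terms, and HIV+MJ+ the sum of hiv, mj and hivmj
#' terms. `location = "outside"` uses the group x metric terms; `"within"`
#' adds the group x metric x dmn_within terms. With
#' `moderated_by_globalT = TRUE` (secondary model only) the same pattern is
#' applied to the GlobalT-product terms, testing the group difference in
#' how GlobalT moderates the slope.
#'
#' @param model `"model1"` or `"model2"`.
#' @param group `"HIV+MJ-"`, `"HIV-MJ+"` or `"HIV+MJ+"`.
#' @param location `"within"` or `"outside"`.
#' @param metric `"clustering"` or `"efficiency"`.
#' @param moderated_by_globalT test the GlobalT moderation instead of the
#'   group main slope difference.
#' @return named numeric contrast vector over [model_terms()] (mostly 0).
#' @export
group_contrast_vector <- function(model = c("model1", "model2"),
                                  group = c("HIV+MJ-", "HIV-MJ+", "HIV+MJ+"),
                                  location = c("within", "outside"),
                                  metric = c("clustering", "efficiency"),
                                  moderated_by_globalT = FALSE) {
  model <- match.arg(model)
  group <- match.arg(group)
  location <- match.arg(location)
  metric <- match.arg(metric)
  if (moderated_by_globalT && model != "model2")
    stop("GlobalT moderation contrasts require model2")
  terms <- model_terms(model)
  L <- setNames(rep(0, length(terms)), terms)
  gset <- switch(group, "HIV+MJ-" = "hiv", "HIV-MJ+" = "mj",
                 "HIV+MJ+" = c("hiv", "mj", "hivmj"))
  m <- if (metric == "clustering") "clust" else "eff"
  pfx <- if (moderated_by_globalT) "globalT_x_" else ""
  sel <- paste0(pfx, gset, "_x_", m)
  if (location == "within")
    sel <- c(sel, paste0(sel, "_x_dmn_within"))
  unknown <- setdiff(sel, terms)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  L[sel] <- 1
  L
}

#' Wald test of a contrast
#'
#' Estimate `L'beta`, standard error `sqrt(L'VL)`, z statistic and
#' two-sided normal p-value for a fixed contrast vector. The normal
#' approximation is appropriate at edge-regression sample sizes (tens of
#' thousands of rows and more).
#'
#' @param fit a `netlmm_fit`.
#' @param L named contrast vector; names must be fit terms. Must not be
#'   all-zero.
#' @param label optional label carried into the result.
#' @return one-row data.frame of class `contrast_result`: label, estimate,
#'   se, z, p, p_adj (NA until FDR adjustment).
#' @export
wald_test <- function(fit, L, label = NA_character_) {
  if (is.null(names(L))) stop("L must be named")
  unknown <- setdiff(names(L), fit$terms)
  if (length(unknown))
    stop("unknown term(s) in contrast: ", paste(unknown, collapse = ", "))
  full <- setNames(rep(0, length(fit$terms)), fit$terms)
  full[names(L)] <- L
  if (all(full == 0)) stop("contrast vector is all zeros")
  est <- sum(full * fit$beta)
  se <- sqrt(drop(t(full) %*% fit$vcov %*% full))
  z <- est / se
  p <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)
  out <- data.frame(label = label, estimate = est, se = se, z = z, p = p,
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Evaluate the full set of group contrasts
#'
#' Computes the 12 slope-difference contrasts (3 groups x 2 DMN locations
#' x 2 metrics) against the control group and adjusts their p-values
#' together with the two-stage adaptive FDR, mirroring the layout of a
#' group-difference results table.
#'
#' @param fit a `netlmm_fit` of model1 or model2.
#' @param moderated_by_globalT evaluate the GlobalT-moderation contrasts
#'   (model2 only).
#' @param q FDR level.
#' @return data.frame of class `contrast_table`: group, location, metric,
#'   estimate, se, z, p, p_adj, reject.
#' @export
evaluate_group_contrasts <- function(fit, moderated_by_globalT = FALSE,
                                     q = 0.05) {
  model <- fit$model
  grid <- expand.grid(group = c("HIV+MJ-", "HIV-MJ+", "HIV+MJ+"),
                      location = c("within", "outside"),
                      metric = c("clustering", "efficiency"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    L <- group_contrast_vector(model, grid$group[i], grid$location[i],
                               grid$metric[i], moderated_by_globalT)
    wald_test(fit, L, label = sprintf("%s / %s DMN / %s", grid$group[i],
                                      grid$location[i], grid$metric[i]))
  })
  out <- cbind(grid, do.call(rbind, res)[, c("estimate", "se", "z", "p")])
  fdr <- adaptive_fdr(out$p, q = q)
  out$p_adj <- fdr$p_adj
  out$reject <- fdr$reject
  class(out) <- c("contrast_table", "data.frame")
  out
}

## Benjamini-Hochberg step-up rejection set at level alpha.
.bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- ps <= alpha * seq_len(m) / m
  if (!any(below)) return(logical(m))
  r <- max(which(below))
  p <= ps[r]
}

## Two-stage adaptive step-up rejection set at level q: stage 1 BH at
## q/(1+q) estimates the number of true nulls m0 = m - r1; if r1 = 0
## nothing is rejected, if m0 = 0 everything is; otherwise stage 2 is BH
## at q * m / m0.
.adaptive_reject <- function(p, q) {
  m <- length(p)
  r1 <- sum(.bh_reject(p, q / (1 + q)))
  if (r1 == 0) return(logical(m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  .bh_reject(p, q * m / m0)
}

#' Two-stage adaptive FDR correction
#'
#' Adaptive (two-stage) linear step-up procedure: a first Benjamini-
#' Hochberg pass at level q/(1+q) estimates the number of true null
#' hypotheses, and a second pass at the inflated level q*m/m0 performs the
#' final step-up. Adjusted p-values are the smallest q at which each
#' hypothesis would be rejected (found by bisection, capped at 1).
#'
#' @param pvals p-values in (0, 1].
#' @param q FDR level for the rejection flags.
#' @return list: `p_adj` (numeric), `reject` (logical at level `q`).
#' @export
adaptive_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0)
    return(list(p_adj = numeric(0), reject = logical(0)))
  if (any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  reject <- .adaptive_reject(pvals, q)
  p_adj <- vapply(seq_along(pvals), function(i) {
    if (!.adaptive_reject(pvals, 1)[i]) return(1)
    lo <- 0; hi <- 1
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      if (.adaptive_reject(pvals, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  list(p_adj = p_adj, reject = reject)
}

#' Collinearity diagnostic for contrast terms
#'
#' Pearson correlation between each (centered) network-metric column and
#' each of its interaction columns in the assembled design — the terms the
#' contrast statements combine. Pairs with |r| > `flag_at` are flagged as
#' problematic collinearity.
#'
#' @param design a `design_matrix`.
#' @param contrast_terms optional subset of interaction terms to check
#'   (default: every interaction column involving a metric).
#' @param flag_at flag threshold on |r|.
#' @return data.frame: metric, term, r, flagged; plus `max_abs_r`
#'   attribute.
#' @export
collinearity_check <- function(design, contrast_terms = NULL,
                               flag_at = 0.95) {
  terms <- colnames(design$X)
  rows <- list()
  for (m in c("clust", "eff")) {
    inter <- terms[grepl("_x_", terms, fixed = TRUE) &
                     vapply(strsplit(terms, "_x_", fixed = TRUE),
                            function(p) m %in% p, logical(1))]
    if (!is.null(contrast_terms)) inter <- intersect(inter, contrast_terms)
    for (tm in inter) {
      r <- suppressWarnings(cor(design$X[, m], design$X[, tm]))
      if (is.na(r)) r <- 1  # constant duplicated column
      rows[[length(rows) + 1L]] <-
        data.frame(metric = m, term = tm, r = r,
                   flagged = abs(r) > flag_at, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_abs_r") <- max(abs(out$r))
  out
}

#' Write a fit summary as JSON / a contrast table as TSV
#' @param fit a `netlmm_fit`.
#' @param path file path.
#' @export
write_fit_summary <- function(fit, path) {
  jsonlite::write_json(list(beta = as.list(fit$beta),
                            se = as.list(sqrt(diag(fit$vcov))),
                            sigma_e = fit$sigma_e, sigma_b = fit$sigma_b,
                            loglik = fit$loglik, reml = fit$reml,
                            n_rows = fit$n_rows,
                            n_subjects = fit$n_subjects,
                            converged = fit$converged),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_summary
#' @param contrasts a `contrast_table` from [evaluate_group_contrasts()].
#' @export
write_contrast_table <- function(contrasts, path) {
  write.table(as.data.frame(contrasts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
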