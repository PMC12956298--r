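# Brute-force oracles, written independently of the package implementation:
# plain loops for the Onnela clustering formula, and exhaustive simple-path
# enumeration for weighted shortest paths. Only usable at toy sizes.

bf_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  out <- numeric(n)
  if (mx == 0) return(out)
  wh <- w / mx
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# All-pairs shortest paths by enumerating every simple path (n <= 7).
bf_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  len <- ifelse(w > 0, 1 / w, Inf)
  explore <- function(current, target, visited, acc) {
    if (current == target) {
      d[visited[1], target] <<- min(d[visited[1], target], acc)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!(nxt %in% visited) && is.finite(len[current, nxt])) {
        explore(nxt, target, c(visited, nxt), acc + len[current, nxt])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) explore(i, j, i, 0)
  }
  d
}

bf_efficiency <- function(w) {
  d <- bf_shortest_paths(w)
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# Random symmetric nonnegative weight matrix on n nodes with weights drawn
# from `levels` (0 = absent edge).
random_weight_matrix <- function(n, levels = c(0, 0.25, 0.5, 1)) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  w[up] <- sample(levels, sum(up), replace = TRUE)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

# Enumerate every weighted graph on n nodes with edge states `levels`
# (including absent), invoking fn(w) for each. 4 states on n = 4 gives
# 4^6 = 4096 graphs.
for_all_graphs <- function(n, levels, fn) {
  m <- n * (n - 1) / 2
  k <- length(levels)
  idx <- rep(1L, m)
  repeat {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- levels[idx]
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    fn(w)
    pos <- 1L
    while (pos <= m && idx[pos] == k) { idx[pos] <- 1L; pos <- pos + 1L }
    if (pos > m) break
    idx[pos] <- idx[pos] + 1L
  }
}

# A small cohort for integration-style tests (memoized per session).
.test_env <- new.env()
small_cohort <- function(model = "model1", seed = 7, n_per_group = 4,
                         n_nodes = 30, n_dmn = 8, ...) {
  key <- paste(model, seed, n_per_group, n_nodes, n_dmn, sep = "_")
  if (is.null(.test_env[[key]])) {
    nodes <- generate_node_layout(n_nodes, n_dmn, 160, seed = seed)
    subj <- generate_subject_table(n_per_group, seed = seed)
    truth <- oracle_truth(model, seed = seed, ...)
    .test_env[[key]] <- simulate_oracle_cohort(nodes, subj, truth)
  }
  .test_env[[key]]
}

# A fabricated model fit with chosen coefficients (identity-scaled vcov),
# for exercising reporting algebra without a simulation.
fake_fit <- function(model, beta_overrides = list(), vcov_scale = 1e-6,
                     centers = c(globalT = 49), globalT_range = c(35, 65)) {
  terms <- model_terms(model)
  beta <- setNames(rep(0, length(terms)), terms)
  for (nm in names(beta_overrides)) beta[nm] <- beta_overrides[[nm]]
  structure(list(beta = beta,
                 vcov = diag(vcov_scale, length(terms)) |>
                   `dimnames<-`(list(terms, terms)),
                 sigma_e = 0.05, sigma_b = 0.02, theta = 0.16,
                 loglik = 0, reml = TRUE, n_rows = 1000, n_subjects = 10,
                 terms = terms, model = model, centers = centers,
                 globalT_range = globalT_range, converged = TRUE),
            class = "netlmm_fit")
}
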