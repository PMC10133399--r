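# Independent oracles, deliberately coded without the package's fitting or
# filtering routines: hand-built design matrices solved by normal equations,
# and a cache-free brute-force percolation grid search.

# Hand-built treatment-coded design for y ~ 1 + x + group + x:group.
oracle_design <- function(x, group) {
  lev <- levels(group)
  X <- cbind(1, x)
  for (g in lev[-1L]) X <- cbind(X, as.numeric(group == g))
  for (g in lev[-1L]) X <- cbind(X, x * as.numeric(group == g))
  X
}

# Normal-equations fit + F-distribution test of the interaction block.
oracle_interaction_fit <- function(x, y, group) {
  group <- droplevels(if (is.factor(group)) group else factor(group))
  lev <- levels(group)
  k <- length(lev)
  n <- length(y)
  X1 <- oracle_design(x, group)
  X0 <- X1[, seq_len(k + 1L), drop = FALSE]  # no interaction columns
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  b0 <- solve(crossprod(X0), crossprod(X0, y))
  rss1 <- sum((y - X1 %*% b1)^2)
  rss0 <- sum((y - X0 %*% b0)^2)
  df_num <- k - 1L
  df_den <- n - 2L * k
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  list(beta = drop(b1), f = f, df_num = df_num, df_den = df_den,
       p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

# Nearest-rank percentile cut-off, independent implementation.
oracle_cutoff <- function(w, pct) {
  if (pct <= 0) return(-Inf)
  sort(w)[ceiling(pct / 100 * length(w))]
}

# Cache-free brute-force percolation grid search: re-filters and re-fits
# every surviving edge at every percentile.
oracle_grid_search <- function(network, expr, metadata, grid, alpha = 0.05,
                               robust = TRUE) {
  groups <- levels(metadata$group)
  nodes <- unique(c(network$source, network$target))
  counts <- integer(length(grid))
  for (j in seq_along(grid)) {
    per_group <- list()
    for (g in groups) {
      samples <- metadata$sample_id[metadata$group == g]
      w <- rowMeans(expr[nodes, samples, drop = FALSE], na.rm = TRUE)
      w[is.nan(w)] <- -Inf
      keepn <- nodes[w >= oracle_cutoff(w, grid[j])]
      keep <- network$source %in% keepn & network$target %in% keepn
      per_group[[g]] <- paste(network$source, network$target,
                              sep = "|")[keep]
    }
    tab <- table(unlist(lapply(per_group, unique)))
    specific_keys <- names(tab)[tab == 1L]
    n_sig <- 0L
    for (g in groups) {
      for (key in intersect(per_group[[g]], specific_keys)) {
        st <- strsplit(key, "|", fixed = TRUE)[[1L]]
        idx <- which(network$source == st[1L] & network$target == st[2L])[1L]
        pd <- build_pair_data(expr, metadata, network[idx, ])
        fit <- if (robust) fit_robust_interaction(pd)
               else fit_ols_interaction(pd)
        if (!is.na(fit$p_interaction) && fit$p_interaction < alpha)
          n_sig <- n_sig + 1L
      }
    }
    counts[j] <- n_sig
  }
  list(grid = grid, counts = counts, chosen = grid[which.max(counts)])
}

# Seeded two-group dataset with a planted slope difference, for fit tests.
make_pair <- function(n_per_group, beta3 = 0, slope = 1, intercept = 1,
                      noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_group
  group <- factor(rep(c("A", "B"), each = n_per_group))
  x <- rnorm(n)
  slope_vec <- ifelse(group == "B", slope + beta3, slope)
  y <- intercept + slope_vec * x + rnorm(n, sd = noise_sd)
  structure(list(x = x, y = y, group = group, n = n, predictor = "GX",
                 response = "GY", degenerate = FALSE,
                 reason = NA_character_),
            class = "pair_data")
}
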