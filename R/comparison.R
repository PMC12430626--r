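## Method comparison: relative errors against the multi-method mean,
## pairwise Wilcoxon signed-rank tests and Spearman rank correlations over
## per-species estimates.

#' Relative errors of method totals against their mean
#'
#' For method totals `X_m`, the baseline is the arithmetic mean `mu` of all
#' supplied totals and the signed relative error of each method is
#' `(X_m - mu) / mu x 100` percent.
#'
#' @param method_totals Named numeric vector of per-method carbon totals
#'   (tC), at least two.
#' @return A tibble with `method`, `total_tC`, `mean_tC`,
#'   `relative_error_pct`.
#' @export
#' @examples
#' relative_errors(c(a = 1, b = 3))
relative_errors <- function(method_totals) {
  if (length(method_totals) < 2) {
    abort("Need at least two method totals.")
  }
  mu <- mean(method_totals)
  if (mu == 0) {
    abort("Mean of method totals is zero; relative errors are undefined.")
  }
  tibble::tibble(
    method = names(method_totals) %||% paste0("method_", seq_along(method_totals)),
    total_tC = unname(method_totals),
    mean_tC = mu,
    relative_error_pct = (unname(method_totals) - mu) / mu * 100
  )
}

# exact two-sided signed-rank p-value by dynamic programming over doubled
# mid-ranks (doubling makes tied mid-ranks integral); all 2^n sign
# assignments are equally likely under the null
signed_rank_exact_p <- function(r2, w2_obs) {
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  p_le <- sum(probs[seq_len(w2_obs + 1)])
  p_ge <- sum(probs[seq.int(w2_obs + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

# one two-sided Wilcoxon signed-rank test; exact null for n_eff <= exact_max
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[d != 0]  # classical zero-drop rule
  n <- length(d)
  if (n == 0) {
    warn("All paired differences are zero; p = 1.")
    return(list(p = 1, n_eff = 0L, statistic = NA_real_, exact = TRUE))
  }
  r <- rank(abs(d))  # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(r2, as.integer(round(2 * w_pos)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(p = p, n_eff = n, statistic = w_pos, exact = exact)
}

#' Pairwise Wilcoxon signed-rank tests across method columns
#'
#' Two-sided signed-rank tests for every pair of columns of a per-group
#' estimate matrix (groups x methods). Zero differences are dropped
#' (Wilcoxon's original rule; the effective n is reported), tied absolute
#' differences are mid-ranked, and the null distribution is exact (full
#' sign-assignment distribution) for effective n up to 25, with a
#' tie-corrected normal approximation above.
#'
#' @param per_species_matrix Numeric matrix or data frame, one row per
#'   group (species), one named column per method.
#' @return A tibble with `method_a`, `method_b`, `statistic` (W+), `n_eff`,
#'   `p_value`, `exact`.
#' @export
pairwise_wilcoxon <- function(per_species_matrix) {
  m <- as.matrix(per_species_matrix)
  if (ncol(m) < 2) abort("Need at least two method columns.")
  if (is.null(colnames(m))) colnames(m) <- paste0("method_", seq_len(ncol(m)))
  pairs <- utils::combn(colnames(m), 2)
  purrr_rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    res <- wilcoxon_signed_rank(m[, a], m[, b])
    tibble::tibble(method_a = a, method_b = b, statistic = res$statistic,
                   n_eff = res$n_eff, p_value = res$p, exact = res$exact)
  })
  dplyr::bind_rows(purrr_rows)
}

# all permutations of 1..n (n small), one permutation per row
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1), 1] <- k
    out[row:(row + nrow(sub) - 1), -1] <- matrix(rest[sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

# Spearman rho from mid-ranks, with exact permutation p for n <= exact_max
spearman_test <- function(x, y, exact_max = 9) {
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 observations.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("Constant column; Spearman rho undefined.")
    return(list(rho = NA_real_, p = NA_real_, exact = NA))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_all(n)
    # rho is affine in sum(rx * ry[perm]) given fixed marginals
    sums <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    obs <- sum(rx * ry)
    mu_r <- mean(rx) * mean(ry) * n
    sd_prod <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rho_perm <- (sums - mu_r) / sd_prod
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    exact <- FALSE
  }
  list(rho = rho, p = p, exact = exact)
}

#' Pairwise Spearman rank correlations across method columns
#'
#' Rank correlations (mid-ranks for ties) for every pair of method columns,
#' with two-sided p-values from the exact permutation distribution for up
#' to 9 groups and a t approximation above. A constant column yields an
#' undefined rho, flagged with a warning and `NA`.
#'
#' @inheritParams pairwise_wilcoxon
#' @return A tibble with `method_a`, `method_b`, `rho`, `p_value`, `exact`.
#' @export
spearman_matrix <- function(per_species_matrix) {
  m <- as.matrix(per_species_matrix)
  if (ncol(m) < 2) abort("Need at least two method columns.")
  if (is.null(colnames(m))) colnames(m) <- paste0("method_", seq_len(ncol(m)))
  pairs <- utils::combn(colnames(m), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    res <- spearman_test(m[, a], m[, b])
    tibble::tibble(method_a = a, method_b = b, rho = res$rho,
                   p_value = res$p, exact = res$exact)
  })
  dplyr::bind_rows(rows)
}

#' Compare the four arbor-layer estimation methods on an inventory
#'
#' Runs all four arbor methods grouped by species, then assembles the
#' comparison report: per-method totals, relative errors against the
#' four-method mean, the species x method estimate matrix, pairwise
#' Wilcoxon signed-rank tests and Spearman rank correlations.
#'
#' @inheritParams carbon_variable_bef
#' @param application_level Application level for the linear
#'   biomass-volume method (default `"species_aggregate"`, the pipeline
#'   convention).
#' @param alpha Significance level annotated on the report (never used to
#'   filter), default 0.05.
#' @return An object of class `carbon_comparison`: list with
#'   `method_totals`, `relative_errors`, `per_species_matrix`, `wilcoxon`,
#'   `spearman`, `alpha`.
#' @export
compare_methods <- function(inventory, registry = default_registry(),
                            application_level = "species_aggregate",
                            alpha = 0.05) {
  stocks <- list(
    variable_bef = carbon_variable_bef(inventory, registry, by = "species"),
    bef = carbon_bef(inventory, registry, by = "species"),
    volume_conversion = carbon_volume_conversion(inventory, registry,
                                                 by = "species"),
    continuous_bcf = carbon_continuous_bcf(inventory, registry,
                                           application_level = application_level,
                                           by = "species")
  )
  wide <- Reduce(function(acc, nm) {
    dplyr::full_join(acc,
                     setNames(stocks[[nm]][c("species", "carbon_tC")],
                              c("species", nm)),
                     by = "species")
  }, names(stocks),
  init = tibble::tibble(species = sort(unique(stocks$bef$species))))
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$species
  totals <- vapply(stocks, function(s) sum(s$carbon_tC), numeric(1))
  out <- list(
    method_totals = totals,
    relative_errors = relative_errors(totals),
    per_species_matrix = mat,
    wilcoxon = pairwise_wilcoxon(mat),
    spearman = spearman_matrix(mat),
    alpha = alpha
  )
  class(out) <- "carbon_comparison"
  out
}

#' @export
print.carbon_comparison <- function(x, ...) {
  cat("<carbon_comparison> four arbor-layer methods\n\n")
  re <- x$relative_errors
  cat(sprintf("Mean total: %.2f tC\n", re$mean_tC[1]))
  for (i in seq_len(nrow(re))) {
    cat(sprintf("  %-18s %14.2f tC  RE %+7.2f%%\n",
                re$method[i], re$total_tC[i], re$relative_error_pct[i]))
  }
  cat(sprintf("\nWilcoxon signed-rank (alpha = %.2f):\n", x$alpha))
  w <- x$wilcoxon
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  %s vs %s: p = %.3f%s\n", w$method_a[i], w$method_b[i],
                w$p_value[i], ifelse(w$p_value[i] < x$alpha, " *", "")))
  }
  cat("\nSpearman rho:\n")
  s <- x$spearman
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s vs %s: rho = %.3f (p = %.3f)\n", s$method_a[i],
                s$method_b[i], s$rho[i], s$p_value[i]))
  }
  invisible(x)
}
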