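# Small in-code fixtures and independent oracles shared across tests.

# a tiny hand-written valid inventory covering all vegetation types
mini_inventory <- function() {
  as_inventory(tibble::tibble(
    record_id = c("r1", "r2", "r3", "r4", "r5"),
    compartment_id = c("c1", "c1", "c2", "c2", "c3"),
    vegetation_type = c("arbor", "arbor", "arbor", "economic", "shrub"),
    species = c("P_yunnanensis", "Quercus_sp", "P_yunnanensis",
                "economic_mixed", "shrub_mixed"),
    age_group = c("middle_aged", "mature", "young", "not_applicable",
                  "not_applicable"),
    area_hm2 = c(10, 5, 8, 3, 2),
    volume_m3 = c(1000, 400, 300, 0, 0),
    zone = c("core", "buffer", "experimental", "experimental", "buffer")
  ), provenance = "test")
}

# single-species arbor inventory with a given volume (one record)
single_arbor <- function(species, age_group, volume, area = 1, zone = "core") {
  as_inventory(tibble::tibble(
    record_id = "r1", compartment_id = "c1", vegetation_type = "arbor",
    species = species, age_group = age_group, area_hm2 = area,
    volume_m3 = volume, zone = zone))
}

# brute-force two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments (zeros dropped, mid-ranks), independent of the DP route
wilcoxon_brute_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Spearman rho via the classical sum-of-squared-rank-differences formula
# (valid without ties)
spearman_d2_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force exact two-sided permutation p for Spearman rho
spearman_brute_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- asplit(perms_matrix(n), 1)
  rho_all <- vapply(perms, function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

perms_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
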