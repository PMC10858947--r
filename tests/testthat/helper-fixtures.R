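# Shared fixtures and independent brute-force oracles used across tests.

# symmetric contact map from an upper-triangle-filled random matrix
random_contact_map <- function(n, lambda = 20, seed = 1, chrom = "chrT",
                               bin_size = 1e4) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lambda)
  m <- m + t(m) - diag(diag(m))
  contact_map(chrom, bin_size, m)
}

# O/E-scale map (positive continuous values), optionally with NA holes
random_oe_map <- function(n, seed = 1, na_frac = 0, chrom = "chrT") {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rlnorm(sum(ut), 0, 0.3)
  m <- m + t(m) - diag(diag(m))
  if (na_frac > 0) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    hole <- idx[runif(nrow(idx)) < na_frac, , drop = FALSE]
    m[hole] <- NA
    m[hole[, c(2, 1), drop = FALSE]] <- NA
  }
  structure(list(chrom = chrom, bin_size = 1e4, n_bins = n, values = m,
                 valid_mask = rep(TRUE, n),
                 coverage = rowSums(m, na.rm = TRUE)),
            class = "contact_map")
}

# brute-force loop-score components by explicit set membership
oracle_loop_score <- function(values, i, j, p, w, m_min = 3) {
  n <- nrow(values)
  if (i - w < 1 || i + w > n || j - w < 1 || j + w > n)
    return(list(P = NA, D = NA, H = NA, V = NA, BL = NA, score = NA,
                valid = FALSE))
  cells <- list(P = c(), D = c(), H = c(), V = c(), BL = c())
  for (a in (i - w):(i + w)) for (b in (j - w):(j + w)) {
    da <- a - i; db <- b - j
    in_peak <- max(abs(da), abs(db)) <= p
    in_H <- abs(da) <= p && abs(db) > p && abs(db) <= w
    in_V <- abs(db) <= p && abs(da) > p && abs(da) <= w
    in_BL <- da > 0 && da <= w && -db > 0 && -db <= w && !in_peak
    in_D <- max(abs(da), abs(db)) <= w && !in_peak && !in_H && !in_V
    v <- values[a, b]
    if (in_peak) cells$P <- c(cells$P, v)
    if (in_D) cells$D <- c(cells$D, v)
    if (in_H) cells$H <- c(cells$H, v)
    if (in_V) cells$V <- c(cells$V, v)
    if (in_BL) cells$BL <- c(cells$BL, v)
  }
  means <- lapply(cells, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < m_min) NA_real_ else mean(x)
  })
  bg <- suppressWarnings(max(means$D, means$H, means$V, means$BL))
  valid <- !any(vapply(means, is.na, TRUE)) && bg > 1e-9
  list(P = means$P, D = means$D, H = means$H, V = means$V, BL = means$BL,
       score = if (valid) means$P / bg else NA_real_, valid = valid)
}

# exact hypergeometric upper tail by enumeration over the overlap count
oracle_hyper_tail <- function(M, na, nb, N) {
  ks <- M:min(na, nb)
  sum(choose(na, ks) * choose(N - na, nb - ks)) / choose(N, nb)
}

# rank-sum U by exhaustive pair enumeration (ties count one half)
oracle_rank_sum_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# standard planted-loop layout used by the recovery tests
standard_loop_table <- function() {
  data.frame(chrom = "chrS",
             i = c(60, 120, 200, 260, 310, 50, 150, 230, 330, 90),
             j = c(100, 170, 240, 300, 360, 140, 210, 320, 380, 220),
             fc = 5,
             status = c(rep("shared", 4), rep("cond1_only", 3),
                        rep("cond2_only", 3)),
             stringsAsFactors = FALSE)
}

# standard fragment fixture: ATAC-like density, 100 equal peaks
standard_frag_params <- function(seed = 1, mult1 = 1, mult2 = 1,
                                 depth_factors = list(cond1 = c(0.5, 1, 2),
                                                      cond2 = c(0.7, 1.5, 1))) {
  starts <- seq(5e4, 9.9e6, length.out = 100)
  frag_sim_params(genome_len = 1e7,
                  peaks = data.frame(start = starts, end = starts + 800,
                                     mult1 = mult1, mult2 = mult2),
                  depth_factors = depth_factors, seed = seed)
}
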