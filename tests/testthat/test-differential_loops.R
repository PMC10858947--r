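.flat_map <- function(values, chrom = "cT") {
  structure(list(chrom = chrom, bin_size = 1e4, n_bins = nrow(values),
                 values = values, valid_mask = rep(TRUE, nrow(values)),
                 coverage = rowSums(values, na.rm = TRUE)),
            class = "contact_map")
}

test_that("per-sample z-scores use the population standard deviation", {
  # three candidates with scores 1, 2, 3 -> z = (-1.2247, 0, 1.2247)
  m <- matrix(1, 40, 40)
  put <- function(m, i, j, v) { m[(i-1):(i+1), (j-1):(j+1)] <- v
                                m[(j-1):(j+1), (i-1):(i+1)] <- v; m }
  m <- put(m, 10, 20, 1 * 2); m <- put(m, 12, 30, 2 * 2)
  m <- put(m, 25, 33, 3 * 2)
  # peak values 2v on unit background give scores 2, 4, 6 (proportional to
  # 1, 2, 3; z-scores are identical for any affine rescaling)
  mp <- .flat_map(m)
  calls <- data.frame(i = c(10, 12, 25), j = c(20, 30, 33))
  un <- score_union_loops(list(a = mp, b = mp), list(a = calls, b = NULL))
  expect_equal(un$z[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  # identical maps -> identical z vectors
  expect_equal(un$z[, "a"], un$z[, "b"])
  expect_equal(mean(un$z[, "a"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(un$z[, "a"]^2)), 1, tolerance = 1e-9)
})

test_that("candidates invalid in any sample are dropped from the union", {
  mp_big <- .flat_map(matrix(1, 40, 40))
  mp_small <- .flat_map(matrix(1, 25, 25))
  calls <- data.frame(i = c(10, 12, 14), j = c(20, 30, 38))
  expect_message(
    un <- score_union_loops(list(a = mp_big, b = mp_small),
                            list(a = calls, b = NULL)),
    "dropped")
  # (12, 30) and (14, 38) leave the 25-bin map's scoring window
  expect_equal(nrow(un$candidates), 1)
  expect_error(score_union_loops(list(a = mp_big, b = mp_big),
                                 list(a = NULL, b = NULL)),
               "empty candidate union")
})

test_that("Stouffer meta matches the printed arithmetic", {
  # matched pairs with z differences (1, 2, 3): Z = 6/sqrt(3) = 3.4641
  z <- rbind(c(1, 2, 3, 0, 0, 0))
  colnames(z) <- paste0("s", 1:6)
  res <- differential_loop_meta(z, rep(c("c1", "c2"), each = 3),
                                mode = "matched_pairs")
  expect_equal(res$Z, 6 / sqrt(3), tolerance = 1e-9)
  expect_equal(res$k, 3)
  expect_true(res$significant)
  expect_equal(res$direction, "lost")
  # all differences zero -> Z = 0, p = 1, unchanged
  z0 <- rbind(c(1, 1), c(-1, -1))
  colnames(z0) <- c("a", "b")
  r0 <- differential_loop_meta(z0, c("c1", "c2"))
  expect_equal(r0$Z, c(0, 0))
  expect_equal(r0$p, c(1, 1))
  expect_equal(r0$direction, rep("unchanged", 2))
  # 3v3 all-combinations -> k = 9
  z9 <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  z9 <- apply(z9, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_equal(unique(differential_loop_meta(
    z9, rep(c("c1", "c2"), each = 3))$k), 9)
})

test_that("meta scores equal a brute-force loop over replicate pairs", {
  set.seed(44)
  for (trial in 1:10) {
    r1 <- sample(1:4, 1); r2 <- sample(1:4, 1)
    nc <- sample(2:20, 1)
    z <- matrix(rnorm(nc * (r1 + r2)), nc, r1 + r2,
                dimnames = list(NULL, paste0("s", seq_len(r1 + r2))))
    cond <- rep(c("c1", "c2"), c(r1, r2))
    res <- differential_loop_meta(z, cond)
    for (cc in seq_len(nc)) {
      ds <- c()
      for (x in which(cond == "c1")) for (y in which(cond == "c2"))
        ds <- c(ds, z[cc, x] - z[cc, y])
      expect_equal(res$Z[cc], sum(ds) / sqrt(length(ds)), tolerance = 1e-12)
      expect_equal(res$p[cc], 2 * pnorm(-abs(res$Z[cc])), tolerance = 1e-12)
    }
  }
})

test_that("degenerate replicate structure is rejected with clear errors", {
  z <- matrix(c(1, 1, 0, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(differential_loop_meta(z, c("c1", "c2")),
               "zero variance.*a")
  z2 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(differential_loop_meta(z2, c("c1", "c1")), "two levels")
  expect_error(differential_loop_meta(
    matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c"))),
    c("c1", "c1", "c2"), mode = "matched_pairs"), "equal replicate")
})

test_that("planted condition-specific loops are detected with direction", {
  sim <- simulate_hic_experiment(
    hic_sim_params(loops = standard_loop_table(), seed = 1))
  dl <- suppressMessages(differential_loops(sim$samples, "chrS"))
  m <- dl$meta
  lp <- standard_loop_table()
  for (k in which(lp$status != "shared")) {
    h <- which(abs(m$i - lp$i[k]) <= 1 & abs(m$j - lp$j[k]) <= 1)
    expect_gte(length(h), 1)
    best <- h[which.min(m$p[h])]
    expect_true(m$significant[best])
    expect_equal(m$direction[best],
                 if (lp$status[k] == "cond1_only") "lost" else "gained")
  }
})

test_that("summaries count chromosomes, promoters and hotspots", {
  diffs <- data.frame(chrom = "chrS",
                      i = c(10, 20, 22, 24, 26, 80),
                      j = c(40, 30, 32, 34, 36, 95),
                      significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  genes <- gene_annotation(c("g1", "g2"), "chrS", "+",
                           tss = c(95000, 3.9e6), tts = c(99000, 3.95e6))
  su <- interaction_change_summary(diffs, 1e4, genes,
                                   tss_halfwidth = 5000,
                                   hotspot_window = 2e5,
                                   chrom_lengths = c(chrS = 4e6))
  expect_equal(su$per_chromosome$n_significant, 5)
  # gene g1 TSS at 95 kb intersects the anchor bin of loop (10, 40)
  expect_equal(su$promoters$gene[1], "g1")
  expect_equal(su$promoters$count, c(1, 0))
  # the cluster of anchors around bins 20-36 tops the hotspot ranking
  expect_lte(su$hotspots$start[1], 2e5)
  expect_gte(su$hotspots$end[1], 3.6e5)
  # no significant loops -> empty summaries
  none <- interaction_change_summary(
    transform(diffs, significant = FALSE), 1e4, genes,
    chrom_lengths = c(chrS = 4e6))
  expect_equal(nrow(none$per_chromosome), 0)
  expect_equal(none$promoters$count, c(0, 0))
})

test_that("locus enrichment reproduces the Welch t arithmetic", {
  # engineer anchor counts: subset loci see (4, 5, 6), reference (1, 2, 3)
  mk_loops <- function(centers, counts) {
    do.call(rbind, lapply(seq_along(centers), function(k) {
      n <- counts[k]
      if (n == 0) return(NULL)
      b <- centers[k] / 1e4
      data.frame(chrom = "chrS", i = rep(b, n),
                 j = b + 60 + seq_len(n), significant = TRUE)
    }))
  }
  subs <- c(1e5, 2e5, 3e5); refs <- c(2e6, 2.4e6, 2.8e6)
  diffs <- rbind(mk_loops(subs, c(4, 5, 6)), mk_loops(refs, c(1, 2, 3)))
  r <- locus_rearrangement_enrichment(
    diffs, 1e4,
    loci_all = data.frame(chrom = "chrS", center = refs),
    loci_subset = data.frame(chrom = "chrS", center = subs),
    halfwidth = 6000)
  expect_equal(r$counts_subset, c(4, 5, 6))
  expect_equal(r$counts_all, c(1, 2, 3))
  expect_equal(r$t, 3 / sqrt(2 / 3), tolerance = 1e-4)
  # subset identical to reference -> t = 0
  r0 <- locus_rearrangement_enrichment(
    diffs, 1e4,
    loci_all = data.frame(chrom = "chrS", center = c(subs, refs)),
    loci_subset = data.frame(chrom = "chrS", center = c(subs, refs)),
    halfwidth = 6000)
  expect_equal(r0$t, 0)
  # zero variance in both groups is a documented error
  expect_error(locus_rearrangement_enrichment(
    diffs, 1e4, loci_all = data.frame(chrom = "chrS", center = c(5e5, 6e5)),
    loci_subset = data.frame(chrom = "chrS", center = c(5e5, 6e5)),
    halfwidth = 100), "zero variance")
})
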