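test_that("peak-to-gene scores split the PHRED-like contribution", {
  genes <- gene_annotation(c("g1", "g2", "g3"), "chr1", "+",
                           tss = c(1e5, 1.2e5, 9e5),
                           tts = c(1.1e5, 1.3e5, 9.1e5))
  # one peak near exactly one gene: -10*log10(0.01) = 20
  pk1 <- data.frame(chrom = "chr1", start = 99e3, end = 101e3, p = 0.01)
  gs1 <- score_genes_from_peaks(pk1, genes[1, ])
  expect_equal(gs1$scores$score[gs1$scores$gene == "g1"], 20)
  # the same peak near two genes: 10 each
  gs2 <- score_genes_from_peaks(pk1, genes)
  expect_equal(gs2$scores$score[match(c("g1", "g2"), gs2$scores$gene)],
               c(10, 10))
  expect_equal(gs2$contributions$n, c(2, 2))
  # inclusive 25 kb boundary: centre exactly 25,000 bp from the TSS
  pk_edge <- data.frame(chrom = "chr1", start = 874500, end = 875500,
                        p = 0.001)
  gs3 <- score_genes_from_peaks(pk_edge, genes)
  expect_equal(gs3$scores$score[gs3$scores$gene == "g3"], 30)
  # p = 0 is clamped, not infinite
  pk0 <- data.frame(chrom = "chr1", start = 99e3, end = 101e3, p = 0)
  expect_message(gs0 <- score_genes_from_peaks(pk0, genes[1, ]), "clamped")
  expect_equal(gs0$scores$score[1], 3000)
})

test_that("gene scoring is additive over peak lists", {
  set.seed(61)
  genes <- gene_annotation(sprintf("g%02d", 1:20), "chr1", "+",
                           tss = sort(runif(20, 0, 2e6)),
                           tts = sort(runif(20, 0, 2e6)) + 3e6)
  pks <- data.frame(chrom = "chr1", start = runif(30, 0, 2e6),
                    p = runif(30, 1e-6, 0.05))
  pks$end <- pks$start + 1000
  joint <- score_genes_from_peaks(pks, genes)$scores
  s1 <- score_genes_from_peaks(pks[1:15, ], genes)$scores
  s2 <- score_genes_from_peaks(pks[16:30, ], genes)$scores
  merged <- merge(s1, s2, by = "gene")
  merged$sum <- merged$score.x + merged$score.y
  expect_equal(merged$sum[match(joint$gene, merged$gene)], joint$score,
               tolerance = 1e-12)
})

test_that("anchor classes follow promoter-over-enhancer precedence", {
  genes <- gene_annotation("g1", "chr1", "+", tss = 5e4, tts = 6e4)
  k27 <- data.frame(chrom = "chr1", start = c(48e3, 2e5), end = c(52e3, 2.1e5))
  anchors <- data.frame(chrom = "chr1",
                        start = c(49e3, 2.0e5, 3e5),
                        end = c(51e3, 2.05e5, 3.1e5))
  ds <- list(yy1 = list(regions = data.frame(chrom = "chr1", start = 2.0e5,
                                             end = 2.02e5,
                                             direction = "gained"),
                        direction = "gained"))
  an <- annotate_anchors(anchors, genes, k27, ds)
  # dual overlap (TSS window + K27ac) resolves to promoter
  expect_equal(an$class, c("promoter", "enhancer", "none"))
  expect_equal(an$flag_yy1, c(FALSE, TRUE, FALSE))
  # direction filter: lost-only set never flags a gained region
  ds_lost <- list(yy1 = list(regions = ds$yy1$regions, direction = "lost"))
  expect_false(any(annotate_anchors(anchors, genes, k27, ds_lost)$flag_yy1))
})

test_that("gain/loss bias counts loops through qualifying anchors", {
  annos <- data.frame(chrom = "chr1", start = (0:3) * 1e4,
                      end = (1:4) * 1e4,
                      class = c("enhancer", "enhancer", "promoter", "none"))
  diffs <- data.frame(direction = c(rep("gained", 6), rep("lost", 3),
                                    "unchanged"),
                      anchor1 = c(1, 1, 1, 2, 2, 2, 1, 2, 3, 4),
                      anchor2 = c(3, 3, 4, 3, 4, 4, 3, 4, 4, 4))
  res <- gain_loss_bias(diffs, annos, categories = list(
    enhancer = function(a) a$class == "enhancer",
    promoter = function(a) a$class == "promoter"))
  enh <- res[res$category == "enhancer", ]
  expect_equal(c(enh$gained, enh$lost), c(6, 2))
  expect_equal(enh$bias, 3)
  # no losses -> undefined bias, not infinity
  res2 <- gain_loss_bias(diffs[diffs$direction != "lost", ], annos,
                         categories = list(
                           enhancer = function(a) a$class == "enhancer"))
  expect_true(is.na(res2$bias))
  expect_equal(res2$gained, 6)
})

test_that("rank-sum comparison matches exhaustive pair enumeration", {
  # engineered nets: category X anchors net (1, 2, 3); Y nets (-1, 0, 1)
  annos <- data.frame(chrom = "chr1", start = (0:6) * 1e4,
                      end = (1:7) * 1e4,
                      grp = c("X", "X", "X", "Y", "Y", "Y", "far"))
  mk <- function(anchor, n, dir) if (n > 0)
    data.frame(direction = dir, anchor1 = rep(anchor, n), anchor2 = 7)
  diffs <- rbind(mk(1, 1, "gained"), mk(2, 2, "gained"), mk(3, 3, "gained"),
                 mk(4, 1, "lost"), mk(6, 1, "gained"))
  res <- gain_loss_bias(diffs, annos,
                        categories = list(X = function(a) a$grp == "X",
                                          Y = function(a) a$grp == "Y"),
                        compare = list(c("X", "Y")))
  xr <- res[res$category == "X", ]
  expect_equal(xr$U, oracle_rank_sum_u(c(1, 2, 3), c(-1, 0, 1)))
  expect_equal(xr$U, 8.5)
  expect_equal(xr$padj, xr$p)
  # randomized agreement with the enumeration oracle (|X|, |Y| <= 8)
  set.seed(62)
  for (trial in 1:20) {
    x <- sample(-3:3, sample(2:8, 1), replace = TRUE)
    y <- sample(-3:3, sample(2:8, 1), replace = TRUE)
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                       exact = FALSE, correct = FALSE))
    expect_equal(unname(wt$statistic), oracle_rank_sum_u(x, y))
  }
  # identical distributions: one-sided p is not small
  annos2 <- annos
  diffs2 <- rbind(mk(1, 2, "gained"), mk(4, 2, "gained"))
  res2 <- gain_loss_bias(diffs2, annos2,
                         categories = list(X = function(a) a$grp == "X",
                                           Y = function(a) a$grp == "Y"),
                         compare = list(c("X", "Y")))
  expect_gte(res2$p[res2$category == "X"], 0.5)
})

test_that("planted enhancer-biased gains order the category biases", {
  # gains planted only at flagged enhancer anchors; losses elsewhere
  annos <- data.frame(chrom = "chr1", start = (0:9) * 1e4, end = (1:10) * 1e4,
                      class = rep(c("enhancer", "promoter"), each = 5),
                      flagged = rep(c(TRUE, FALSE), 5))
  flag_enh <- which(annos$class == "enhancer" & annos$flagged)
  other <- which(!(annos$class == "enhancer" & annos$flagged))
  set.seed(63)
  diffs <- rbind(
    data.frame(direction = "gained",
               anchor1 = sample(flag_enh, 12, TRUE), anchor2 = 10),
    data.frame(direction = sample(c("gained", "lost"), 12, TRUE,
                                  prob = c(0.5, 0.5)),
               anchor1 = sample(other, 12, TRUE), anchor2 = 10))
  res <- gain_loss_bias(diffs, annos, categories = list(
    flagged_enh = function(a) a$class == "enhancer" & a$flagged,
    plain_enh = function(a) a$class == "enhancer" & !a$flagged))
  b1 <- res$bias[res$category == "flagged_enh"]
  b2 <- res$bias[res$category == "plain_enh"]
  expect_true(is.na(b2) || b1 > b2)
})
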