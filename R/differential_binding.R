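# Two-group differential occupancy on a common region catalog, with the
# overlap and co-occurrence statistics used for integrating assays.

#' Wald test for differential counts on a region catalog
#'
#' A moment-based simplification of the negative-binomial Wald test:
#' normalized counts `q = count/sf` give per-region group means; a
#' per-region dispersion is estimated by the method of moments from
#' group-centred residuals, `alpha_hat = max(1e-8, (v - mean(q))/mean(q)^2)`
#' with `v` the pooled within-group variance; the log2 fold change uses a
#' 0.5 pseudocount on group means; and the Wald statistic is
#' `log2fc / SE` with `SE^2 = (1/ln 2)^2 * sum_g v_g / (n_g * qbar_g^2)`,
#' `v_g = qbar_g + alpha_hat * qbar_g^2`, compared to a standard normal.
#'
#' @param counts integer matrix, regions x samples.
#' @param sf named size-factor vector (column order of `counts`).
#' @param condition character/factor of length `ncol(counts)` with exactly
#'   two levels; the second level is the treatment.
#' @param alpha significance threshold on the gating p-value.
#' @param gate `"padj"` (default) or `"p"`: which p-value the
#'   gained/lost/unchanged call is thresholded on.
#' @param dispersion `"pooled"` estimates the dispersion from group-centred
#'   residuals; `"all"` from the variance across all samples ignoring
#'   groups.
#' @param moderate if `TRUE` (default), each region's dispersion is floored
#'   at the catalog-wide median dispersion. Per-region moment estimates from
#'   a handful of replicates are very noisy and underestimates inflate the
#'   Wald statistic; sharing information across the catalog in this
#'   max-of-(region, catalog) way stabilizes the test.
#' @return Data frame with `log2fc`, `p`, `padj`, `direction`.
#' @export
differential_test <- function(counts, sf, condition, alpha = 0.05,
                              gate = c("padj", "p"),
                              dispersion = c("pooled", "all"),
                              moderate = TRUE) {
  gate <- match.arg(gate)
  dispersion <- match.arg(dispersion)
  stopifnot(length(condition) == ncol(counts))
  cond <- factor(condition)
  if (nlevels(cond) != 2) stop("condition must have exactly two levels")
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  q <- sweep(counts, 2, sf[colnames(counts)], "/")
  g1 <- cond == levels(cond)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, g2, drop = FALSE])
  mu <- rowMeans(q)
  if (dispersion == "all") {
    v <- apply(q, 1, var)
  } else {
    resid <- q
    resid[, g1] <- q[, g1, drop = FALSE] - m1
    resid[, g2] <- q[, g2, drop = FALSE] - m2
    df <- n1 + n2 - 2
    v <- rowSums(resid^2) / max(1, df)
  }
  disp <- pmax(1e-8, (v - mu) / mu^2)
  disp[!is.finite(disp)] <- 1e-8
  if (moderate && length(disp) > 1)
    disp <- pmax(disp, median(disp))
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  v1 <- m1 + disp * m1^2
  v2 <- m2 + disp * m2^2
  se2 <- (1 / log(2))^2 * (v1 / (n1 * m1^2) + v2 / (n2 * m2^2))
  w <- ifelse(is.finite(se2) & se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * pnorm(-abs(w))
  p[!is.finite(se2)] <- 1
  padj <- p.adjust(p, method = "BH")
  gatep <- if (gate == "padj") padj else p
  direction <- ifelse(gatep < alpha & log2fc > 0, "gained",
                      ifelse(gatep < alpha & log2fc < 0, "lost", "unchanged"))
  data.frame(log2fc = log2fc, p = p, padj = padj, direction = direction,
             stringsAsFactors = FALSE)
}

#' Differential occupancy between two conditions of fragment samples
#'
#' Builds a common region catalog by calling enriched regions on all
#' samples' pooled fragments, counts fragments per region per sample,
#' and applies [differential_test()] with the supplied size factors.
#'
#' @param samples list of samples (`id`, `condition`, `fragments`).
#' @param sf named size-factor vector; use unit factors for pre-thinned
#'   samples.
#' @param genome_len genome length in bp.
#' @param window peak-caller window in bp.
#' @param alpha significance threshold.
#' @param gate,dispersion passed to [differential_test()].
#' @return Data frame: region coordinates plus `log2fc`, `p`, `padj`,
#'   `direction`.
#' @export
differential_regions <- function(samples, sf, genome_len, window = 500,
                                 alpha = 0.05, gate = "padj",
                                 dispersion = "pooled") {
  pooled <- do.call(rbind, lapply(samples, `[[`, "fragments"))
  catalog <- call_enriched_regions(pooled, genome_len, window)
  if (nrow(catalog) == 0) stop("empty region catalog")
  cm <- count_fragments_in_regions(samples, catalog)
  condition <- vapply(samples, `[[`, "", "condition")
  res <- differential_test(cm$counts, sf, condition, alpha = alpha,
                           gate = gate, dispersion = dispersion)
  cbind(catalog[, c("chrom", "start", "end")], res)
}

#' One-sided hypergeometric overlap test
#'
#' Tests whether two subsets of a common region catalog co-occur more than
#' expected: with population `catalog_size`, `|a|` successes and `|b|`
#' draws, the p-value is the upper tail `P(X >= M)` at the observed overlap
#' `M = |a intersect b|`.
#'
#' @param a,b integer index vectors into the catalog.
#' @param catalog_size catalog size.
#' @return List with `M`, `p` and a `padj` slot (`NA`; fill via
#'   [adjust_overlap_batch()]).
#' @export
overlap_significance <- function(a, b, catalog_size) {
  a <- unique(a); b <- unique(b)
  if (length(a) > catalog_size || length(b) > catalog_size)
    stop("subset larger than catalog")
  M <- length(intersect(a, b))
  p <- phyper(M - 1, length(a), catalog_size - length(a), length(b),
              lower.tail = FALSE)
  list(M = M, p = p, padj = NA_real_)
}

#' BH-adjust a batch of overlap tests
#'
#' @param tests list of results from [overlap_significance()].
#' @return The list with `padj` filled in across the batch.
#' @export
adjust_overlap_batch <- function(tests) {
  padj <- p.adjust(vapply(tests, `[[`, 0, "p"), method = "BH")
  for (k in seq_along(tests)) tests[[k]]$padj <- padj[k]
  tests
}

#' Loci co-differential across multiple assays
#'
#' Given named differential-region sets, each with a required direction,
#' merges all qualifying regions (joining intervals separated by at most
#' `merge_gap` bp) and keeps merged loci that intersect at least one
#' qualifying region from every set.
#'
#' @param sets named list; each element a list with `regions` (a data frame
#'   with `chrom`, `start`, `end`, `direction`) and `direction`, the
#'   required direction (`"gained"`, `"lost"` or `"any"`).
#' @param merge_gap maximum gap in bp for merging.
#' @return Data frame of loci with a `sets` column naming contributors.
#' @export
co_differential_loci <- function(sets, merge_gap = 1000) {
  if (length(sets) < 2) stop("need at least two sets")
  qual <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (!s$direction %in% c("gained", "lost", "any"))
      stop("unknown direction token: ", s$direction)
    r <- s$regions
    if (s$direction != "any") r <- r[r$direction == s$direction, , drop = FALSE]
    r
  })
  names(qual) <- names(sets)
  all_r <- do.call(rbind, lapply(qual, function(r)
    r[, c("chrom", "start", "end"), drop = FALSE]))
  if (nrow(all_r) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sets = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (ch in unique(all_r$chrom)) {
    rr <- all_r[all_r$chrom == ch, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(start = rr$start + 1,
                                               end = rr$end),
                              min.gapwidth = merge_gap + 1)
    hit_all <- vapply(seq_along(merged), function(k) {
      mk <- merged[k]
      all(vapply(qual, function(r) {
        rc <- r[r$chrom == ch, , drop = FALSE]
        if (!nrow(rc)) return(FALSE)
        length(IRanges::findOverlaps(
          mk, IRanges::IRanges(start = rc$start + 1, end = rc$end))) > 0
      }, TRUE))
    }, TRUE)
    keep <- merged[hit_all]
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(keep) - 1,
                              end = IRanges::end(keep),
                              sets = paste(names(sets), collapse = ","),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sets = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
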