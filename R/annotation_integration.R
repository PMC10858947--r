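# Integration of differential regions with genes and loop anchors:
# peak-to-gene scoring, enhancer/promoter anchor annotation, and anchor-level
# loop gain/loss bias statistics.

#' Gene annotation table
#'
#' @param gene gene ids.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss,tts transcription start/termination positions (bp); the TSS
#'   must lie upstream of the TTS with respect to strand.
#' @return Data frame of gene annotations.
#' @export
gene_annotation <- function(gene, chrom, strand, tss, tts) {
  stopifnot(all(strand %in% c("+", "-")), all(tss != tts))
  if (any((strand == "+" & tss > tts) | (strand == "-" & tss < tts)))
    stop("TSS must be upstream of TTS with respect to strand")
  data.frame(gene = as.character(gene), chrom = as.character(chrom),
             strand = strand, tss = as.numeric(tss), tts = as.numeric(tts),
             stringsAsFactors = FALSE)
}

#' Score genes from differential peaks
#'
#' Each differential peak contributes `(1/n) * (-10*log10 p)` to every gene
#' whose TSS lies within `window` bp (inclusive) of the peak midpoint,
#' where `n` is the number of such genes; peaks near no gene contribute
#' nothing. A gene's score is the sum over contributing peaks.
#'
#' @param peaks data frame with `chrom`, `start`, `end`, `p`.
#' @param genes [gene_annotation()] table.
#' @param window TSS distance cutoff in bp (default 25000).
#' @param p_floor p-values below this are clamped (caps the per-peak
#'   contribution; default `1e-300`).
#' @return List with `scores` (ranked data frame `gene`, `score`) and
#'   `contributions` (per peak-gene pair: `peak`, `gene`, `n`, `p`,
#'   `contribution`).
#' @export
score_genes_from_peaks <- function(peaks, genes, window = 25000,
                                   p_floor = 1e-300) {
  stopifnot(window > 0)
  contrib <- list()
  score <- setNames(rep(0, nrow(genes)), genes$gene)
  for (k in seq_len(nrow(peaks))) {
    center <- (peaks$start[k] + peaks$end[k]) / 2
    near <- which(genes$chrom == peaks$chrom[k] &
                    abs(genes$tss - center) <= window)
    n <- length(near)
    if (n == 0) next
    p <- peaks$p[k]
    if (is.na(p)) next
    if (p < p_floor) {
      message("peak ", k, ": p-value clamped to ", p_floor)
      p <- p_floor
    }
    contribution <- (1 / n) * (-10 * log10(p))
    score[genes$gene[near]] <- score[genes$gene[near]] + contribution
    contrib[[length(contrib) + 1L]] <-
      data.frame(peak = k, gene = genes$gene[near], n = n, p = p,
                 contribution = contribution, stringsAsFactors = FALSE)
  }
  scores <- data.frame(gene = names(score), score = unname(score),
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$score, scores$gene), , drop = FALSE]
  rownames(scores) <- NULL
  list(scores = scores,
       contributions = if (length(contrib)) do.call(rbind, contrib)
       else data.frame(peak = integer(), gene = character(), n = integer(),
                       p = numeric(), contribution = numeric()))
}

.intersects_any <- function(chrom, start, end, regions) {
  if (is.null(regions) || !nrow(regions)) return(FALSE)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  if (!nrow(r)) return(FALSE)
  any(r$start < end & r$end > start)
}

#' Annotate loop anchors as promoter or enhancer with differential flags
#'
#' An anchor is a promoter if it intersects any TSS window
#' `[tss - h, tss + h)`; otherwise it is an enhancer if it intersects an
#' active-chromatin (H3K27ac) peak; promoter takes precedence. Each named
#' differential set flags the anchor when it intersects a region of that
#' set carrying the set's required direction.
#'
#' @param anchors interval data frame (`chrom`, `start`, `end`).
#' @param genes [gene_annotation()] table.
#' @param k27ac_peaks interval data frame of active-enhancer marks.
#' @param differential_sets named list; each element a list with `regions`
#'   (data frame with `direction` column) and `direction`
#'   (`"gained"`/`"lost"`/`"any"`).
#' @param promoter_halfwidth TSS window half-width in bp.
#' @return Data frame: anchors plus `class` (`promoter`, `enhancer` or
#'   `none`) and one logical `flag_<name>` column per differential set.
#' @export
annotate_anchors <- function(anchors, genes, k27ac_peaks,
                             differential_sets = list(),
                             promoter_halfwidth = 2000) {
  stopifnot(promoter_halfwidth > 0)
  tss_win <- data.frame(chrom = genes$chrom,
                        start = genes$tss - promoter_halfwidth,
                        end = genes$tss + promoter_halfwidth)
  out <- anchors
  out$class <- vapply(seq_len(nrow(anchors)), function(k) {
    if (.intersects_any(anchors$chrom[k], anchors$start[k], anchors$end[k],
                        tss_win)) return("promoter")
    if (.intersects_any(anchors$chrom[k], anchors$start[k], anchors$end[k],
                        k27ac_peaks)) return("enhancer")
    "none"
  }, "")
  for (nm in names(differential_sets)) {
    s <- differential_sets[[nm]]
    r <- s$regions
    if (!is.null(s$direction) && s$direction != "any")
      r <- r[r$direction == s$direction, , drop = FALSE]
    out[[paste0("flag_", nm)]] <- vapply(seq_len(nrow(anchors)), function(k)
      .intersects_any(anchors$chrom[k], anchors$start[k], anchors$end[k], r),
      TRUE)
  }
  out
}

#' Loop gain/loss bias per anchor category
#'
#' For each named category (a predicate over anchor annotations), counts
#' significant gained and lost loops with at least one qualifying anchor
#' and reports the gain/loss ratio. For requested category pairs, the
#' per-anchor net change (gained minus lost loop count at each qualifying
#' anchor) distributions are compared with a one-sided Wilcoxon rank-sum
#' test (first category greater), normal approximation with tie
#' correction, BH-adjusted across all requested comparisons.
#'
#' @param diffs differential loop table with `direction` and anchor index
#'   columns `anchor1`, `anchor2` referring to rows of `annos`.
#' @param annos anchor annotation table from [annotate_anchors()].
#' @param categories named list of predicate functions taking `annos` and
#'   returning a logical vector over anchors.
#' @param compare list of 2-element character vectors naming category pairs
#'   to test.
#' @return Data frame per category: `category`, `gained`, `lost`, `bias`,
#'   and for compared pairs `U`, `p`, `padj` on the first-named row.
#' @export
gain_loss_bias <- function(diffs, annos, categories, compare = list()) {
  memb <- lapply(categories, function(f) f(annos))
  res <- data.frame(category = names(categories),
                    gained = 0L, lost = 0L, bias = NA_real_,
                    U = NA_real_, p = NA_real_, padj = NA_real_,
                    stringsAsFactors = FALSE)
  net_of <- list()
  for (ci in seq_along(categories)) {
    q <- memb[[ci]]
    has_anchor <- q[diffs$anchor1] | q[diffs$anchor2]
    g <- sum(has_anchor & diffs$direction == "gained")
    l <- sum(has_anchor & diffs$direction == "lost")
    res$gained[ci] <- g; res$lost[ci] <- l
    res$bias[ci] <- if (l > 0) g / l else NA_real_
    anchor_ids <- which(q)
    net_of[[names(categories)[ci]]] <- vapply(anchor_ids, function(a) {
      at <- diffs$anchor1 == a | diffs$anchor2 == a
      sum(at & diffs$direction == "gained") -
        sum(at & diffs$direction == "lost")
    }, 0)
  }
  if (length(compare)) {
    ps <- rep(NA_real_, length(compare))
    for (k in seq_along(compare)) {
      pr <- compare[[k]]
      x <- net_of[[pr[1]]]; y <- net_of[[pr[2]]]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                         exact = FALSE, correct = FALSE))
      ri <- match(pr[1], res$category)
      res$U[ri] <- unname(wt$statistic)
      ps[k] <- wt$p.value
      res$p[ri] <- wt$p.value
    }
    padj <- p.adjust(ps, method = "BH")
    for (k in seq_along(compare))
      res$padj[match(compare[[k]][1], res$category)] <- padj[k]
  }
  res
}
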