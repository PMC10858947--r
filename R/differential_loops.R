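# The central differential statistic: per-sample z-normalized loop scores on
# a union candidate set, replicate-pair difference scores, and a Stouffer
# meta z-score per candidate, followed by genomic summaries.

#' Score a union of loop candidates in every sample
#'
#' Pools per-sample loop calls into a union of interaction pixels,
#' recomputes the donut loop score of every union candidate in every
#' sample, drops candidates that are invalid in any sample (logged), and
#' z-score-normalizes scores within each sample across the surviving union
#' using the population (n-denominator) standard deviation.
#'
#' @param maps named list of smoothed O/E [contact_map()]s, one per sample.
#' @param calls list (same names) of per-sample call data frames with `i`,
#'   `j` columns; ignored entries may be `NULL`.
#' @param p,w,m_min scoring geometry, see [loop_score()].
#' @return List with `candidates` (data frame `i`, `j`), `scores` and `z`
#'   (candidate x sample matrices).
#' @export
score_union_loops <- function(maps, calls, p = 1, w = 5, m_min = 3) {
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  allc <- do.call(rbind, lapply(calls, function(cl)
    if (is.null(cl) || !nrow(cl)) NULL else cl[, c("i", "j")]))
  if (is.null(allc) || !nrow(allc)) stop("empty candidate union")
  cand <- unique(allc)
  cand <- cand[order(cand$i, cand$j), , drop = FALSE]
  rownames(cand) <- NULL
  scores <- matrix(NA_real_, nrow(cand), length(maps),
                   dimnames = list(NULL, names(maps)))
  for (s in names(maps)) {
    for (k in seq_len(nrow(cand))) {
      ls <- loop_score(maps[[s]], cand$i[k], cand$j[k], p, w, m_min)
      scores[k, s] <- if (ls$valid) ls$score else NA
    }
  }
  ok <- rowSums(is.na(scores)) == 0
  if (!all(ok))
    message(sum(!ok), " union candidate(s) dropped: invalid in >=1 sample")
  if (!any(ok)) stop("no union candidate scorable in every sample")
  cand <- cand[ok, , drop = FALSE]
  rownames(cand) <- NULL
  scores <- scores[ok, , drop = FALSE]
  z <- apply(scores, 2, function(x) {
    sdp <- sqrt(mean((x - mean(x))^2))
    if (sdp == 0) return(rep(0, length(x)))
    (x - mean(x)) / sdp
  })
  if (!is.matrix(z)) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(maps)))
  list(candidates = cand, scores = scores, z = z)
}

#' Stouffer meta-analysis of replicate difference scores
#'
#' For each union candidate, difference scores `DS` are formed as
#' `z_cond1,x - z_cond2,y` over replicate pairings -- the full cross
#' product in `all_combinations` mode (`k = R1*R2`), or index-matched
#' replicates in `matched_pairs` mode (`k = R`). The meta score is
#' `Z = sum(DS)/sqrt(k)` with a two-sided normal p-value; candidates with
#' `p < alpha` are directional: `Z > 0` means the interaction is weaker in
#' condition 2 (`lost`), `Z < 0` stronger (`gained`).
#'
#' @param z candidate x sample z-score matrix (from
#'   [score_union_loops()]).
#' @param condition named or positional character vector giving each
#'   sample's condition; exactly two levels, the second is the treatment.
#' @param mode `"all_combinations"` or `"matched_pairs"`.
#' @param alpha significance threshold on the raw p-value.
#' @return Data frame `Z`, `k`, `p`, `significant`, `direction`.
#' @export
differential_loop_meta <- function(z, condition,
                                   mode = c("all_combinations",
                                            "matched_pairs"),
                                   alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(ncol(z) == length(condition))
  cond <- factor(condition)
  if (nlevels(cond) != 2) stop("condition must have exactly two levels")
  sds <- apply(z, 2, function(x) sd(x))
  flat <- which(nrow(z) > 1 & sds == 0)
  if (length(flat))
    stop("zero variance in scores of sample(s): ",
         paste(colnames(z)[flat], collapse = ", "))
  i1 <- which(cond == levels(cond)[1])
  i2 <- which(cond == levels(cond)[2])
  if (mode == "matched_pairs") {
    if (length(i1) != length(i2))
      stop("matched_pairs requires equal replicate counts")
    ds <- z[, i1, drop = FALSE] - z[, i2, drop = FALSE]
  } else {
    pairs <- expand.grid(x = i1, y = i2)
    ds <- z[, pairs$x, drop = FALSE] - z[, pairs$y, drop = FALSE]
  }
  k <- ncol(ds)
  Z <- rowSums(ds) / sqrt(k)
  p <- 2 * pnorm(-abs(Z))
  sig <- p < alpha
  direction <- ifelse(sig & Z > 0, "lost", ifelse(sig & Z < 0, "gained",
                                                  "unchanged"))
  data.frame(Z = Z, k = k, p = p, significant = sig, direction = direction,
             stringsAsFactors = FALSE)
}

#' Full per-chromosome differential loop analysis
#'
#' Convenience wrapper: O/E-normalize and smooth each sample's raw map,
#' call loops per sample, score the union and run the Stouffer meta test.
#'
#' @param samples list of samples (`id`, `condition`, `maps` keyed by
#'   chromosome) as produced by [simulate_hic_experiment()].
#' @param chrom chromosome to analyse.
#' @param p,w,m_min,d_min,d_max,score_min loop-calling parameters.
#' @param sigma,alpha_blend smoothing parameters, see [smooth_impute()].
#' @param mode,alpha meta-analysis parameters.
#' @return List with `candidates`, `scores`, `z`, `meta` (the
#'   [differential_loop_meta()] table bound to candidate coordinates),
#'   `bin_size`, and the per-sample `calls`.
#' @export
differential_loops <- function(samples, chrom, p = 1, w = 5, m_min = 3,
                               d_min = 3, d_max = 200, score_min = 2,
                               sigma = 1, alpha_blend = 0.5,
                               mode = "all_combinations", alpha = 0.05) {
  ids <- vapply(samples, `[[`, "", "id")
  condition <- vapply(samples, `[[`, "", "condition")
  maps <- lapply(samples, function(s)
    smooth_impute(oe_normalize(s$maps[[chrom]]), sigma, alpha_blend))
  names(maps) <- ids
  calls <- lapply(maps, call_loops, p = p, w = w, m_min = m_min,
                  d_min = d_min, d_max = d_max, score_min = score_min)
  un <- score_union_loops(maps, calls, p, w, m_min)
  un$candidates <- cbind(chrom = chrom, un$candidates)
  meta <- differential_loop_meta(un$z, condition, mode = mode, alpha = alpha)
  list(candidates = un$candidates, scores = un$scores, z = un$z,
       meta = cbind(un$candidates, meta),
       bin_size = samples[[1]]$maps[[chrom]]$bin_size, calls = calls,
       chrom = chrom)
}

.anchor_intervals <- function(meta, chrom, bin_size) {
  rbind(
    data.frame(chrom = chrom, start = (meta$i - 1) * bin_size,
               end = meta$i * bin_size, loop = seq_len(nrow(meta))),
    data.frame(chrom = chrom, start = (meta$j - 1) * bin_size,
               end = meta$j * bin_size, loop = seq_len(nrow(meta))))
}

#' Genomic summaries of differential interactions
#'
#' Tabulates significant differential loops per chromosome, ranks gene
#' promoters by the number of significant loops with an anchor inside the
#' TSS window, and ranks sliding hotspot windows by the number of fully
#' contained significant anchors.
#'
#' @param diffs data frame: candidate coordinates (`chrom`, `i`, `j`) with
#'   `significant` flags, plus attribute columns from
#'   [differential_loops()]'s `meta`.
#' @param bin_size bin width in bp.
#' @param genes gene table (`gene`, `chrom`, `strand`, `tss`, `tts`).
#' @param tss_halfwidth promoter window half-width in bp.
#' @param hotspot_window hotspot window width in bp (step = half width).
#' @param chrom_lengths named chromosome lengths for window tiling.
#' @return List with `per_chromosome`, `promoters` (ranked), `hotspots`
#'   (ranked).
#' @export
interaction_change_summary <- function(diffs, bin_size, genes,
                                       tss_halfwidth = 5000,
                                       hotspot_window = 1e6,
                                       chrom_lengths = NULL) {
  sig <- diffs[diffs$significant, , drop = FALSE]
  tb <- table(sig$chrom)
  per_chrom <- data.frame(chrom = names(tb),
                          n_significant = as.integer(tb),
                          stringsAsFactors = FALSE)
  # promoter ranking
  prom <- data.frame(gene = genes$gene, count = 0L,
                     stringsAsFactors = FALSE)
  if (nrow(sig)) {
    for (g in seq_len(nrow(genes))) {
      win_lo <- genes$tss[g] - tss_halfwidth
      win_hi <- genes$tss[g] + tss_halfwidth
      on_chr <- sig[sig$chrom == genes$chrom[g], , drop = FALSE]
      if (!nrow(on_chr)) next
      a1_lo <- (on_chr$i - 1) * bin_size; a1_hi <- on_chr$i * bin_size
      a2_lo <- (on_chr$j - 1) * bin_size; a2_hi <- on_chr$j * bin_size
      hit <- (a1_lo < win_hi & a1_hi > win_lo) |
        (a2_lo < win_hi & a2_hi > win_lo)
      prom$count[g] <- sum(hit)
    }
  }
  prom <- prom[order(-prom$count, prom$gene), , drop = FALSE]
  rownames(prom) <- NULL
  # hotspot windows
  hs <- NULL
  if (nrow(sig)) {
    anchors <- .anchor_intervals(sig, sig$chrom, bin_size)
    hs_list <- list()
    for (ch in unique(anchors$chrom)) {
      an <- anchors[anchors$chrom == ch, , drop = FALSE]
      len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
        chrom_lengths[[ch]] else max(an$end)
      step <- hotspot_window / 2
      starts <- seq(0, max(0, len - 1), by = step)
      cnt <- vapply(starts, function(s0)
        sum(an$start >= s0 & an$end <= s0 + hotspot_window), 0)
      hs_list[[ch]] <- data.frame(chrom = ch, start = starts,
                                  end = pmin(len, starts + hotspot_window),
                                  n_anchors = cnt, stringsAsFactors = FALSE)
    }
    hs <- do.call(rbind, hs_list)
    hs <- hs[order(-hs$n_anchors, hs$chrom, hs$start), , drop = FALSE]
    rownames(hs) <- NULL
  }
  list(per_chromosome = per_chrom, promoters = prom, hotspots = hs)
}

#' Locus-level enrichment of loop rearrangements
#'
#' Counts, for every locus, the significant differential loops with an
#' anchor intersecting a window of `halfwidth` bp around the locus centre,
#' then compares the subset's counts against all loci with Welch's
#' unequal-variance t test.
#'
#' @param diffs significant-flagged loop table (`chrom`, `i`, `j`,
#'   `significant`).
#' @param bin_size bin width in bp.
#' @param loci_all data frame of reference loci with `chrom` and `center`
#'   columns (e.g., all TSS).
#' @param loci_subset data frame of the focal loci (same columns),
#'   typically a subset of `loci_all`.
#' @param halfwidth window half-width in bp.
#' @param side `"two.sided"`, `"greater"` (subset more enriched) or
#'   `"less"`.
#' @return List with `mean_all`, `mean_subset`, `t`, `p`, `counts_all`,
#'   `counts_subset`.
#' @export
locus_rearrangement_enrichment <- function(diffs, bin_size, loci_all,
                                           loci_subset, halfwidth = 25000,
                                           side = "two.sided") {
  if (!nrow(loci_subset)) stop("empty locus subset")
  sig <- diffs[diffs$significant, , drop = FALSE]
  count_at <- function(ch, center) {
    on_chr <- sig[sig$chrom == ch, , drop = FALSE]
    if (!nrow(on_chr)) return(0L)
    lo <- center - halfwidth; hi <- center + halfwidth
    a1_lo <- (on_chr$i - 1) * bin_size; a1_hi <- on_chr$i * bin_size
    a2_lo <- (on_chr$j - 1) * bin_size; a2_hi <- on_chr$j * bin_size
    sum((a1_lo < hi & a1_hi > lo) | (a2_lo < hi & a2_hi > lo))
  }
  counts_of <- function(loci) vapply(seq_len(nrow(loci)), function(k)
    count_at(loci$chrom[k], loci$center[k]), 0L)
  counts_all <- counts_of(loci_all)
  counts_subset <- counts_of(loci_subset)
  if (length(counts_subset) < 2 || length(counts_all) < 2)
    stop("need at least two loci in each group")
  if (var(counts_subset) == 0 && var(counts_all) == 0)
    stop("zero variance in both groups; t statistic undefined")
  tt <- t.test(counts_subset, counts_all, var.equal = FALSE,
               alternative = side)
  list(mean_all = mean(counts_all), mean_subset = mean(counts_subset),
       t = unname(tt$statistic), p = tt$p.value,
       counts_all = counts_all, counts_subset = counts_subset)
}
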