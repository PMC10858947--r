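# Background-based normalization of fragment coverage: size filter, window
# peak calling on pooled fragments, peak-flank extraction, median-of-ratios
# size factors on flank counts, and depth equalization by random thinning.

.midpoints <- function(frags) (frags$start + frags$end) / 2

#' Filter fragments by size
#'
#' Retains fragments with length strictly below `max_len`, the convention
#' used for nucleosome-free selection: 120 bp for transcription-factor
#' CUT&RUN, 150 bp for ATAC. Order is preserved.
#'
#' @param sample list with `id`, `condition`, `fragments` (interval data
#'   frame), or a bare fragment data frame.
#' @param max_len size threshold in bp (exclusive).
#' @return Same shape as the input, filtered.
#' @export
filter_fragments_by_size <- function(sample, max_len) {
  stopifnot(max_len > 0)
  bare <- is.data.frame(sample)
  frags <- if (bare) sample else sample$fragments
  keep <- (frags$end - frags$start) < max_len
  message(sprintf("size filter < %d bp: kept %d of %d fragments", max_len,
                  sum(keep), length(keep)))
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (bare) return(out)
  sample$fragments <- out
  sample
}

#' Default fragment-size filter per assay
#'
#' @param assay one of `"tf"` (TF CUT&RUN, < 120 bp), `"atac"` (< 150 bp),
#'   `"histone"` or `"chip"` (no filter).
#' @return Size threshold in bp, or `Inf` for no filtering.
#' @export
assay_size_filter <- function(assay = c("tf", "atac", "histone", "chip")) {
  switch(match.arg(assay), tf = 120, atac = 150, histone = Inf, chip = Inf)
}

#' Call enriched regions from pooled fragments
#'
#' A window-based Poisson enrichment caller: the genome is tiled into fixed
#' windows, fragments are assigned to windows by midpoint, and each window's
#' count is tested against the uniform background rate
#' `lambda = N * window / genome_len` with an upper-tail Poisson test.
#' Windows significant after BH correction are merged when separated by at
#' most one window; each merged region reports the minimum member-window raw
#' p-value.
#'
#' @param fragments pooled fragment data frame (`chrom`, `start`, `end`).
#' @param genome_len genome length in bp.
#' @param window window size in bp.
#' @param alpha BH-adjusted significance threshold.
#' @return Data frame of regions `chrom`, `start`, `end`, `p`.
#' @export
call_enriched_regions <- function(fragments, genome_len, window = 500,
                                  alpha = 0.05) {
  if (genome_len <= 0) stop("genome_len must be positive")
  stopifnot(window > 0)
  if (nrow(fragments) == 0) stop("no fragments to call regions from")
  n_win <- ceiling(genome_len / window)
  mid <- .midpoints(fragments)
  widx <- pmin(n_win, floor(mid / window) + 1L)
  counts <- tabulate(widx, nbins = n_win)
  lambda <- nrow(fragments) * window / genome_len
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  sig <- which(padj < alpha)
  if (!length(sig))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  # merge significant windows with gap <= 1 window
  grp <- cumsum(c(1, diff(sig) > 2))
  chrom <- if (nrow(fragments)) fragments$chrom[1] else "chrS"
  out <- do.call(rbind, lapply(split(sig, grp), function(w)
    data.frame(chrom = chrom,
               start = (min(w) - 1) * window,
               end = min(genome_len, max(w) * window),
               p = min(p[w]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Peak-flanking background regions
#'
#' For each peak, emits a left flank `[start-flank, start)` and a right
#' flank `[end, end+flank)`, clipped to the chromosome, with any overlap
#' with any peak subtracted; empty results are dropped. These regions hold
#' background reads and drive the size-factor estimate.
#'
#' @param peaks interval data frame.
#' @param flank flank width in bp on each side.
#' @param genome_len chromosome length for clipping (single-chromosome
#'   coordinate space); use `Inf` for no right clipping.
#' @return Interval data frame of background regions.
#' @export
flank_regions <- function(peaks, flank = 5000, genome_len = Inf) {
  stopifnot(flank > 0)
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    # IRanges is 1-based closed; shift 0-based half-open [s,e) to [s+1, e]
    pk_ir <- IRanges::IRanges(start = pk$start + 1, end = pk$end)
    cand <- c(IRanges::IRanges(start = pmax(0, pk$start - flank) + 1,
                               end = pmax(0, pk$start)),
              IRanges::IRanges(start = pk$end + 1,
                               end = if (is.finite(genome_len))
                                 pmin(genome_len, pk$end + flank)
                               else pk$end + flank))
    cand <- cand[IRanges::width(cand) > 0]
    kept <- IRanges::setdiff(IRanges::reduce(cand), IRanges::reduce(pk_ir))
    if (length(kept))
      out[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(kept) - 1,
                              end = IRanges::end(kept),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count fragment midpoints in regions
#'
#' @param samples list of samples (`id`, `fragments`).
#' @param regions interval data frame.
#' @return List with `regions`, `samples` (ids) and integer `counts`
#'   (region x sample).
#' @export
count_fragments_in_regions <- function(samples, regions) {
  ids <- vapply(samples, `[[`, "", "id")
  counts <- matrix(0L, nrow(regions), length(samples),
                   dimnames = list(NULL, ids))
  for (s in seq_along(samples)) {
    fr <- samples[[s]]$fragments
    for (ch in unique(regions$chrom)) {
      rg <- which(regions$chrom == ch)
      fch <- fr[fr$chrom == ch, , drop = FALSE]
      if (!nrow(fch)) next
      mid <- floor(.midpoints(fch))
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(start = mid + 1, width = 1L),
        IRanges::IRanges(start = regions$start[rg] + 1,
                         end = regions$end[rg]))
      tab <- tabulate(S4Vectors::subjectHits(hit), nbins = length(rg))
      counts[rg, s] <- counts[rg, s] + tab
    }
  }
  list(regions = regions, samples = ids, counts = counts)
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: for each region the geometric mean of counts
#' across samples is the pseudo-reference; a sample's size factor is the
#' median, over regions whose geometric mean is positive, of the ratio of
#' its count to the reference.
#'
#' @param counts a region-count object from [count_fragments_in_regions()],
#'   or a bare numeric matrix (regions x samples).
#' @return Named vector of size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts$counts
  if (ncol(m) < 2) stop("need at least two samples")
  logm <- log(m)
  ok <- rowSums(!is.finite(logm)) == 0   # rows with all-positive counts
  if (!any(ok))
    stop("no region with positive counts in every sample; ",
         "cannot estimate size factors")
  logg <- rowMeans(logm[ok, , drop = FALSE])
  sf <- apply(logm[ok, , drop = FALSE], 2, function(col)
    exp(median(col - logg)))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Thin fragments to equalized background depth
#'
#' Retention rate for sample j is `min(sf)/sf_j`, so the relatively deepest
#' samples are down-sampled to the shallowest and no rate exceeds 1; each
#' fragment is kept independently with that probability.
#'
#' @param sample a sample list (`id`, `fragments`).
#' @param sf named size-factor vector covering the sample id.
#' @param seed integer seed for the Bernoulli thinning.
#' @return The sample with thinned fragments; the realized retention rate is
#'   reported via `message()`.
#' @export
thin_fragments <- function(sample, sf, seed = 1) {
  if (!sample$id %in% names(sf)) stop("sample ", sample$id, " not in sf")
  r <- min(sf) / sf[[sample$id]]
  n <- nrow(sample$fragments)
  set.seed(seed)
  keep <- if (r >= 1) rep(TRUE, n) else rbinom(n, 1L, r) == 1L
  message(sprintf("thinning %s at rate %.4f: kept %d of %d", sample$id, r,
                  sum(keep), n))
  sample$fragments <- sample$fragments[keep, , drop = FALSE]
  rownames(sample$fragments) <- NULL
  sample
}

#' Background-normalize a set of fragment samples
#'
#' The full chain: pool all samples' fragments, call enriched regions,
#' derive peak-flanking background regions, count flank reads per sample,
#' estimate median-of-ratios size factors and thin every sample to the
#' common background depth.
#'
#' @param samples list of samples (`id`, `condition`, `fragments`).
#' @param genome_len genome length in bp.
#' @param window peak-caller window (bp).
#' @param flank flank width (bp).
#' @param alpha peak-caller BH threshold.
#' @param seed integer seed; per-sample thinning seeds are derived from it.
#' @return List with `samples` (thinned), `peaks`, `flanks`, `sf`.
#' @export
normalize_background <- function(samples, genome_len, window = 500,
                                 flank = 5000, alpha = 0.05, seed = 1) {
  pooled <- do.call(rbind, lapply(samples, `[[`, "fragments"))
  peaks <- call_enriched_regions(pooled, genome_len, window, alpha)
  if (nrow(peaks) == 0) stop("no enriched regions found; cannot normalize")
  flanks <- flank_regions(peaks, flank, genome_len)
  cm <- count_fragments_in_regions(samples, flanks)
  sf <- size_factors_median_of_ratios(cm)
  thinned <- lapply(seq_along(samples), function(s)
    thin_fragments(samples[[s]], sf, seed = seed + s))
  names(thinned) <- names(samples)
  list(samples = thinned, peaks = peaks, flanks = flanks, sf = sf)
}
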