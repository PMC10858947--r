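# A/B compartment analysis: leading eigenvector of the O/E correlation
# matrix with TSS-based sign orientation, saddle-plot coarse-graining with
# low-coverage removal, corner interaction strengths, differential saddles,
# and the compartment switching fraction.

#' Compartment eigenvector (PC1) with TSS orientation
#'
#' Computes the O/E matrix on valid bins, the Pearson correlation matrix of
#' its columns, and its leading eigenvector. The sign is oriented so that
#' the sign class with the higher mean TSS density per bin is positive
#' (the A compartment); with equal densities the vector is left as computed
#' and flagged ambiguous (with a deterministic canonical sign).
#'
#' @param map a raw [contact_map()], conventionally at 50 kb resolution.
#' @param tss numeric vector of TSS positions (bp) on the chromosome.
#' @return List of class `compartment_track`: `chrom`, `bin_size`, `pc1`
#'   (full-length, `NA` on invalid bins), `valid_mask`, `coverage`,
#'   `orientation_fixed`, `ambiguous`.
#' @export
compartment_pc1 <- function(map, tss) {
  stopifnot(inherits(map, "contact_map"))
  if (sum(map$valid_mask) < 10) stop("need at least 10 valid bins")
  oe <- oe_normalize(map)
  vi <- which(map$valid_mask)
  sub <- oe$values[vi, vi, drop = FALSE]
  if (all(is.na(sub))) stop("no defined O/E cells on valid bins")
  cm <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  if (any(!is.finite(cm))) {
    bad <- !is.finite(cm)
    if (all(bad)) stop("degenerate correlation matrix (constant O/E)")
    cm[bad] <- 0
  }
  sdc <- apply(sub, 2, sd, na.rm = TRUE)
  if (all(sdc == 0 | is.na(sdc)))
    stop("degenerate correlation matrix (constant O/E)")
  eg <- eigen(cm, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  # TSS density per valid bin
  bin_of <- pmin(map$n_bins, floor(tss / map$bin_size) + 1L)
  tss_cnt <- tabulate(bin_of, nbins = map$n_bins)[vi]
  pos <- v1 > 0; neg <- v1 < 0
  dens_pos <- if (any(pos)) mean(tss_cnt[pos]) else NA
  dens_neg <- if (any(neg)) mean(tss_cnt[neg]) else NA
  ambiguous <- FALSE
  if (is.na(dens_pos) || is.na(dens_neg) || dens_pos == dens_neg) {
    ambiguous <- TRUE
    # canonical sign for reproducibility: first nonzero entry positive
    nz <- which(v1 != 0)[1]
    if (!is.na(nz) && v1[nz] < 0) v1 <- -v1
  } else if (dens_neg > dens_pos) {
    v1 <- -v1
  }
  pc1 <- rep(NA_real_, map$n_bins)
  pc1[vi] <- v1
  structure(list(chrom = map$chrom, bin_size = map$bin_size, pc1 = pc1,
                 valid_mask = map$valid_mask, coverage = map$coverage,
                 orientation_fixed = !ambiguous, ambiguous = ambiguous),
            class = "compartment_track")
}

.percentile_groups <- function(n, n_groups = 100) {
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  rep(seq_len(n_groups), times = sizes)
}

#' Saddle-plot analysis of compartmentalization strength
#'
#' Per chromosome: the 1% (ceiling) lowest-coverage valid bins are removed,
#' the rest are ranked by PC1 from high to low and partitioned into
#' `n_groups` contiguous rank groups of near-equal size (remainder spread
#' over the leading groups); element `(m, n)` of the coarse-grained matrix
#' is the mean O/E between group-m and group-n bins over defined cells.
#' Chromosome matrices are averaged without weighting. `AA` is the mean of
#' the top-left quarter block, `BB` bottom-right, `AB` top-right.
#'
#' @param oe_maps named list of O/E [contact_map()]s per chromosome (or a
#'   single map).
#' @param tracks matching named list of [compartment_pc1()] tracks.
#' @param n_groups number of percentile groups (default 100).
#' @param drop_frac fraction of lowest-coverage bins removed (default 1%).
#' @return List of class `saddle_result`: `S` (`n_groups` square matrix),
#'   `AA`, `BB`, `AB`, `bins_used` (named per chromosome).
#' @export
saddle_analysis <- function(oe_maps, tracks, n_groups = 100,
                            drop_frac = 0.01) {
  if (inherits(oe_maps, "contact_map"))
    oe_maps <- setNames(list(oe_maps), oe_maps$chrom)
  if (inherits(tracks, "compartment_track"))
    tracks <- setNames(list(tracks), tracks$chrom)
  acc <- matrix(0, n_groups, n_groups)
  nacc <- matrix(0, n_groups, n_groups)
  bins_used <- c()
  for (ch in names(oe_maps)) {
    mp <- oe_maps[[ch]]
    tr <- tracks[[ch]]
    if (is.null(tr)) stop("no compartment track for ", ch)
    if (tr$bin_size != mp$bin_size || length(tr$pc1) != mp$n_bins)
      stop("track and map bin grids mismatched for ", ch)
    vi <- which(mp$valid_mask & !is.na(tr$pc1))
    n_drop <- ceiling(drop_frac * length(vi))
    if (n_drop > 0) {
      drop <- vi[order(mp$coverage[vi])][seq_len(n_drop)]
      vi <- setdiff(vi, drop)
    }
    if (length(vi) < n_groups) {
      message("chromosome ", ch, " skipped: fewer than ", n_groups,
              " usable bins")
      next
    }
    vi <- vi[order(-tr$pc1[vi])]
    grp <- .percentile_groups(length(vi), n_groups)
    sub <- mp$values[vi, vi, drop = FALSE]
    def <- !is.na(sub)
    sub0 <- ifelse(def, sub, 0)
    gi <- factor(grp, levels = seq_len(n_groups))
    sums <- rowsum(t(rowsum(sub0, gi)), gi)        # n_groups x n_groups
    cnts <- rowsum(t(rowsum(def + 0, gi)), gi)
    S_chr <- ifelse(cnts > 0, sums / cnts, NA)
    ok <- !is.na(S_chr)
    acc[ok] <- acc[ok] + S_chr[ok]
    nacc <- nacc + ok
    bins_used[ch] <- length(vi)
  }
  if (!length(bins_used)) stop("no chromosome had enough usable bins")
  S <- ifelse(nacc > 0, acc / nacc, NA)
  dimnames(S) <- NULL
  q <- floor(n_groups / 4)
  top <- seq_len(q); bot <- (n_groups - q + 1):n_groups
  structure(list(S = S,
                 AA = mean(S[top, top], na.rm = TRUE),
                 BB = mean(S[bot, bot], na.rm = TRUE),
                 AB = mean(S[top, bot], na.rm = TRUE),
                 bins_used = bins_used),
            class = "saddle_result")
}

#' Differential saddle: element-wise log2 fold change
#'
#' @param a,b [saddle_analysis()] results on the same grid.
#' @return Matrix `log2(a$S / b$S)`; cells undefined or non-positive on
#'   either side are `NA`.
#' @export
saddle_diff <- function(a, b) {
  stopifnot(inherits(a, "saddle_result"), inherits(b, "saddle_result"),
            all(dim(a$S) == dim(b$S)))
  out <- log2(a$S / b$S)
  out[is.na(a$S) | is.na(b$S) | a$S <= 0 | b$S <= 0] <- NA
  out
}

#' Fraction of bins switching compartment
#'
#' @param a,b oriented [compartment_pc1()] tracks on the same grid.
#' @return Fraction of commonly valid bins (with nonzero PC1 in both) whose
#'   PC1 signs disagree.
#' @export
switching_fraction <- function(a, b) {
  stopifnot(inherits(a, "compartment_track"),
            inherits(b, "compartment_track"),
            length(a$pc1) == length(b$pc1))
  ok <- !is.na(a$pc1) & !is.na(b$pc1) & a$pc1 != 0 & b$pc1 != 0
  if (!any(ok)) stop("no common valid bins")
  mean(sign(a$pc1[ok]) != sign(b$pc1[ok]))
}
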