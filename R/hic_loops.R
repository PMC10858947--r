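# Loop detection on cis contact maps: distance-decay (O/E) normalization,
# masked Gaussian-kernel smoothing/imputation, donut-style local-background
# scoring, and greedy loop calling.

#' Observed-over-expected normalization
#'
#' Divides each cell by the mean of defined cells at its genomic distance,
#' removing the distance-decay trend. Sparse far diagonals (fewer than
#' `min_cells` defined cells) are pooled with progressively farther
#' diagonals until the pool reaches `min_cells`, sharing one expected value.
#' Missing cells stay missing.
#'
#' @param map a [contact_map()].
#' @param min_cells minimum defined cells per expected-value estimate.
#' @return A [contact_map()] of O/E ratios (coverage field retains the raw
#'   marginal counts of the input).
#' @export
oe_normalize <- function(map, min_cells = 10) {
  stopifnot(inherits(map, "contact_map"))
  v <- map$values
  n <- map$n_bins
  if (all(is.na(v))) stop("all cells missing; cannot normalize")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  def <- !is.na(v)
  # per-diagonal sums and defined-cell counts (distance 0..n-1)
  di <- d[def] + 1L
  sums <- rep(0, n); cnts <- rep(0, n)
  agg <- rowsum(v[def], di)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  agc <- rowsum(rep(1, length(di)), di)
  cnts[as.integer(rownames(agc))] <- agc[, 1]
  expected <- rep(NA_real_, n)
  k <- 1
  while (k <= n) {
    k2 <- k
    while (sum(cnts[k:k2]) < min_cells && k2 < n) k2 <- k2 + 1
    tot <- sum(cnts[k:k2])
    if (tot > 0) expected[k:k2] <- sum(sums[k:k2]) / tot
    k <- k2 + 1
  }
  e_of_cell <- matrix(expected[d + 1], n, n)
  oe <- v / e_of_cell
  oe[!def | is.na(e_of_cell) | e_of_cell == 0] <- NA
  out <- map
  out$values <- oe
  out
}

.shift_mat <- function(m, da, db) {
  # out[i, j] = m[i + da, j + db], zero outside
  n <- nrow(m)
  out <- matrix(0, n, n)
  ri <- max(1, 1 + da):min(n, n + da)
  rj <- max(1, 1 + db):min(n, n + db)
  if (length(ri) && length(rj))
    out[ri - da, rj - db] <- m[ri, rj]
  out
}

#' Masked Gaussian smoothing and imputation
#'
#' A kernel-based stand-in for model-based imputation: every cell's local
#' Gaussian-weighted mean `K` over defined neighbours within a Chebyshev
#' radius of 2 bins fills missing cells and is blended with observed values
#' as `alpha*observed + (1-alpha)*K`. Cells with no defined neighbour stay
#' missing; symmetry is preserved.
#'
#' @param map an O/E [contact_map()].
#' @param sigma Gaussian kernel standard deviation in bins.
#' @param alpha blending weight on the observed value, in `[0, 1]`;
#'   `alpha = 1` leaves defined cells untouched and only fills gaps.
#' @return Smoothed [contact_map()].
#' @export
smooth_impute <- function(map, sigma = 1, alpha = 0.5) {
  stopifnot(inherits(map, "contact_map"), sigma > 0, alpha >= 0, alpha <= 1)
  v <- map$values
  def <- !is.na(v)
  v0 <- ifelse(def, v, 0)
  num <- matrix(0, nrow(v), ncol(v))
  den <- matrix(0, nrow(v), ncol(v))
  for (da in -2:2) for (db in -2:2) {
    wgt <- exp(-(da^2 + db^2) / (2 * sigma^2))
    num <- num + wgt * .shift_mat(v0, da, db)
    den <- den + wgt * .shift_mat(def + 0, da, db)
  }
  K <- ifelse(den > 0, num / den, NA)
  out_v <- ifelse(def, alpha * v + (1 - alpha) * K, K)
  out <- map
  out$values <- out_v
  out
}

.component_masks <- function(p, w) {
  off <- -w:w
  da <- matrix(off, 2 * w + 1, 2 * w + 1)
  db <- t(da)
  peak <- pmax(abs(da), abs(db)) <= p
  H <- abs(da) <= p & abs(db) > p & abs(db) <= w
  V <- abs(db) <= p & abs(da) > p & abs(da) <= w
  BL <- da > 0 & da <= w & (-db) > 0 & (-db) <= w & !peak
  D <- pmax(abs(da), abs(db)) <= w & !peak & !H & !V
  list(peak = peak, D = D, H = H, V = V, BL = BL, da = da, db = db)
}

#' Donut-style loop score at one candidate pixel
#'
#' The score of candidate `(i, j)` is the mean O/E over the peak window
#' divided by the strongest of four local-background estimates: the donut
#' `D`, the horizontal stripe `H`, the vertical stripe `V`, and the
#' lower-left quadrant `BL` (toward the diagonal). Offsets `(da, db)`
#' relative to `(i, j)` define the components: peak
#' `max(|da|,|db|) <= p`; H `|da| <= p, p < |db| <= w`; V symmetric; BL
#' `0 < da <= w, 0 < -db <= w` minus the peak; D the remainder of the
#' `(2w+1)^2` square. Each component is the mean of its defined cells.
#'
#' @param map smoothed O/E [contact_map()].
#' @param i,j bin indices (1-based), `i < j`.
#' @param p peak half-width in bins.
#' @param w outer half-width in bins (`p < w`).
#' @param m_min minimum defined cells required in every component.
#' @return List with `P`, `D`, `H`, `V`, `BL`, `score`, `valid`. A
#'   candidate whose `(2w+1)` square leaves the matrix, or with an
#'   under-populated component, or with an all-but-zero background is
#'   flagged `valid = FALSE` with `score = NA`.
#' @export
loop_score <- function(map, i, j, p = 1, w = 5, m_min = 3) {
  stopifnot(inherits(map, "contact_map"), p < w, i < j)
  n <- map$n_bins
  bad <- list(P = NA_real_, D = NA_real_, H = NA_real_, V = NA_real_,
              BL = NA_real_, score = NA_real_, valid = FALSE)
  if (i - w < 1 || i + w > n || j - w < 1 || j + w > n) return(bad)
  sub <- map$values[(i - w):(i + w), (j - w):(j + w)]
  mk <- .component_masks(p, w)
  comp <- function(mask) {
    x <- sub[mask]
    x <- x[!is.na(x)]
    if (length(x) < m_min) return(NA_real_)
    mean(x)
  }
  P <- comp(mk$peak); D <- comp(mk$D); H <- comp(mk$H); V <- comp(mk$V)
  BL <- comp(mk$BL)
  vals <- c(D, H, V, BL)
  if (any(is.na(c(P, vals))) || max(vals) <= 1e-9)
    return(list(P = P, D = D, H = H, V = V, BL = BL, score = NA_real_,
                valid = FALSE))
  list(P = P, D = D, H = H, V = V, BL = BL, score = P / max(vals),
       valid = TRUE)
}

#' Score every candidate pixel in a distance band
#'
#' Vectorized computation of the [loop_score()] components for all pixels
#' `(i, j)` with `d_min <= j - i <= d_max` whose scoring square fits inside
#' the matrix.
#'
#' @inheritParams loop_score
#' @param d_min,d_max distance band in bins.
#' @return Data frame `i`, `j`, `P`, `D`, `H`, `V`, `BL`, `score`, `valid`.
#' @export
score_candidates <- function(map, p = 1, w = 5, m_min = 3, d_min = 3,
                             d_max = 200) {
  stopifnot(inherits(map, "contact_map"), p < w, d_min >= p + 1)
  v <- map$values
  n <- map$n_bins
  def <- !is.na(v)
  v0 <- ifelse(def, v, 0)
  mk <- .component_masks(p, w)
  sums <- list(); cnts <- list()
  for (cn in c("peak", "D", "H", "V", "BL")) {
    sm <- matrix(0, n, n); ct <- matrix(0, n, n)
    sel <- which(mk[[cn]])
    for (kk in sel) {
      da <- mk$da[kk]; db <- mk$db[kk]
      sm <- sm + .shift_mat(v0, da, db)
      ct <- ct + .shift_mat(def + 0, da, db)
    }
    sums[[cn]] <- sm; cnts[[cn]] <- ct
  }
  dmat <- outer(seq_len(n), seq_len(n), function(a, b) b - a)
  inb <- row(v) - w >= 1 & row(v) + w <= n & col(v) - w >= 1 & col(v) + w <= n
  cand <- which(dmat >= d_min & dmat <= d_max & inb, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(i = integer(), j = integer(), P = numeric(),
                      D = numeric(), H = numeric(), V = numeric(),
                      BL = numeric(), score = numeric(), valid = logical()))
  getm <- function(cn) {
    s <- sums[[cn]][cand]; ctc <- cnts[[cn]][cand]
    ifelse(ctc >= m_min, s / ctc, NA)
  }
  P <- getm("peak"); D <- getm("D"); H <- getm("H"); V <- getm("V")
  BL <- getm("BL")
  bg <- pmax(D, H, V, BL)
  valid <- !is.na(P) & !is.na(D) & !is.na(H) & !is.na(V) & !is.na(BL) &
    bg > 1e-9
  score <- ifelse(valid, P / bg, NA)
  data.frame(i = cand[, 1], j = cand[, 2], P = P, D = D, H = H, V = V,
             BL = BL, score = score, valid = valid)
}

#' Call loops on a smoothed O/E map
#'
#' Scores every pixel in the distance band, keeps valid scores at or above
#' `score_min`, and applies greedy non-maximum suppression: candidates are
#' accepted in descending score order (ties broken by ascending `(i, j)`),
#' rejecting any candidate within Chebyshev radius `p` of an accepted one.
#'
#' @inheritParams score_candidates
#' @param score_min minimum accepted score.
#' @return Data frame of accepted loops `i`, `j`, `score` (plus component
#'   columns), sorted by descending score.
#' @export
call_loops <- function(map, p = 1, w = 5, m_min = 3, d_min = 3, d_max = 200,
                       score_min = 2) {
  sc <- score_candidates(map, p, w, m_min, d_min, d_max)
  sc <- sc[sc$valid & sc$score >= score_min, , drop = FALSE]
  if (!nrow(sc)) return(sc)
  sc <- sc[order(-sc$score, sc$i, sc$j), , drop = FALSE]
  acc_i <- integer(0); acc_j <- integer(0); keep <- logical(nrow(sc))
  for (k in seq_len(nrow(sc))) {
    if (!length(acc_i) ||
        all(pmax(abs(acc_i - sc$i[k]), abs(acc_j - sc$j[k])) > p)) {
      keep[k] <- TRUE
      acc_i <- c(acc_i, sc$i[k]); acc_j <- c(acc_j, sc$j[k])
    }
  }
  out <- sc[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert called loops to anchor-pair intervals
#'
#' @param calls data frame with `i`, `j` bin indices (1-based).
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param score optional score column name to carry through.
#' @return BEDPE-style data frame of anchor pairs.
#' @export
loops_to_bedpe <- function(calls, chrom, bin_size, score = "score") {
  data.frame(chrom1 = chrom, start1 = (calls$i - 1) * bin_size,
             end1 = calls$i * bin_size,
             chrom2 = chrom, start2 = (calls$j - 1) * bin_size,
             end2 = calls$j * bin_size,
             score = if (score %in% names(calls)) calls[[score]] else NA,
             stringsAsFactors = FALSE)
}
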