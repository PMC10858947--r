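# Synthetic experiments with planted ground truth.  These emulate the shape
# of the real data (distance decay, compartment checkerboard, focal loops,
# replicate depth variation, low-coverage bins; enriched fragment peaks with
# a bimodal length mixture) at desk scale, so that every downstream stage can
# be validated against known truth without external downloads.

#' Parameters for a synthetic Hi-C experiment
#'
#' Defaults describe the package's standard desk-scale experiment: one 4 Mb
#' chromosome at 10 kb resolution (400 bins), three replicates per condition
#' with mild depth variation, power-law distance decay with exponent 1, a
#' compartment checkerboard of strength 0.3 with 40-bin blocks, and a small
#' fraction of low-coverage bins.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param n_rep replicates per condition.
#' @param depth_factors list with elements `cond1`, `cond2`: per-replicate
#'   multiplicative depth factors (positive).
#' @param base_level expected count at distance 0 at depth 1 (before
#'   compartment/loop factors).
#' @param gamma distance-decay exponent; expected counts fall as
#'   `(1+d)^-gamma` in bin units.
#' @param comp_block_len compartment block length in bins.
#' @param comp_strength checkerboard strength `s` in `[0, 1)`: same-label
#'   cells are scaled by `1+s`, cross-label cells by `1-s`.
#' @param loops data frame with columns `chrom`, `i`, `j` (bin indices,
#'   1-based, `i < j`), `fc` (enrichment, > 1) and
#'   `status` in `shared`, `cond1_only`, `cond2_only`; may be `NULL`.
#' @param loop_halfwidth loops are enriched over a square window of
#'   `2*loop_halfwidth+1` bins centred on (i, j); the default 1 matches the
#'   default scoring peak half-width.
#' @param low_cov_frac fraction of bins whose expected counts are scaled by
#'   `low_cov_factor`.
#' @param low_cov_factor depletion factor for low-coverage bins.
#' @param tss_rate_a,tss_rate_b expected TSS count per bin in A and B
#'   compartment bins; TSS positions orient the compartment eigenvector.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A list of class `hic_sim_params`.
#' @export
hic_sim_params <- function(chrom_lengths = c(chrS = 4e6),
                           bin_size = 1e4,
                           n_rep = 3,
                           depth_factors = list(cond1 = c(1, 0.8, 1.25),
                                                cond2 = c(1.1, 0.9, 1)),
                           base_level = 150,
                           gamma = 1,
                           comp_block_len = 40,
                           comp_strength = 0.3,
                           loops = NULL,
                           loop_halfwidth = 1,
                           low_cov_frac = 0.03,
                           low_cov_factor = 0.05,
                           tss_rate_a = 1.5,
                           tss_rate_b = 0.15,
                           seed = 1) {
  stopifnot(all(chrom_lengths > 0), bin_size > 0, n_rep >= 1,
            base_level > 0, gamma > 0,
            comp_strength >= 0, comp_strength < 1,
            low_cov_frac >= 0, low_cov_frac < 1,
            all(unlist(depth_factors) > 0),
            length(depth_factors$cond1) == n_rep,
            length(depth_factors$cond2) == n_rep)
  if (!is.null(loops)) {
    stopifnot(all(c("chrom", "i", "j", "fc", "status") %in% names(loops)))
    if (any(loops$i >= loops$j)) stop("loop bins must satisfy i < j")
    if (any(loops$fc <= 1)) stop("loop enrichment fc must exceed 1")
    if (!all(loops$status %in% c("shared", "cond1_only", "cond2_only")))
      stop("unknown loop status")
  }
  structure(as.list(environment()), class = "hic_sim_params")
}

.expected_cis_matrix <- function(n, params, labels) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- params$base_level * (1 + d)^(-params$gamma)
  s <- params$comp_strength
  if (s > 0) {
    same <- outer(labels, labels, "==")
    e <- e * ifelse(same, 1 + s, 1 - s)
  }
  e
}

#' Simulate a two-condition Hi-C experiment with planted loops
#'
#' Expected counts follow `depth * base_level * (1+d)^-gamma`, modulated by a
#' compartment checkerboard (`1+s` within, `1-s` across), by planted loop
#' enrichment over a small square window when the loop is active in the
#' condition, and by a depletion factor for each low-coverage bin an
#' interaction touches. Observed counts are independent Poisson draws on the
#' upper triangle, mirrored to keep maps symmetric.
#'
#' @param params a [hic_sim_params()] object.
#' @return List with `samples` (each a list with `id`, `condition`, `maps`: a
#'   named list of [contact_map()] per chromosome) and `truth`: compartment
#'   labels, low-coverage flags, TSS positions, and the planted loop table.
#' @export
simulate_hic_experiment <- function(params) {
  stopifnot(inherits(params, "hic_sim_params"))
  set.seed(params$seed)
  n_bins_of <- floor(params$chrom_lengths / params$bin_size)
  truth <- list(compartments = list(), low_coverage = list(), tss = list(),
                loops = params$loops)
  # fixed per-chromosome structure shared by all samples
  structure_of <- list()
  for (ch in names(params$chrom_lengths)) {
    n <- n_bins_of[[ch]]
    if (!is.null(params$loops)) {
      lp <- params$loops[params$loops$chrom == ch, , drop = FALSE]
      if (nrow(lp) && (any(lp$i < 1) || any(lp$j > n)))
        stop("planted loop outside chromosome ", ch)
    }
    labels <- rep(rep(c("A", "B"), length.out = ceiling(n / params$comp_block_len)),
                  each = params$comp_block_len)[seq_len(n)]
    low <- runif(n) < params$low_cov_frac
    rate <- ifelse(labels == "A", params$tss_rate_a, params$tss_rate_b)
    tss_n <- rpois(n, rate)
    tss <- unlist(lapply(which(tss_n > 0), function(b)
      floor(runif(tss_n[b], (b - 1) * params$bin_size, b * params$bin_size))))
    truth$compartments[[ch]] <- labels
    truth$low_coverage[[ch]] <- low
    truth$tss[[ch]] <- sort(as.numeric(tss))
    structure_of[[ch]] <- list(labels = labels, low = low)
  }
  samples <- list()
  for (cond in c("cond1", "cond2")) {
    for (r in seq_len(params$n_rep)) {
      id <- sprintf("%s_rep%d", cond, r)
      depth <- params$depth_factors[[cond]][r]
      maps <- list()
      for (ch in names(params$chrom_lengths)) {
        n <- n_bins_of[[ch]]
        st <- structure_of[[ch]]
        e <- .expected_cis_matrix(n, params, st$labels) * depth
        if (!is.null(params$loops)) {
          lp <- params$loops[params$loops$chrom == ch, , drop = FALSE]
          active <- lp$status == "shared" |
            (cond == "cond1" & lp$status == "cond1_only") |
            (cond == "cond2" & lp$status == "cond2_only")
          hw <- params$loop_halfwidth
          for (k in which(active)) {
            ri <- max(1, lp$i[k] - hw):min(n, lp$i[k] + hw)
            rj <- max(1, lp$j[k] - hw):min(n, lp$j[k] + hw)
            e[ri, rj] <- e[ri, rj] * lp$fc[k]
            e[rj, ri] <- e[rj, ri] * lp$fc[k]
          }
        }
        lowfac <- ifelse(st$low, params$low_cov_factor, 1)
        e <- e * outer(lowfac, lowfac)
        obs <- matrix(0, n, n)
        ut <- upper.tri(obs, diag = TRUE)
        obs[ut] <- rpois(sum(ut), e[ut])
        obs <- obs + t(obs) - diag(diag(obs))
        maps[[ch]] <- contact_map(ch, params$bin_size, obs)
      }
      samples[[id]] <- list(id = id, condition = cond, maps = maps)
    }
  }
  list(samples = samples, truth = truth)
}

#' Parameters for a synthetic fragment-coverage experiment
#'
#' Emulates CUT&RUN/ATAC-style data: uniform background fragments plus focal
#' peaks whose intensity may differ between conditions, with a two-component
#' normal fragment-length mixture (nucleosome-free and mono-nucleosome
#' modes).
#'
#' @param genome_len genome length in bp (single synthetic chromosome
#'   `chrS`).
#' @param peaks data frame with `start`, `end` and per-condition intensity
#'   multipliers `mult1`, `mult2` (>= 0); `intensity` is the expected
#'   fragment count per peak at depth and multiplier 1.
#' @param intensity baseline expected fragments per peak.
#' @param background_rate expected background fragments per bp at depth 1.
#' @param frag_len_means,frag_len_sds,frag_len_weights two-component length
#'   mixture; weights must sum to 1.
#' @param n_rep replicates per condition.
#' @param depth_factors list `cond1`/`cond2` of per-replicate depths.
#' @param seed integer seed.
#' @return A list of class `frag_sim_params`.
#' @export
frag_sim_params <- function(genome_len = 1e7,
                            peaks = NULL,
                            intensity = 400,
                            background_rate = 0.01,
                            frag_len_means = c(70, 200),
                            frag_len_sds = c(15, 30),
                            frag_len_weights = c(0.6, 0.4),
                            n_rep = 3,
                            depth_factors = list(cond1 = c(1, 0.8, 1.2),
                                                 cond2 = c(0.9, 1.1, 1)),
                            seed = 1) {
  stopifnot(genome_len > 0, background_rate >= 0, intensity >= 0,
            abs(sum(frag_len_weights) - 1) < 1e-8,
            all(unlist(depth_factors) > 0),
            length(depth_factors$cond1) == n_rep,
            length(depth_factors$cond2) == n_rep)
  if (!is.null(peaks)) {
    stopifnot(all(c("start", "end", "mult1", "mult2") %in% names(peaks)))
    if (any(peaks$mult1 < 0) || any(peaks$mult2 < 0))
      stop("peak intensity multipliers must be >= 0")
    if (any(peaks$start < 0) || any(peaks$end > genome_len))
      stop("peak outside genome")
  }
  structure(as.list(environment()), class = "frag_sim_params")
}

.draw_fragments <- function(n, centers, params) {
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  comp <- sample.int(2L, n, replace = TRUE, prob = params$frag_len_weights)
  len <- pmax(1, round(rnorm(n, params$frag_len_means[comp],
                             params$frag_len_sds[comp])))
  start <- pmax(0, round(centers - len / 2))
  end <- pmin(params$genome_len, start + len)
  start <- pmin(start, end - 1)
  data.frame(chrom = "chrS", start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Simulate a two-condition fragment-coverage experiment
#'
#' Background fragment midpoints are uniform over the genome with a Poisson
#' total of `depth * background_rate * genome_len`; each peak adds a Poisson
#' `depth * intensity * mult` fragments with midpoints uniform inside the
#' peak. Fragment lengths come from the two-component normal mixture.
#'
#' @param params a [frag_sim_params()] object.
#' @return List with `samples` (each `id`, `condition`, `fragments` interval
#'   data frame) and `truth` (`peaks` with `direction` in
#'   gained/lost/unchanged w.r.t. condition 2).
#' @export
simulate_fragment_experiment <- function(params) {
  stopifnot(inherits(params, "frag_sim_params"))
  set.seed(params$seed)
  samples <- list()
  for (cond in c("cond1", "cond2")) {
    for (r in seq_len(params$n_rep)) {
      id <- sprintf("%s_rep%d", cond, r)
      depth <- params$depth_factors[[cond]][r]
      n_bg <- rpois(1, depth * params$background_rate * params$genome_len)
      centers <- runif(n_bg, 0, params$genome_len)
      if (!is.null(params$peaks) && nrow(params$peaks)) {
        mult <- if (cond == "cond1") params$peaks$mult1 else params$peaks$mult2
        n_pk <- rpois(nrow(params$peaks), depth * params$intensity * mult)
        pk_centers <- unlist(lapply(which(n_pk > 0), function(k)
          runif(n_pk[k], params$peaks$start[k], params$peaks$end[k])))
        centers <- c(centers, pk_centers)
      }
      samples[[id]] <- list(id = id, condition = cond,
                            fragments = .draw_fragments(length(centers),
                                                        centers, params))
    }
  }
  truth_peaks <- params$peaks
  if (!is.null(truth_peaks) && nrow(truth_peaks)) {
    truth_peaks$direction <- ifelse(
      truth_peaks$mult2 > truth_peaks$mult1, "gained",
      ifelse(truth_peaks$mult2 < truth_peaks$mult1, "lost", "unchanged"))
  }
  list(samples = samples, truth = list(peaks = truth_peaks))
}
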