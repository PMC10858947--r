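#' @importFrom stats median sd var rnorm rpois rbinom runif ppois phyper pnorm
#'   p.adjust cor t.test wilcox.test quantile setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# Coordinate convention used everywhere in this package: 0-based, half-open
# [start, end).  Bin b of a binned map spans [b*bin_size, (b+1)*bin_size).

#' Create a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `strand` plus arbitrary extra columns. Coordinates are 0-based
#' half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"`.
#' @param ... further equal-length columns carried along.
#' @return A data frame of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0) ||
      any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    df$strand <- strand
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

.parse_coord_cols <- function(fields, idx, lineno, what) {
  start <- suppressWarnings(as.numeric(fields[idx[1]]))
  end <- suppressWarnings(as.numeric(fields[idx[2]]))
  if (is.na(start) || is.na(end))
    stop(sprintf("line %d: non-numeric %s coordinates", lineno, what))
  if (start < 0 || start >= end)
    stop(sprintf("line %d: invalid %s interval [%s, %s)", lineno, what,
                 fields[idx[1]], fields[idx[2]]))
  c(start, end)
}

#' Read BED or BEDPE interval files
#'
#' Parses tab-separated interval files using 0-based half-open coordinates.
#' For BED, columns 4-6 are mapped to `name`, `score`, `strand` when present;
#' for BEDPE, columns 7-8 to `name`, `score`. Further columns are kept as
#' `extra1`, `extra2`, ... Input order is preserved.
#'
#' @param path file path.
#' @param kind `"bed"` or `"bedpe"`.
#' @return A data frame; for BEDPE the coordinate columns are
#'   `chrom1,start1,end1,chrom2,start2,end2`.
#' @export
read_intervals <- function(path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  need <- if (kind == "bed") 3L else 6L
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < need)
      stop(sprintf("line %d: expected >= %d columns, got %d", k, need,
                   length(f)))
    if (kind == "bed") {
      se <- .parse_coord_cols(f, c(2L, 3L), k, "bed")
      row <- list(chrom = f[1], start = se[1], end = se[2])
      if (length(f) >= 4) row$name <- f[4]
      if (length(f) >= 5) row$score <- suppressWarnings(as.numeric(f[5]))
      if (length(f) >= 6) row$strand <- f[6]
      if (length(f) > 6)
        for (j in 7:length(f)) row[[paste0("extra", j - 6L)]] <- f[j]
    } else {
      se1 <- .parse_coord_cols(f, c(2L, 3L), k, "first")
      se2 <- .parse_coord_cols(f, c(5L, 6L), k, "second")
      row <- list(chrom1 = f[1], start1 = se1[1], end1 = se1[2],
                  chrom2 = f[4], start2 = se2[1], end2 = se2[2])
      if (length(f) >= 7) row$name <- f[7]
      if (length(f) >= 8) row$score <- suppressWarnings(as.numeric(f[8]))
      if (length(f) > 8)
        for (j in 9:length(f)) row[[paste0("extra", j - 8L)]] <- f[j]
    }
    rows[[k]] <- row
  }
  if (length(rows) == 0) {
    if (kind == "bed")
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn)
    unlist(lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write intervals as BED or BEDPE
#'
#' @param x data frame as returned by [read_intervals()].
#' @param path output path.
#' @param kind `"bed"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  base <- if (kind == "bed") c("chrom", "start", "end")
          else c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  opt <- if (kind == "bed") c("name", "score", "strand") else c("name", "score")
  extras <- grep("^extra", names(x), value = TRUE)
  present <- c(opt[opt %in% names(x)], extras)
  # BED optional columns must be contiguous: pad any gap with "."
  n_opt <- if (length(present)) max(match(present, c(opt, extras))) else 0L
  df <- x[, base, drop = FALSE]
  for (cn in head(c(opt, extras), n_opt))
    df[[cn]] <- if (cn %in% names(x)) x[[cn]] else "."
  for (cn in names(df)) if (is.numeric(df[[cn]]))
    df[[cn]] <- format(df[[cn]], trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a binned cis contact map
#'
#' A symmetric per-chromosome matrix of interaction counts (or O/E ratios)
#' with an explicit distinction between observed zero and missing: cells
#' involving a bin with zero total coverage are `NA` and such bins are
#' flagged invalid in `valid_mask`.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param values symmetric numeric matrix, `NA` for missing cells.
#' @param valid_mask optional logical per-bin vector; defaults to bins with
#'   positive marginal coverage.
#' @return An object of class `contact_map` with fields `chrom`, `bin_size`,
#'   `n_bins`, `values`, `valid_mask`, `coverage`.
#' @export
contact_map <- function(chrom, bin_size, values, valid_mask = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  vals <- values
  bad <- !is.na(vals) & vals < 0
  if (any(bad)) stop("contact map values must be non-negative")
  asym <- which(!is.na(vals) & !is.na(t(vals)) & abs(vals - t(vals)) > 1e-8)
  if (length(asym)) stop("contact map values must be symmetric")
  coverage <- rowSums(vals, na.rm = TRUE)
  if (is.null(valid_mask)) valid_mask <- coverage > 0
  stopifnot(length(valid_mask) == nrow(vals))
  vals[!valid_mask, ] <- NA
  vals[, !valid_mask] <- NA
  structure(list(chrom = as.character(chrom), bin_size = bin_size,
                 n_bins = nrow(vals), values = vals,
                 valid_mask = valid_mask,
                 coverage = rowSums(vals, na.rm = TRUE)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins of %s bp, %d valid\n", x$chrom,
              x$n_bins, format(x$bin_size, scientific = FALSE),
              sum(x$valid_mask)))
  invisible(x)
}

#' Read a contact map in triplet + bin-table form
#'
#' The bin table is BED with the absolute bin id in column 4; the matrix file
#' holds whitespace-separated `id_i id_j value` triplets (upper triangle is
#' sufficient). Bins without any observed contact are masked; their cells are
#' missing rather than zero.
#'
#' @param matrix_path triplet file.
#' @param bins_path bin BED file.
#' @return Named list of [contact_map()] objects, one per chromosome.
#' @export
read_contact_map <- function(matrix_path, bins_path) {
  bins <- read.table(bins_path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
  if (ncol(bins) < 4) stop("bins file must carry the bin id in column 4")
  names(bins)[1:4] <- c("chrom", "start", "end", "id")
  bins$id <- as.integer(bins$id)
  trip <- read.table(matrix_path, header = FALSE,
                     col.names = c("i", "j", "value"))
  if (any(trip$value < 0)) stop("negative contact value in triplet file")
  known <- bins$id
  miss <- setdiff(unique(c(trip$i, trip$j)), known)
  if (length(miss))
    stop("triplet bin id(s) absent from bins file: ",
         paste(head(miss, 5), collapse = ", "))
  chrom_of <- setNames(bins$chrom, as.character(bins$id))
  cis <- chrom_of[as.character(trip$i)] == chrom_of[as.character(trip$j)]
  if (any(!cis)) {
    warning(sum(!cis), " trans triplet(s) ignored")
    trip <- trip[cis, , drop = FALSE]
  }
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    n <- nrow(b)
    idx <- setNames(seq_len(n), as.character(b$id))
    m <- matrix(0, n, n)
    tt <- trip[chrom_of[as.character(trip$i)] == ch, , drop = FALSE]
    if (nrow(tt)) {
      ii <- idx[as.character(tt$i)]
      jj <- idx[as.character(tt$j)]
      for (k in seq_len(nrow(tt))) {
        m[ii[k], jj[k]] <- m[ii[k], jj[k]] + tt$value[k]
        if (ii[k] != jj[k]) m[jj[k], ii[k]] <- m[jj[k], ii[k]] + tt$value[k]
      }
    }
    bs <- if (n > 1) b$end[1] - b$start[1] else b$end[1] - b$start[1]
    out[[ch]] <- contact_map(ch, bs, m)
  }
  out
}

#' Write a contact map as triplets plus a bin table
#'
#' Inverse of [read_contact_map()]: emits the upper triangle of every
#' non-missing, non-zero cell. Bin ids are absolute across chromosomes.
#'
#' @param maps named list of [contact_map()] objects.
#' @param matrix_path,bins_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_contact_map <- function(maps, matrix_path, bins_path) {
  if (inherits(maps, "contact_map")) maps <- setNames(list(maps), maps$chrom)
  bin_rows <- list(); trip_rows <- list(); offset <- 0L
  for (ch in names(maps)) {
    mp <- maps[[ch]]
    ids <- offset + seq_len(mp$n_bins)
    bin_rows[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(mp$n_bins) - 1) * mp$bin_size,
      end = seq_len(mp$n_bins) * mp$bin_size, id = ids)
    ut <- which(upper.tri(mp$values, diag = TRUE) & !is.na(mp$values) &
                  mp$values != 0, arr.ind = TRUE)
    if (nrow(ut))
      trip_rows[[ch]] <- data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
                                    value = mp$values[ut])
    offset <- offset + mp$n_bins
  }
  bins <- do.call(rbind, bin_rows)
  write.table(bins, bins_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  trips <- if (length(trip_rows)) do.call(rbind, trip_rows)
           else data.frame(i = integer(), j = integer(), value = numeric())
  write.table(trips, matrix_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, bins_path))
}

#' Write scored anchor pairs in longrange track format
#'
#' One line per pair, `chrom\\tstart\\tend\\tchrom2:start2-end2,score`,
#' sorted by (chrom, start) so the file is ready for bgzip/tabix indexing.
#'
#' @param pairs data frame with `chrom1,start1,end1,chrom2,start2,end2,score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_longrange <- function(pairs, path) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "score")
  if (!all(req %in% names(pairs)))
    stop("pairs must have columns ", paste(req, collapse = ", "))
  if (nrow(pairs) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  sc <- suppressWarnings(as.numeric(pairs$score))
  if (any(is.na(sc))) stop("non-numeric score in longrange export")
  ord <- order(pairs$chrom1, pairs$start1, pairs$start2)
  p <- pairs[ord, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s\t%s:%s-%s,%s",
                   p$chrom1,
                   format(p$start1, trim = TRUE, scientific = FALSE),
                   format(p$end1, trim = TRUE, scientific = FALSE),
                   p$chrom2,
                   format(p$start2, trim = TRUE, scientific = FALSE),
                   format(p$end2, trim = TRUE, scientific = FALSE),
                   vapply(sc[ord], format, "", trim = TRUE,
                          scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a longrange track back into an anchor-pair table
#'
#' @param path file written by [write_longrange()].
#' @return Data frame with the same columns [write_longrange()] expects.
#' @export
read_longrange <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) != 4L)
  if (length(bad)) stop("line ", bad[1], ": expected 4 tab-separated fields")
  tgt <- vapply(f, `[`, "", 4L)
  m <- regmatches(tgt, regexec("^([^:]+):([0-9]+)-([0-9]+),(.+)$", tgt))
  bad <- which(vapply(m, length, 1L) != 5L)
  if (length(bad)) stop("line ", bad[1], ": malformed target field")
  data.frame(
    chrom1 = vapply(f, `[`, "", 1L),
    start1 = as.numeric(vapply(f, `[`, "", 2L)),
    end1 = as.numeric(vapply(f, `[`, "", 3L)),
    chrom2 = vapply(m, `[`, "", 2L),
    start2 = as.numeric(vapply(m, `[`, "", 3L)),
    end2 = as.numeric(vapply(m, `[`, "", 4L)),
    score = as.numeric(vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#'
#' @param intervals data frame with `chrom`, `start`, `end`.
#' @param values numeric vector, one per interval.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(intervals, values, path) {
  stopifnot(nrow(intervals) == length(values))
  df <- data.frame(intervals$chrom,
                   format(intervals$start, trim = TRUE, scientific = FALSE),
                   format(intervals$end, trim = TRUE, scientific = FALSE),
                   values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
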