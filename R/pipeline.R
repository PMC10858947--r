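# End-to-end orchestration from a single configuration: simulation,
# background normalization, differential binding, loop calling, differential
# loops, compartments, annotation/bias, with a JSON manifest of outputs.

.default_config <- function() {
  list(
    seed = 1,
    outdir = "pipeline_out",
    hic_sim = list(),          # hic_sim_params() overrides
    frag_sim = list(),         # frag_sim_params() overrides
    compartment_sim = list(chrom_lengths = c(chrC = 2e7), bin_size = 5e4,
                           comp_block_len = 40, loops = NULL),
    normalize = list(window = 500, flank = 5000, alpha = 0.05),
    diffbind = list(window = 500, alpha = 0.05),
    loops = list(p = 1, w = 5, m_min = 3, d_min = 3, d_max = 200,
                 score_min = 2, sigma = 1, alpha_blend = 0.5),
    diffloops = list(mode = "all_combinations", alpha = 0.05),
    summary = list(tss_halfwidth = 5000, hotspot_window = 1e6),
    annotate = list(promoter_halfwidth = 2000)
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config: seed must be a single number")
  if (!is.character(cfg$outdir)) stop("config: outdir must be a path")
  if (is.null(cfg$hic_sim) && is.null(cfg$frag_sim))
    stop("config: at least one simulation block (hic_sim, frag_sim) ",
         "is required")
  for (blk in c("normalize", "diffbind", "loops", "diffloops")) {
    if (!is.list(cfg[[blk]])) stop("config: block '", blk, "' must be a map")
  }
  bad <- setdiff(names(cfg), c(names(.default_config())))
  if (length(bad)) stop("config: unknown key(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and validates
#' before any stage runs.
#'
#' @param config path to a YAML file or a named list.
#' @return Validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.default_config(), user)
  # yaml turns named numeric maps into lists; coerce simulation vectors
  for (blk in c("hic_sim", "compartment_sim")) {
    if (!is.null(cfg[[blk]]$chrom_lengths))
      cfg[[blk]]$chrom_lengths <- unlist(cfg[[blk]]$chrom_lengths)
    if (!is.null(cfg[[blk]]$depth_factors))
      cfg[[blk]]$depth_factors <- lapply(cfg[[blk]]$depth_factors, unlist)
    if (!is.null(cfg[[blk]]$loops) && !is.data.frame(cfg[[blk]]$loops))
      cfg[[blk]]$loops <- as.data.frame(lapply(as.data.frame(
        do.call(rbind, lapply(cfg[[blk]]$loops, as.data.frame))),
        function(x) if (is.factor(x)) as.character(x) else x))
  }
  if (!is.null(cfg$frag_sim$depth_factors))
    cfg$frag_sim$depth_factors <- lapply(cfg$frag_sim$depth_factors, unlist)
  if (!is.null(cfg$frag_sim$peaks) && !is.data.frame(cfg$frag_sim$peaks))
    cfg$frag_sim$peaks <- do.call(rbind, lapply(cfg$frag_sim$peaks,
                                                as.data.frame))
  .validate_config(cfg)
}

.stage_log <- function(log, stage, t0, note) {
  line <- sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, note)
  message(line)
  c(log, line)
}

.register <- function(manifest, stage, path, params = NULL) {
  manifest[[length(manifest) + 1L]] <- list(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)),
    params = params)
  manifest
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes simulate, normalize, differential binding, per-sample loop
#' calling, differential loops with genomic summaries, compartment/saddle
#' analysis and anchor annotation/bias in dependency order, writing every
#' artifact under `outdir` and a JSON manifest with per-file checksums.
#' The global seed is expanded into fixed per-stage substreams so reruns
#' with the same configuration reproduce identical outputs.
#'
#' @param config YAML path or configuration list, see
#'   [load_pipeline_config()].
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  manifest <- list()
  log <- character()
  seed <- as.integer(cfg$seed)
  op <- function(...) file.path(cfg$outdir, paste0(...))

  # --- simulate -----------------------------------------------------------
  hic_par <- do.call(hic_sim_params, c(cfg$hic_sim, list(seed = seed + 11L)))
  if (is.null(hic_par$loops)) {
    hic_par <- do.call(hic_sim_params, c(
      cfg$hic_sim,
      list(loops = data.frame(
        chrom = names(hic_par$chrom_lengths)[1],
        i = c(60, 120, 200, 260, 310),
        j = c(100, 170, 240, 300, 360),
        fc = 5,
        status = c("shared", "cond1_only", "cond2_only", "cond1_only",
                   "cond2_only")),
        seed = seed + 11L)))
  }
  hic <- simulate_hic_experiment(hic_par)
  chrom <- names(hic_par$chrom_lengths)[1]
  frag_par <- do.call(frag_sim_params, c(cfg$frag_sim,
                                         list(seed = seed + 13L)))
  if (is.null(frag_par$peaks)) {
    starts <- seq(5e4, frag_par$genome_len - 5e4, length.out = 100)
    frag_par <- do.call(frag_sim_params, c(
      cfg$frag_sim,
      list(peaks = data.frame(start = starts, end = starts + 800,
                              mult1 = rep(c(1, 1, 0.25, 1), 25),
                              mult2 = rep(c(1, 4, 1, 1), 25)),
           seed = seed + 13L)))
  }
  frg <- simulate_fragment_experiment(frag_par)
  comp_par <- do.call(hic_sim_params,
                      c(cfg$compartment_sim, list(seed = seed + 17L)))
  comp <- simulate_hic_experiment(comp_par)
  comp_chrom <- names(comp_par$chrom_lengths)[1]
  write_contact_map(hic$samples[[1]]$maps, op("hic_", chrom, "_cond1_rep1.matrix"),
                    op("hic_", chrom, "_bins.bed"))
  jsonlite::write_json(hic$truth, op("hic_truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- .register(manifest, "simulate", op("hic_truth.json"))
  manifest <- .register(manifest, "simulate",
                        op("hic_", chrom, "_cond1_rep1.matrix"))
  manifest <- .register(manifest, "simulate", op("hic_", chrom, "_bins.bed"))
  log <- .stage_log(log, "simulate", t0,
                    sprintf("%d Hi-C samples, %d fragment samples",
                            length(hic$samples), length(frg$samples)))

  # --- normalize ----------------------------------------------------------
  nb <- do.call(normalize_background,
                c(list(samples = frg$samples,
                       genome_len = frag_par$genome_len,
                       seed = seed + 19L), cfg$normalize))
  write_intervals(nb$peaks, op("pooled_peaks.bed"), "bed")
  write.table(data.frame(sample = names(nb$sf), sf = nb$sf),
              op("size_factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (s in names(nb$samples))
    write_intervals(nb$samples[[s]]$fragments,
                    op("thinned_", s, ".bed"), "bed")
  manifest <- .register(manifest, "normalize", op("pooled_peaks.bed"),
                        cfg$normalize)
  manifest <- .register(manifest, "normalize", op("size_factors.tsv"))
  log <- .stage_log(log, "normalize", t0,
                    sprintf("%d peaks, sf range %.3f-%.3f", nrow(nb$peaks),
                            min(nb$sf), max(nb$sf)))

  # --- differential binding ----------------------------------------------
  sf1 <- setNames(rep(1, length(nb$samples)),
                  vapply(nb$samples, `[[`, "", "id"))
  db <- do.call(differential_regions,
                c(list(samples = nb$samples, sf = sf1,
                       genome_len = frag_par$genome_len), cfg$diffbind))
  write.table(db, op("differential_regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (dr in c("gained", "lost")) {
    sel <- db[db$direction == dr, c("chrom", "start", "end")]
    write_intervals(sel, op("regions_", dr, ".bed"), "bed")
  }
  manifest <- .register(manifest, "diffbind", op("differential_regions.tsv"),
                        cfg$diffbind)
  log <- .stage_log(log, "diffbind", t0,
                    sprintf("%d regions (%d gained, %d lost)", nrow(db),
                            sum(db$direction == "gained"),
                            sum(db$direction == "lost")))

  # --- loops + differential loops ----------------------------------------
  lp <- cfg$loops
  dl <- differential_loops(hic$samples, chrom,
                           p = lp$p, w = lp$w, m_min = lp$m_min,
                           d_min = lp$d_min, d_max = lp$d_max,
                           score_min = lp$score_min, sigma = lp$sigma,
                           alpha_blend = lp$alpha_blend,
                           mode = cfg$diffloops$mode,
                           alpha = cfg$diffloops$alpha)
  bedpe <- loops_to_bedpe(dl$meta, chrom, dl$bin_size)
  bedpe$name <- dl$meta$direction
  bedpe$score <- dl$meta$Z
  write_intervals(bedpe, op("differential_loops.bedpe"), "bedpe")
  for (dr in c("gained", "lost")) {
    sel <- dl$meta[dl$meta$direction == dr, , drop = FALSE]
    pr <- loops_to_bedpe(sel, chrom, dl$bin_size)
    # browser convention: positive scores for gains, negative for losses
    pr$score <- if (dr == "gained") abs(sel$Z) else -abs(sel$Z)
    write_longrange(pr, op("loops_", dr, ".longrange"))
    manifest <- .register(manifest, "diffloops",
                          op("loops_", dr, ".longrange"))
  }
  manifest <- .register(manifest, "diffloops",
                        op("differential_loops.bedpe"), cfg$loops)
  genes <- .genes_from_tss(hic$truth$tss[[chrom]], chrom,
                           hic_par$chrom_lengths[[chrom]])
  summ <- interaction_change_summary(
    dl$meta, dl$bin_size, genes,
    tss_halfwidth = cfg$summary$tss_halfwidth,
    hotspot_window = cfg$summary$hotspot_window,
    chrom_lengths = hic_par$chrom_lengths)
  write.table(summ$per_chromosome, op("chromosome_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summ$promoters, op("promoter_ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summ$hotspots, op("hotspots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- .register(manifest, "diffloops", op("chromosome_counts.tsv"))
  manifest <- .register(manifest, "diffloops", op("promoter_ranking.tsv"))
  manifest <- .register(manifest, "diffloops", op("hotspots.tsv"))
  log <- .stage_log(log, "diffloops", t0,
                    sprintf("%d union candidates, %d significant",
                            nrow(dl$meta), sum(dl$meta$significant)))

  # --- compartments -------------------------------------------------------
  pooled_by_cond <- lapply(c("cond1", "cond2"), function(cd) {
    ms <- Filter(function(s) s$condition == cd, comp$samples)
    vals <- Reduce(`+`, lapply(ms, function(s)
      ifelse(is.na(s$maps[[comp_chrom]]$values), 0,
             s$maps[[comp_chrom]]$values)))
    contact_map(comp_chrom, comp_par$bin_size, vals)
  })
  names(pooled_by_cond) <- c("cond1", "cond2")
  tss_c <- comp$truth$tss[[comp_chrom]]
  tracks <- lapply(pooled_by_cond, compartment_pc1, tss = tss_c)
  oes <- lapply(pooled_by_cond, oe_normalize)
  saddles <- lapply(names(oes), function(cd)
    saddle_analysis(oes[[cd]], tracks[[cd]]))
  names(saddles) <- names(oes)
  sd_diff <- saddle_diff(saddles$cond2, saddles$cond1)
  sw <- switching_fraction(tracks$cond1, tracks$cond2)
  bins_df <- data.frame(chrom = comp_chrom,
                        start = (seq_along(tracks$cond1$pc1) - 1) *
                          comp_par$bin_size,
                        end = seq_along(tracks$cond1$pc1) *
                          comp_par$bin_size)
  ok <- !is.na(tracks$cond1$pc1)
  write_bedgraph(bins_df[ok, ], tracks$cond1$pc1[ok], op("pc1_cond1.bedgraph"))
  write.table(saddles$cond1$S, op("saddle_cond1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  comp_summary <- data.frame(
    condition = names(saddles),
    AA = vapply(saddles, `[[`, 0, "AA"),
    BB = vapply(saddles, `[[`, 0, "BB"),
    AB = vapply(saddles, `[[`, 0, "AB"),
    switching_fraction = sw)
  write.table(comp_summary, op("compartment_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- .register(manifest, "compartments", op("pc1_cond1.bedgraph"))
  manifest <- .register(manifest, "compartments", op("saddle_cond1.tsv"))
  manifest <- .register(manifest, "compartments",
                        op("compartment_summary.tsv"))
  log <- .stage_log(log, "compartments", t0,
                    sprintf("AA=%.2f BB=%.2f AB=%.2f switching=%.3f",
                            saddles$cond1$AA, saddles$cond1$BB,
                            saddles$cond1$AB, sw))

  # --- annotation & bias --------------------------------------------------
  anchors <- unique(rbind(
    data.frame(chrom = chrom, start = (dl$meta$i - 1) * dl$bin_size,
               end = dl$meta$i * dl$bin_size),
    data.frame(chrom = chrom, start = (dl$meta$j - 1) * dl$bin_size,
               end = dl$meta$j * dl$bin_size)))
  rownames(anchors) <- NULL
  # fragment-space features are re-mapped onto the Hi-C chromosome for the
  # demo: peaks were simulated on a separate coordinate space
  k27 <- nb$peaks; k27$chrom <- chrom
  dbh <- db; dbh$chrom <- chrom
  annos <- annotate_anchors(anchors, genes, k27,
                            differential_sets = list(
                              occupancy = list(regions = dbh,
                                               direction = "any")),
                            promoter_halfwidth =
                              cfg$annotate$promoter_halfwidth)
  a_key <- paste(anchors$chrom, anchors$start)
  dl_bias <- data.frame(
    direction = dl$meta$direction,
    anchor1 = match(paste(chrom, (dl$meta$i - 1) * dl$bin_size), a_key),
    anchor2 = match(paste(chrom, (dl$meta$j - 1) * dl$bin_size), a_key))
  bias <- gain_loss_bias(dl_bias, annos, categories = list(
    promoter = function(a) a$class == "promoter",
    enhancer = function(a) a$class == "enhancer"))
  write_intervals(cbind(annos[, c("chrom", "start", "end")],
                        name = annos$class), op("anchor_annotation.bed"),
                  "bed")
  write.table(bias, op("gain_loss_bias.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- .register(manifest, "annotate", op("anchor_annotation.bed"))
  manifest <- .register(manifest, "annotate", op("gain_loss_bias.tsv"))
  log <- .stage_log(log, "annotate", t0,
                    sprintf("%d anchors annotated", nrow(annos)))

  # --- manifest -----------------------------------------------------------
  writeLines(log, op("pipeline.log"))
  out <- list(seed = seed, config = cfg, artifacts = manifest)
  jsonlite::write_json(out, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  message("pipeline complete: ", length(manifest), " artifacts")
  invisible(out)
}

.genes_from_tss <- function(tss, chrom, chrom_len) {
  if (!length(tss))
    return(gene_annotation(character(), character(), character(),
                           numeric(), numeric()))
  gene_annotation(gene = sprintf("G%04d", seq_along(tss)),
                  chrom = chrom, strand = "+", tss = tss,
                  tts = pmin(chrom_len, tss + 1000))
}
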