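# End-to-end orchestration: simulate (optional) -> filter -> windows -> HMM
# -> RoH -> inbreeding -> sharing -> pedigree, with TSV/BED outputs that are
# byte-identical under identical config and seed.

# small deterministic config fingerprint for output headers (polynomial
# rolling hash mod the Mersenne prime 2^31 - 1)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles and validates every stage parameter. Either `sim` (a
#' [sim_config()]) or the input `paths` must be supplied.
#'
#' @param sim optional [sim_config()]; when given, inputs are simulated.
#' @param paths optional named list: `vcf`, `mask`, `genome`,
#'   `sample_sheet`, `pedigree` (optional), `x_scaffold` (optional).
#' @param width,overlap window geometry in bp (defaults 150,000 / 100,000).
#' @param max_noncallable init-filter cutoff in bp (default 60,000).
#' @param depth_min,depth_max,qual_min,max_missing_frac,maf_min site filters
#'   (defaults 3, 30, 30, 0.20, 0.02).
#' @param min_scaffold_len scaffold-length cutoff in bp; default 45 Mb for
#'   file inputs, 0 (keep all) when simulating.
#' @param hmm_seed,tol,max_iter,var_floor Baum-Welch controls.
#' @param min_windows minimum RoH run length in windows (default 3).
#' @param baseline_cutoff ratio cutoff of the threshold comparator.
#' @param decode `"viterbi"` or `"posterior"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, width = 150000L,
                            overlap = 100000L, max_noncallable = 60000,
                            depth_min = 3, depth_max = 30, qual_min = 30,
                            max_missing_frac = 0.20, maf_min = 0.02,
                            min_scaffold_len = if (is.null(sim)) 45e6 else 0,
                            hmm_seed = 1L, tol = 1e-6, max_iter = 1000L,
                            var_floor = 1e-12, min_windows = 3L,
                            baseline_cutoff = 1e-4,
                            decode = c("viterbi", "posterior")) {
  decode <- match.arg(decode)
  if (is.null(sim) && is.null(paths))
    stop("either sim or paths must be supplied")
  if (overlap >= width || width <= 0) stop("invalid window geometry")
  if (!is.null(paths)) {
    need <- c("vcf", "mask", "genome", "sample_sheet")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0)
      stop("paths missing: ", paste(missing, collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage and (optionally) writes the declared outputs:
#' filtered-variant accounting, per-sample window tracks, fitted HMM
#' parameters (YAML), RoH BED/TSV for both callers, the inbreeding table,
#' the Spearman correlation matrix, group comparisons, the Jaccard matrix
#' and the sharing spectrum, plus pedigree kinship when a pedigree is
#' available. Every output file carries the package version, a config hash
#' and the seed in its header.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress per-stage messages.
#' @return A list bundle with all stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stamp <- function(stage) say("[%s] %+.1fs", stage,
                               as.numeric(difftime(Sys.time(), t0, "secs")))
  hash <- .config_hash(unclass(config))
  hdr <- sprintf("rohmm %s config=%s seed=%d",
                 as.character(utils::packageVersion("rohmm")), hash,
                 as.integer(config$hmm_seed))

  truth <- NULL
  ped <- NULL
  if (!is.null(config$sim)) {
    truth <- if (config$sim$mode == "planted") plant_tracts(config$sim)
             else gene_drop(config$sim$pedigree, config$sim)
    ds <- emit_dataset(truth, config$sim)
    vt_raw <- ds$vt; mask <- ds$mask; index <- ds$index
    sheet <- ds$sample_sheet
    ped <- config$sim$pedigree
    stamp("simulate")
  } else {
    vt_raw <- read_variants(config$paths$vcf)
    mask <- read_bed(config$paths$mask)
    index <- read_genome_index(config$paths$genome,
                               x_scaffold = config$paths$x_scaffold)
    sheet <- utils::read.table(config$paths$sample_sheet, header = TRUE,
                               sep = "\t", colClasses = "character")
    if (!is.null(config$paths$pedigree))
      ped <- read_pedigree(config$paths$pedigree)
    stamp("load")
  }

  keep_scaf <- if (config$min_scaffold_len > 0)
    select_scaffolds(index, config$min_scaffold_len) else index$scaffold
  index <- index[index$scaffold %in% keep_scaf & !index$is_x, , drop = FALSE]
  mask <- mask[mask$scaffold %in% index$scaffold, , drop = FALSE]
  autosome_len <- sum(index$length)

  vt <- filter_variants(vt_raw, depth_min = config$depth_min,
                        depth_max = config$depth_max,
                        qual_min = config$qual_min,
                        max_missing_frac = config$max_missing_frac,
                        maf_min = config$maf_min)
  vt_stats <- attr(vt, "filter_stats")
  say("[filter] %d -> %d sites (%d genotypes depth-masked)",
      vt_stats$n_in, vt_stats$n_out, vt_stats$genotypes_masked)

  samples <- intersect(sheet$sample, vt$samples)
  tracks <- list(); models <- list(); roh1 <- list(); roh2 <- list()
  het <- numeric(0)
  for (i in seq_along(samples)) {
    s <- samples[i]
    sites <- het_sites(vt, mask, s)
    track <- build_window_track(sites, mask, index, width = config$width,
                                overlap = config$overlap, sample = s)
    ratios <- filter_windows_for_init(track, config$max_noncallable)
    init <- kmeans3_init(ratios, seed = config$hmm_seed + i,
                         var_floor = config$var_floor)
    model <- fit_baum_welch(track, init, seed = config$hmm_seed + i,
                            tol = config$tol, max_iter = config$max_iter,
                            var_floor = config$var_floor)
    path <- decode_states(track, model, method = config$decode)
    tracks[[s]] <- track
    models[[s]] <- model
    roh1[[s]] <- call_roh(path, track, min_windows = config$min_windows)
    roh2[[s]] <- baseline_threshold_caller(track, config$baseline_cutoff,
                                           config$min_windows)
    het[s] <- genome_wide_heterozygosity(vt, mask, s)$rate
  }
  stamp("hmm")

  fped <- rep(NA_real_, length(samples))
  kin <- NULL
  if (!is.null(ped)) {
    kin <- kinship_matrix(ped)
    known <- samples %in% ped$id
    fped[known] <- f_ped(ped, samples[known], kinship = kin)
  }
  inb <- inbreeding_table(
    samples, sheet$group[match(samples, sheet$sample)],
    f_roh1 = vapply(roh1, f_roh, 0, autosome_len = autosome_len),
    f_roh2 = vapply(roh2, f_roh, 0, autosome_len = autosome_len),
    f_hom = vapply(samples, function(s) f_hom(vt, s), 0),
    f_ped = fped)
  corr <- correlation_matrix(inb)
  comparisons <- NULL
  grp_sizes <- table(inb$group)
  if (sum(grp_sizes >= 2) >= 2) {
    comparisons <- list(
      f_roh1_wilcoxon = compare_groups(inb$F_ROH1, inb$group, "wilcoxon_bh"),
      het_tukey = compare_groups(het[inb$sample], inb$group, "anova_tukey"))
  }
  jac <- jaccard_matrix(roh1)
  spectrum <- if (length(samples) >= 2) sharing_spectrum(roh1, index) else NULL
  stamp("inbreeding+sharing")

  bundle <- list(config = config, config_hash = hash, index = index,
                 mask = mask, variants = vt, filter_stats = vt_stats,
                 tracks = tracks, models = models, roh_hmm = roh1,
                 roh_baseline = roh2, heterozygosity = het,
                 inbreeding = inb, correlations = corr,
                 comparisons = comparisons, jaccard = jac,
                 spectrum = spectrum, kinship = kin, truth = truth)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, hdr)
  bundle
}

.write_tsv <- function(x, path, hdr) {
  con <- file(path, "w")
  writeLines(paste0("#", hdr), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
}

.write_bundle <- function(b, out_dir, hdr) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(b$roh_hmm)) {
    write_roh(b$roh_hmm[[s]],
              bed_path = file.path(out_dir, sprintf("roh_hmm_%s.bed", s)),
              tsv_path = file.path(out_dir, sprintf("roh_hmm_%s.tsv", s)),
              header = hdr)
    write_roh(b$roh_baseline[[s]],
              bed_path = file.path(out_dir, sprintf("roh_baseline_%s.bed", s)),
              header = hdr)
    write_hmm_model(b$models[[s]],
                    file.path(out_dir, sprintf("hmm_%s.yaml", s)))
    write_window_track(b$tracks[[s]],
                       file.path(out_dir, sprintf("track_%s.tsv", s)),
                       header = hdr)
  }
  .write_tsv(b$inbreeding, file.path(out_dir, "inbreeding.tsv"), hdr)
  .write_tsv(as.data.frame(b$jaccard),
             file.path(out_dir, "jaccard.tsv"), hdr)
  if (!is.null(b$spectrum))
    .write_tsv(b$spectrum$spectrum, file.path(out_dir, "spectrum.tsv"), hdr)
  .write_tsv(as.data.frame(b$correlations$rho),
             file.path(out_dir, "correlations.tsv"), hdr)
  if (!is.null(b$kinship))
    .write_tsv(as.data.frame(b$kinship), file.path(out_dir, "kinship.tsv"), hdr)
  invisible(out_dir)
}

#' Base-pair F1 between called and true intervals
#'
#' Precision, recall and F1 of a called interval set against a truth set,
#' all in base pairs (the natural accuracy summary for planted-tract
#' simulations).
#'
#' @param called,truth interval data frames.
#' @return list with `precision`, `recall`, `f1`, `called_bp`, `truth_bp`,
#'   `shared_bp`.
#' @export
interval_f1 <- function(called, truth) {
  called <- merge_intervals(genomic_intervals(called$scaffold, called$start,
                                              called$end))
  truth <- merge_intervals(genomic_intervals(truth$scaffold, truth$start,
                                             truth$end))
  cb <- intervals_bp(called, merged = TRUE)
  tb <- intervals_bp(truth, merged = TRUE)
  sb <- intervals_bp(intersect_intervals(called, truth))
  precision <- if (cb > 0) sb / cb else NA_real_
  recall <- if (tb > 0) sb / tb else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, called_bp = cb,
       truth_bp = tb, shared_bp = sb)
}
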