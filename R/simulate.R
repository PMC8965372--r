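# Synthetic diploid data with known autozygosity, so every pipeline stage
# can be checked against ground truth.
#
# The analysis consumes only per-site het/hom status, so het sites are
# emulated as a marked Poisson process: a background rate outside autozygous
# tracts and a much lower rate inside them. Autozygosity comes either from
# planted tracts (direct control of the true fraction) or from gene-dropping
# founder haplotypes through a pedigree with recombination (realized IBD).

#' Simulation configuration
#'
#' Defaults emulate a ~7x short-read study of a small bottlenecked
#' population: background heterozygosity 2.4e-4 per bp, residual rate 1e-5
#' inside autozygous tracts, ~25% of the genome masked as non-callable,
#' depth ~ Poisson(7).
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @param x_scaffold identifier of the X-aligned scaffold, or `NULL`.
#' @param n_samples number of samples (planted mode).
#' @param groups group label per sample, recycled.
#' @param background_het_rate het sites per bp outside tracts.
#' @param roh_het_rate het sites per bp inside tracts.
#' @param target_fraction per-sample autozygous genome fraction
#'   (planted mode).
#' @param tract_len_min,tract_len_max uniform tract-length bounds in bp.
#' @param mask_gap_fraction fraction of each scaffold carved out of the
#'   callability mask.
#' @param gap_mean_len mean mask-gap length in bp (exponential lengths).
#' @param depth_mean mean per-genotype read depth (Poisson).
#' @param spike_frac fraction of sites spiked to fail a filter class.
#' @param recomb_rate crossovers per bp per meiosis (gene-drop mode);
#'   default 1e-8 (1 cM/Mb).
#' @param mode `"planted"` or `"gene_drop"`.
#' @param pedigree a [pedigree()] (gene-drop mode).
#' @param seed integer seed governing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scaffold_lengths = c(s1 = 25e6, s2 = 15e6, s3 = 10e6),
                       x_scaffold = NULL, n_samples = 6L,
                       groups = "A", background_het_rate = 2.4e-4,
                       roh_het_rate = 1e-5, target_fraction = 0.25,
                       tract_len_min = 5e5, tract_len_max = 2.5e6,
                       mask_gap_fraction = 0.25, gap_mean_len = 2e4,
                       depth_mean = 7, spike_frac = 0, recomb_rate = 1e-8,
                       mode = c("planted", "gene_drop"), pedigree = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(background_het_rate >= 0, roh_het_rate >= 0,
            roh_het_rate < background_het_rate,
            target_fraction >= 0, target_fraction <= 1,
            mask_gap_fraction >= 0, mask_gap_fraction < 1)
  if (mode == "gene_drop" && is.null(pedigree))
    stop("gene_drop mode requires a pedigree")
  structure(list(scaffold_lengths = scaffold_lengths, x_scaffold = x_scaffold,
                 n_samples = as.integer(n_samples),
                 groups = rep_len(groups, n_samples),
                 background_het_rate = background_het_rate,
                 roh_het_rate = roh_het_rate,
                 target_fraction = target_fraction,
                 tract_len_min = tract_len_min, tract_len_max = tract_len_max,
                 mask_gap_fraction = mask_gap_fraction,
                 gap_mean_len = gap_mean_len, depth_mean = depth_mean,
                 spike_frac = spike_frac, recomb_rate = recomb_rate,
                 mode = mode, pedigree = pedigree, seed = as.integer(seed)),
            class = "sim_config")
}

#' Genome index of a simulation
#'
#' @param config a `sim_config`.
#' @return A [genome_index()] for the simulated scaffolds.
#' @export
sim_genome_index <- function(config) {
  genome_index(names(config$scaffold_lengths), config$scaffold_lengths,
               config$x_scaffold)
}

# place one sample's tracts: uniform placement without overlap until the
# target fraction is reached within half a mean tract length
.plant_one <- function(config) {
  lens <- config$scaffold_lengths
  genome_bp <- sum(lens)
  target <- config$target_fraction * genome_bp
  if (config$target_fraction > 0.95) stop("target fraction > 0.95 infeasible")
  mean_len <- (config$tract_len_min + config$tract_len_max) / 2
  placed <- genomic_intervals()
  total <- 0
  attempts <- 0
  while (total < target - mean_len / 2) {
    attempts <- attempts + 1
    if (attempts > 1e5) stop("tract placement failed; target likely infeasible")
    len <- round(stats::runif(1, config$tract_len_min, config$tract_len_max))
    scaf <- sample(names(lens), 1, prob = lens)
    if (lens[scaf] < len) next
    start <- floor(stats::runif(1, 1, lens[scaf] - len + 1))
    cand <- genomic_intervals(scaf, start, start + len - 1)
    if (intervals_bp(intersect_intervals(placed, cand)) > 0) next
    placed <- rbind(placed, cand)
    total <- total + len
  }
  merge_intervals(placed)
}

#' Plant autozygous tracts
#'
#' Draws per-sample tracts (uniform lengths, uniform non-overlapping
#' placement) until each sample's target genome fraction is reached within
#' half a mean tract length. Deterministic given the config seed.
#'
#' @param config a `sim_config` (planted mode).
#' @return A `truth_set`: list with `tracts` (named list of interval data
#'   frames per sample) and `fraction` (named numeric of true autozygous
#'   fractions).
#' @export
plant_tracts <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  genome_bp <- sum(config$scaffold_lengths)
  tracts <- list()
  for (s in samples) {
    tracts[[s]] <- if (config$target_fraction == 0) genomic_intervals()
                   else .plant_one(config)
  }
  structure(list(tracts = tracts,
                 fraction = vapply(tracts, function(tr)
                   intervals_bp(tr, merged = TRUE) / genome_bp, 0),
                 samples = samples, mode = "planted"),
            class = "truth_set")
}

# --- gene dropping ---------------------------------------------------------

# a haplotype is, per scaffold, a partition of [1, L] into labelled segments
.founder_haplotype <- function(lens, label) {
  lapply(lens, function(L) data.frame(start = 1, end = L, lab = label))
}

.restrict_segments <- function(segs, s, e) {
  keep <- segs$end >= s & segs$start <= e
  out <- segs[keep, , drop = FALSE]
  out$start <- pmax(out$start, s)
  out$end <- pmin(out$end, e)
  out
}

# one meiosis: recombine the parent's two haplotypes into a gamete
.gamete <- function(parent_haps, lens, rate) {
  out <- list()
  for (scaf in names(lens)) {
    L <- lens[[scaf]]
    n_x <- stats::rpois(1, rate * L)
    bp <- sort(stats::runif(n_x, 1, L))
    bounds <- c(1, floor(bp) + 1, L + 1)     # segment starts, then sentinel
    hap <- sample(1:2, 1)
    pieces <- list()
    for (j in seq_len(length(bounds) - 1)) {
      s <- bounds[j]; e <- bounds[j + 1] - 1
      if (e < s) { hap <- 3 - hap; next }
      pieces[[length(pieces) + 1]] <-
        .restrict_segments(parent_haps[[hap]][[scaf]], s, e)
      hap <- 3 - hap
    }
    segs <- do.call(rbind, pieces)
    # merge adjacent same-label segments
    if (nrow(segs) > 1) {
      run <- cumsum(c(TRUE, segs$lab[-1] != segs$lab[-nrow(segs)] |
                            segs$start[-1] != segs$end[-nrow(segs)] + 1))
      segs <- data.frame(start = tapply(segs$start, run, min),
                         end = tapply(segs$end, run, max),
                         lab = segs$lab[!duplicated(run)])
    }
    out[[scaf]] <- segs
  }
  out
}

# intervals where the two haplotypes carry the same founder label
.autozygous_intervals <- function(h1, h2, lens) {
  out <- genomic_intervals()
  for (scaf in names(lens)) {
    a <- h1[[scaf]]; b <- h2[[scaf]]
    cuts <- sort(unique(c(a$start, b$start)))
    ends <- c(cuts[-1] - 1, lens[[scaf]])
    la <- a$lab[findInterval(cuts, a$start)]
    lb <- b$lab[findInterval(cuts, b$start)]
    same <- la == lb
    if (any(same))
      out <- rbind(out, genomic_intervals(rep(scaf, sum(same)),
                                          cuts[same], ends[same]))
  }
  merge_intervals(out)
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Each founder carries two globally unique haplotype labels. Every
#' transmission draws a Poisson number of crossovers (`recomb_rate` x
#' scaffold length) at uniform positions and copies the recombined parental
#' mosaic. An interval is autozygous when both inherited labels coincide;
#' realized IBD is the autozygous fraction of the genome.
#'
#' @param ped a [pedigree()] (selfing is rejected at construction).
#' @param config a `sim_config`.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return A `truth_set` with `tracts`, `fraction` (realized IBD per
#'   individual) and `samples` in pedigree order.
#' @export
gene_drop <- function(ped, config, seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- as.list(config$scaffold_lengths)
  genome_bp <- sum(config$scaffold_lengths)
  haps <- list()
  label <- 0L
  tracts <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (ped$is_founder[i]) {
      haps[[id]] <- list(.founder_haplotype(lens, label + 1L),
                         .founder_haplotype(lens, label + 2L))
      label <- label + 2L
    } else {
      gam <- list(NULL, NULL)
      for (p in 1:2) {
        par <- c(ped$sire[i], ped$dam[i])[p]
        gam[[p]] <- if (is.na(par)) {
          label <- label + 1L           # unknown parent: unique novel gamete
          .founder_haplotype(lens, label)
        } else .gamete(haps[[par]], lens, config$recomb_rate)
      }
      haps[[id]] <- gam
    }
    tracts[[id]] <- .autozygous_intervals(haps[[id]][[1]], haps[[id]][[2]], lens)
  }
  structure(list(tracts = tracts,
                 fraction = vapply(tracts, function(tr)
                   intervals_bp(tr, merged = TRUE) / genome_bp, 0),
                 samples = ped$id, mode = "gene_drop"),
            class = "truth_set")
}

#' Realized IBD over gene-drop replicates
#'
#' @param ped a [pedigree()].
#' @param config a `sim_config`.
#' @param n_replicates number of independent gene drops.
#' @return numeric matrix, replicates x individuals.
#' @export
gene_drop_replicates <- function(ped, config, n_replicates) {
  out <- matrix(0, n_replicates, nrow(ped), dimnames = list(NULL, ped$id))
  for (r in seq_len(n_replicates)) {
    out[r, ] <- gene_drop(ped, config, seed = config$seed + r - 1L)$fraction
  }
  out
}

# carve random gaps until the target fraction of a scaffold is non-callable
.carve_gaps <- function(L, gap_fraction, gap_mean) {
  target <- gap_fraction * L
  gaps <- genomic_intervals()
  total <- 0
  while (total < target) {
    len <- max(1000, round(stats::rexp(1, 1 / gap_mean)))
    start <- floor(stats::runif(1, 1, max(1, L - len)))
    gaps <- merge_intervals(rbind(gaps, genomic_intervals("x", start,
                                                          min(start + len - 1, L))))
    total <- intervals_bp(gaps, merged = TRUE)
  }
  gaps
}

#' Emit the synthetic dataset
#'
#' Realizes a `truth_set` as analysis inputs: a callability mask with random
#' gaps, per-sample het sites from the two-rate Poisson process (restricted
#' to the mask), a multi-sample variant table whose genotypes are consistent
#' with each sample's het/hom status (non-focal samples are filled in as
#' homozygotes under allele frequencies drawn from a Beta(0.5, 0.5)
#' spectrum), per-genotype depths ~ Poisson(`depth_mean`), and passing
#' quality except for an optional spiked fraction of sites constructed to
#' fail one filter class each. Deterministic given the config seed.
#'
#' @param truth a `truth_set`.
#' @param config the `sim_config` used to build it.
#' @param out_dir optional directory; when given, writes `variants.vcf`,
#'   `mask.bed`, `truth_<sample>.bed`, `sample_sheet.tsv`, `genome.tsv` and
#'   (gene-drop mode) `pedigree.tsv`.
#' @return list with `vt` (a [variant_table()]), `mask`, `index`,
#'   `sample_sheet`, `truth`, `spiked` (data frame of spiked site rows and
#'   their filter class), and `config`.
#' @export
emit_dataset <- function(truth, config, out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 104729L)   # independent stream from tract placement
  lens <- config$scaffold_lengths
  samples <- truth$samples
  index <- sim_genome_index(config)

  mask <- genomic_intervals()
  for (scaf in names(lens)) {
    full <- genomic_intervals(scaf, 1, lens[[scaf]])
    if (config$mask_gap_fraction > 0) {
      gaps <- .carve_gaps(lens[[scaf]], config$mask_gap_fraction,
                          config$gap_mean_len)
      gaps$scaffold <- scaf
      mask <- rbind(mask, setdiff_intervals(full, gaps))
    } else mask <- rbind(mask, full)
  }
  mask <- merge_intervals(mask)

  # per-sample het positions: two-rate Poisson process on the mask
  het_pos <- list()
  for (s in samples) {
    tr <- truth$tracts[[s]]
    inside <- intersect_intervals(mask, tr)
    outside <- setdiff_intervals(mask, tr)
    draw <- function(iv, rate) {
      if (nrow(iv) == 0 || rate <= 0) return(iv[0, c("scaffold", "start")])
      n <- stats::rpois(nrow(iv), rate * (iv$end - iv$start + 1))
      keep <- n > 0
      if (!any(keep))
        return(data.frame(scaffold = character(0), pos = numeric(0),
                          stringsAsFactors = FALSE))
      pos <- mapply(function(st, en, k)
        st - 1 + sample.int(en - st + 1, min(k, en - st + 1)),
        iv$start[keep], iv$end[keep], n[keep], SIMPLIFY = FALSE)
      data.frame(scaffold = rep(iv$scaffold[keep], lengths(pos)),
                 pos = unlist(pos), stringsAsFactors = FALSE)
    }
    hp <- rbind(stats::setNames(draw(inside, config$roh_het_rate),
                                c("scaffold", "pos")),
                stats::setNames(draw(outside, config$background_het_rate),
                                c("scaffold", "pos")))
    het_pos[[s]] <- hp[order(hp$scaffold, hp$pos), , drop = FALSE]
  }

  # union of sites across samples
  all_sites <- unique(do.call(rbind, het_pos))
  all_sites <- all_sites[order(all_sites$scaffold, all_sites$pos), ,
                         drop = FALSE]
  n_sites <- nrow(all_sites)
  n_s <- length(samples)
  gt <- matrix(0L, n_sites, n_s, dimnames = list(NULL, samples))
  key <- paste(all_sites$scaffold, all_sites$pos)
  for (s in samples) {
    gt[match(paste(het_pos[[s]]$scaffold, het_pos[[s]]$pos), key), s] <- 1L
  }
  # non-focal fill-in: hom-alt with probability p^2, p ~ Beta(0.5, 0.5)
  p <- stats::rbeta(n_sites, 0.5, 0.5)
  homalt <- matrix(stats::runif(n_sites * n_s), n_sites, n_s) < p^2
  gt[homalt & gt == 0L] <- 2L

  dp <- matrix(stats::rpois(n_sites * n_s, config$depth_mean), n_sites, n_s,
               dimnames = list(NULL, samples))
  qual <- round(stats::runif(n_sites, 40, 200), 2)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  spiked <- data.frame(row = integer(), class = character(),
                       stringsAsFactors = FALSE)
  if (config$spike_frac > 0 && n_sites > 0) {
    classes <- c("qual", "depth", "missing")
    n_spike <- max(length(classes), round(config$spike_frac * n_sites))
    rows <- sample.int(n_sites, min(n_spike, n_sites))
    cls <- rep_len(classes, length(rows))
    for (j in seq_along(rows)) {
      i <- rows[j]
      if (cls[j] == "qual") {
        qual[i] <- round(stats::runif(1, 0, 29), 2)
      } else if (cls[j] == "depth") {
        dp[i, ] <- 1L                 # every genotype masked: site dropped
      } else {
        gt[i, ] <- NA_integer_
      }
    }
    spiked <- data.frame(row = rows, class = cls, stringsAsFactors = FALSE)
  }

  site <- data.frame(scaffold = all_sites$scaffold, pos = all_sites$pos,
                     ref = ref, alt = alt, qual = qual,
                     stringsAsFactors = FALSE)
  vt <- variant_table(site, gt, dp)
  sheet <- data.frame(sample = samples,
                      group = rep_len(config$groups, n_s),
                      stringsAsFactors = FALSE)
  out <- list(vt = vt, mask = mask, index = index, sample_sheet = sheet,
              truth = truth, spiked = spiked, config = config)
  if (!is.null(out_dir)) .write_dataset(out, out_dir)
  out
}

.write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed=%d", ds$config$seed)
  write_vcf(ds$vt, file.path(out_dir, "variants.vcf"),
            contigs = ds$config$scaffold_lengths, extra_header = hdr)
  write_bed(ds$mask, file.path(out_dir, "mask.bed"), header = hdr)
  for (s in names(ds$truth$tracts))
    write_bed(ds$truth$tracts[[s]],
              file.path(out_dir, sprintf("truth_%s.bed", s)), header = hdr)
  utils::write.table(ds$sample_sheet, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$index[, c("scaffold", "length")],
                     file.path(out_dir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(ds$config$pedigree))
    utils::write.table(ds$config$pedigree[, c("id", "sire", "dam", "sex",
                                              "cohort")],
                       file.path(out_dir, "pedigree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "0")
  invisible(out_dir)
}

#' Write a variant table as VCF v4.2
#'
#' @param vt a `variant_table`.
#' @param path output path.
#' @param contigs optional named lengths for `##contig` header lines.
#' @param extra_header optional extra header comment (goes into a
#'   `##rohmm=` line).
#' @export
write_vcf <- function(vt, path, contigs = NULL, extra_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(extra_header)) writeLines(paste0("##rohmm=", extra_header), con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vt$samples), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vt$gt + 1L], nrow = nrow(vt$gt))
  gt_str[is.na(vt$gt)] <- "./."
  dp_str <- matrix(as.character(vt$dp), nrow = nrow(vt$dp))
  dp_str[is.na(vt$dp)] <- "."
  body <- apply(matrix(paste0(gt_str, ":", dp_str), nrow = nrow(vt$gt)), 1,
                paste, collapse = "\t")
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s",
                     vt$site$scaffold, as.integer(vt$site$pos), vt$site$ref,
                     vt$site$alt, format(vt$site$qual, trim = TRUE), body),
             con)
  invisible(path)
}

#' Simulate a Hardy-Weinberg genotype panel
#'
#' Independent sites with allele frequencies drawn uniformly and genotypes
#' in exact Hardy-Weinberg proportions; used to calibrate the F_HOM
#' estimator (its mean is ~0 under HWE).
#'
#' @param n_samples,n_sites panel dimensions.
#' @param seed integer seed.
#' @param p_range allele-frequency range (default 0.05-0.95).
#' @return A `variant_table`.
#' @export
sim_hwe_genotypes <- function(n_samples, n_sites, seed = 1L,
                              p_range = c(0.05, 0.95)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- stats::runif(n_sites, p_range[1], p_range[2])
  gt <- matrix(stats::rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
               n_sites, n_samples,
               dimnames = list(NULL, sprintf("S%02d", seq_len(n_samples))))
  site <- data.frame(scaffold = "s1", pos = seq_len(n_sites), ref = "A",
                     alt = "G", qual = 60, stringsAsFactors = FALSE)
  variant_table(site, gt, matrix(7, n_sites, n_samples,
                                 dimnames = dimnames(gt)))
}
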