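# Synthetic-data generators. Every generator seeds the RNG from the
# config (with a fixed per-generator offset so stages are decoupled), so
# an identical sim_config reproduces the whole study bit-for-bit.

seed_for <- function(config, offset) {
  (config$seed + offset) %% .Machine$integer.max
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a bisulfite amplicon reference with a chosen CpG count
#'
#' Builds a deterministic CpG-free backbone and plants `n_cpg` evenly
#' spaced CG dinucleotides, emulating a CMV-promoter-like or LTR-like
#' amplicon for the clone pipeline.
#'
#' @param n_cpg Number of CpGs to plant.
#' @param length_bp Amplicon length.
#' @param id Locus id.
#' @return A [bis_locus()].
#' @export
simulate_locus_reference <- function(n_cpg = 17, length_bp = 400,
                                     id = "CMV-like") {
  if (length_bp < 4 * n_cpg + 10) abort("amplicon too short for CpG count")
  unit <- c("A", "T", "T", "G", "A", "C", "A", "T")  # no CG when tiled
  backbone <- rep_len(unit, length_bp)
  at <- round(seq(5, length_bp - 5, length.out = n_cpg))
  for (p in at) {
    backbone[p] <- "C"
    backbone[p + 1] <- "G"
    if (p + 2 <= length_bp && backbone[p + 2] == "G") backbone[p + 2] <- "A"
    if (backbone[p - 1] == "C") backbone[p - 1] <- "T"
  }
  bis_locus(id, paste(backbone, collapse = ""))
}

#' Simulate bisulfite Sanger clones from a reference
#'
#' Each clone is the bisulfite image of the (top-strand) reference:
#' non-CpG cytosines convert C->T with probability
#' `conversion_efficiency`; the C of CpG number *i* is retained with
#' probability `per_cpg_prob[i]` (otherwise read as T); every base is then
#' substituted by a uniformly random different base with probability
#' `sequencing_error_rate`. Clone order is deterministic given the seed.
#'
#' @param reference A [bis_locus()] or a DNA string with >= 1 CpG.
#' @param per_cpg_prob Methylation probability per CpG, one value per CpG
#'   (a scalar is recycled).
#' @param n_clones Number of clones to draw.
#' @param config A [sim_config()]; uses `seed`, `conversion_efficiency`,
#'   `sequencing_error_rate`.
#' @return A list of class `bisulfite_sim`: `locus`, `sequences` (named
#'   character vector of clone sequences), `per_cpg_prob`.
#' @examples
#' loc <- simulate_locus_reference(n_cpg = 4, length_bp = 60)
#' sim <- simulate_bisulfite_clones(loc, 1, n_clones = 3,
#'   config = sim_config(seed = 7, sequencing_error_rate = 0,
#'                       conversion_efficiency = 1))
#' substr(sim$sequences[1], 1, 10)
#' @export
simulate_bisulfite_clones <- function(reference, per_cpg_prob, n_clones,
                                      config = sim_config()) {
  locus <- if (inherits(reference, "bis_locus")) reference else {
    bis_locus("locus", reference)
  }
  n_cpg <- length(locus$cpg_pos)
  if (length(per_cpg_prob) == 1) {
    per_cpg_prob <- rep(per_cpg_prob, n_cpg)
  }
  if (length(per_cpg_prob) != n_cpg) {
    abort(paste0("per_cpg_prob has length ", length(per_cpg_prob),
                 " but the locus has ", n_cpg, " CpGs"))
  }
  if (any(per_cpg_prob < 0 | per_cpg_prob > 1)) {
    abort("per_cpg_prob must lie in [0, 1]")
  }
  ref <- strsplit(locus$reference, "")[[1]]
  cpg_i <- locus$cpg_pos + 1L
  non_cpg_c <- setdiff(which(ref == "C"), cpg_i)
  bases <- c("A", "C", "G", "T")
  set.seed(seed_for(config, 11L))
  seqs <- vapply(seq_len(n_clones), function(k) {
    obs <- ref
    conv <- runif(length(non_cpg_c)) < config$conversion_efficiency
    obs[non_cpg_c[conv]] <- "T"
    meth <- runif(n_cpg) < per_cpg_prob
    obs[cpg_i[!meth]] <- "T"
    err_at <- which(runif(length(obs)) < config$sequencing_error_rate)
    for (i in err_at) obs[i] <- sample(setdiff(bases, obs[i]), 1)
    paste(obs, collapse = "")
  }, "")
  names(seqs) <- sprintf("%s_clone%03d", locus$id, seq_len(n_clones))
  structure(list(locus = locus, sequences = seqs,
                 per_cpg_prob = per_cpg_prob),
            class = "bisulfite_sim")
}

#' Call and summarise a simulated clone set
#'
#' Convenience pipeline: [call_clone()] on every simulated sequence,
#' [qc_filter()] with the given thresholds, then [locus_level()].
#'
#' @param sim A `bisulfite_sim` from [simulate_bisulfite_clones()].
#' @param min_conversion,max_mismatch QC thresholds, see [qc_filter()].
#' @return A [locus_level()] result.
#' @export
quantify_clone_sim <- function(sim, min_conversion = 0.95,
                               max_mismatch = 0.10) {
  pats <- purrr::imap(sim$sequences, function(s, id) {
    call_clone(sim$locus, s, clone_id = id)
  })
  cs <- clone_set(sim$locus, unname(pats))
  cs <- qc_filter(cs, min_conversion, max_mismatch)
  locus_level(cs)
}

#' Simulate a toy genome with p65 peaks and genes
#'
#' One synthetic chromosome carrying `n_peaks` p65-peak intervals, each
#' embedding the kappaB consensus GGGACTTTCC, with planted CpG landscapes
#' of alternating density (low: 0-5 CpGs within +-250 bp of the motif;
#' high: 10-25) and alternating initial methylation class (unmethylated
#' < 20%, methylated >= 50%). Gene TSSs are planted so peak-TSS distances
#' span the < 10 kb, 10-100 kb and > 100 kb strata. The backbone sequence
#' is CpG-free, so every CpG is a planted one and can be recounted from
#' the emitted sequence.
#'
#' @param config A [sim_config()]; needs `n_peaks >= 2`, `n_genes >= 2`.
#' @return A list of class `toy_genome`: `chrom`, `length`, `sequence`,
#'   `peaks` (tibble: peak_id, chrom, start, end, motif_start,
#'   motif_strand, cpg_class, meth_class), `cpgs` (tibble: peak_id, pos,
#'   p0), `genes` (tibble: gene_id, tss, strand).
#' @export
simulate_toy_genome <- function(config = sim_config()) {
  if (config$n_peaks < 2 || config$n_genes < 2) {
    abort("need n_peaks >= 2 and n_genes >= 2")
  }
  L <- config$genome_length
  peak_w <- 400L
  # peaks occupy the first ~60% of the chromosome; the remainder hosts
  # the mid- and far-stratum TSSs so nearest-peak distances are
  # controlled
  spacing <- floor(0.6 * L / (config$n_peaks + 1))
  if (spacing < peak_w + 600 || L < 320000) {
    abort(paste0("genome too short (", L, " bp) to place ",
                 config$n_peaks, " peaks and stratified TSSs"))
  }
  set.seed(seed_for(config, 23L))
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, L, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3))
  # strip accidental CG so planted CpGs are the only ones
  cg <- find_cpgs(paste(seq_chars, collapse = ""))
  while (length(cg) > 0) {
    seq_chars[cg + 2L] <- "A"
    cg <- find_cpgs(paste(seq_chars, collapse = ""))
  }
  motif <- strsplit(KB_CONSENSUS, "")[[1]]
  mw <- length(motif)
  peaks <- vector("list", config$n_peaks)
  cpgs <- vector("list", config$n_peaks)
  for (k in seq_len(config$n_peaks)) {
    start <- k * spacing
    end <- start + peak_w
    motif_start <- start + (peak_w - mw) %/% 2
    seq_chars[(motif_start + 1):(motif_start + mw)] <- motif
    center <- motif_start + mw %/% 2
    cpg_class <- if (k %% 2 == 1) "high" else "low"
    meth_class <- if (((k - 1) %/% 2) %% 2 == 0) "methylated" else
      "unmethylated"
    n_cpg <- if (cpg_class == "high") sample(10:25, 1) else sample(0:5, 1)
    cand <- setdiff(seq(center - 250L, center + 250L, by = 3L),
                    seq(motif_start - 2L, motif_start + mw + 1L))
    pos <- sort(sample(cand, n_cpg))
    for (p in pos) {
      seq_chars[p + 1] <- "C"
      seq_chars[p + 2] <- "G"
      if (p + 3 <= L && seq_chars[p + 3] == "G") seq_chars[p + 3] <- "A"
    }
    p0 <- if (meth_class == "methylated") runif(n_cpg, 0.70, 0.95) else
      runif(n_cpg, 0.02, 0.10)
    peaks[[k]] <- tibble(peak_id = sprintf("peak%03d", k), chrom = "chrS",
                         start = start, end = end,
                         motif_start = motif_start, motif_strand = "+",
                         cpg_class = cpg_class, meth_class = meth_class)
    cpgs[[k]] <- if (n_cpg > 0) {
      tibble(peak_id = sprintf("peak%03d", k), pos = pos, p0 = p0)
    } else NULL
  }
  peaks <- bind_rows(peaks)
  cpgs <- bind_rows(cpgs)
  # place TSSs cycling through distance strata: near genes flank an
  # anchor peak; mid (10-100 kb) and far (> 100 kb) genes sit past the
  # last peak, where the nearest-peak distance equals their offset
  centers <- peaks$motif_start + mw %/% 2
  last_center <- max(centers)
  j <- seq_len(config$n_genes)
  stratum <- (j - 1) %% 3          # 0 near, 1 mid, 2 far
  anchors <- centers[((j - 1) %/% 3) %% config$n_peaks + 1]
  tss <- integer(config$n_genes)
  sign_near <- sample(c(-1L, 1L), config$n_genes, replace = TRUE)
  tss[stratum == 0] <- anchors[stratum == 0] +
    sign_near[stratum == 0] *
    (500L + sample(0:3500, sum(stratum == 0), replace = TRUE))
  tss[stratum == 1] <- last_center + 12000L +
    (which(stratum == 1) %% 30L) * 2500L
  tss[stratum == 2] <- last_center + 105000L +
    (which(stratum == 2) %% 40L) * 250L
  genes <- tibble(
    gene_id = sprintf("gene%03d", j),
    tss = pmin(L - 1L, pmax(0L, as.integer(tss))),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
  structure(list(chrom = "chrS", length = L,
                 sequence = paste(seq_chars, collapse = ""),
                 peaks = peaks, cpgs = cpgs, genes = genes),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome>", x$chrom, x$length, "bp,", nrow(x$peaks), "peaks,",
      nrow(x$cpgs), "CpGs,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Simulate methylation dynamics across sustained TNF-alpha treatment
#'
#' Per-CpG methylation before (t0) and after 12 days of stimulation
#' (t12). The underlying t12 level is
#' `t0 - g * delta * exp(-|pos - motif_center| / lambda)` clipped to
#' \[0, 1\], where `g` is the genotype multiplier (WT 1, reduced for TET
#' knockouts, ~0 for RELA KO and the TET triple KO): demethylation is
#' p65-nucleated and TET-executed, strongest at the kappaB motif and
#' decaying with distance. Counts are then drawn binomially at the
#' configured coverage.
#'
#' @param genome A [simulate_toy_genome()] result.
#' @param config A [sim_config()].
#' @return List with tibbles `t0` and `t12` (columns `chrom`, `pos`,
#'   `level`, `count_meth`, `count_unmeth`, plus the noise-free
#'   `true_level`).
#' @export
simulate_methylation_dynamics <- function(genome, config = sim_config()) {
  stopifnot(inherits(genome, "toy_genome"))
  g <- genotype_multiplier(config$genotype)
  mw <- nchar(KB_CONSENSUS)
  centers <- setNames(genome$peaks$motif_start + mw %/% 2,
                      genome$peaks$peak_id)
  cp <- genome$cpgs
  d <- abs(cp$pos - centers[cp$peak_id])
  p0 <- cp$p0
  p12 <- clip01(p0 - g * config$demethylation_scale *
                  exp(-d / config$decay_length))
  set.seed(seed_for(config, 37L))
  draw <- function(p) {
    m <- rbinom(length(p), config$coverage, p)
    tibble(chrom = genome$chrom, pos = cp$pos,
           level = m / config$coverage,
           count_meth = m,
           count_unmeth = config$coverage - m,
           true_level = p)
  }
  list(t0 = draw(p0), t12 = draw(p12))
}

#' Simulate p65 occupancy coupled to total methylation
#'
#' Summit signal per peak is `amplitude * exp(-beta * M) * 2^eps`, where
#' `M` is the peak's total methylation (sum of per-CpG levels within
#' +-250 bp of the motif, see [peak_methylation()]) and `eps` is Gaussian
#' on the log2 scale with sd `noise_sd`. The lognormal noise keeps the
#' signal strictly positive and its error proportional to the mean, so
#' the occupancy-methylation ordering is preserved at every signal
#' magnitude. A Gaussian-shaped binned track around each motif is also
#' emitted for profile aggregation.
#'
#' @param genome A [simulate_toy_genome()] result.
#' @param meth Per-CpG methylation tibble (e.g. `$t0` of
#'   [simulate_methylation_dynamics()]).
#' @param config A [sim_config()].
#' @param amplitude Maximal expected summit signal at M = 0.
#' @param flank,min_cov Passed to the total-methylation computation.
#' @return List: `peaks` (tibble `peak_id`, `M`, `summit_signal`),
#'   `track` (tibble `sample`, `chrom`, `start`, `end`, `value`).
#' @export
simulate_occupancy <- function(genome, meth, config = sim_config(),
                               amplitude = 100, flank = 250, min_cov = 5) {
  stopifnot(inherits(genome, "toy_genome"))
  mw <- nchar(KB_CONSENSUS)
  set.seed(seed_for(config, 53L))
  pk <- genome$peaks
  res <- purrr::map(seq_len(nrow(pk)), function(i) {
    center <- pk$motif_start[i] + mw %/% 2
    cp <- genome$cpgs[genome$cpgs$peak_id == pk$peak_id[i], ]
    cp <- cp[abs(cp$pos - center) <= flank, ]
    M <- if (nrow(cp) == 0) 0 else {
      pm <- peak_methylation(meth, cp$pos, min_cov = min_cov)
      if (is.na(pm$M)) 0 else pm$M
    }
    eps <- rnorm(1, 0, config$noise_sd)
    summit <- amplitude * exp(-config$occupancy_decay * M) * 2^eps
    bins <- seq(center - 500L, center + 500L - 50L, by = 50L)
    tibble(peak_id = pk$peak_id[i], M = M, summit_signal = summit,
           bin_start = bins,
           bin_value = summit * exp(-((bins + 25 - center)^2) /
                                      (2 * 150^2)))
  }) |> bind_rows()
  peaks <- dplyr::distinct(res, .data$peak_id, .data$M,
                           .data$summit_signal)
  track <- tibble(sample = "occupancy", chrom = genome$chrom,
                  start = res$bin_start, end = res$bin_start + 50L,
                  value = res$bin_value)
  list(peaks = peaks, track = track)
}

#' Default plan of planted genes for the five-condition memory design
#'
#' Names are `*_like` stand-ins for the study's genes. Memory genes
#' (CALCB/PTGES/CCL2/TNF/LHX2-like and the EGFP-like reporter) are
#' planted to satisfy all classifier criteria with margin; the IL32-like
#' control is TNF-alpha-responsive with an elevated recovery baseline but
#' no stronger second induction; two responsive-only controls and a
#' lognormal-spaced background complete the table.
#'
#' @param n_background Number of non-responsive background genes.
#' @return Tibble: `gene`, `role`, and planted mean FPKM per condition
#'   (`naive_0h`, `first_12h`, `sustained_12d`, `recovery_10d`,
#'   `second_12h`).
#' @export
default_memory_plan <- function(n_background = 500) {
  planted <- tibble::tribble(
    ~gene,         ~role,         ~naive_0h, ~first_12h, ~sustained_12d,
      ~recovery_10d, ~second_12h,
    "CALCB_like",  "memory",      2,   100, 699, 20, 346,
    "PTGES_like",  "memory",      3,    60, 200, 30, 150,
    "EGFP_like",   "memory",      1,    50, 300, 40, 150,
    "CCL2_like",   "memory",      10,  120, 150, 12, 200,
    "TNF_like",    "memory",      8,   110,  90,  9, 180,
    "LHX2_like",   "memory",      0.5,  20,  40,  2,  35,
    "IL32_like",   "il32_like",   5,    80, 120, 25,  80,
    "NFKBIA_like", "responsive",  20,  200, 180, 22, 200,
    "NFKB2_like",  "responsive",  15,   90,  80, 16,  92)
  if (n_background > 0) {
    base <- exp(seq(log(0.5), log(200), length.out = n_background))
    bg <- tibble(gene = sprintf("bg%04d", seq_len(n_background)),
                 role = "background",
                 naive_0h = base, first_12h = base, sustained_12d = base,
                 recovery_10d = base, second_12h = base)
    planted <- bind_rows(planted, bg)
  }
  planted
}

MEMORY_CONDITIONS <- c("naive_0h", "first_12h", "sustained_12d",
                       "recovery_10d", "second_12h")

#' Simulate a five-condition FPKM expression table
#'
#' Replicate FPKMs are lognormal around the planted per-condition means:
#' `fpkm = mean * 2^N(0, noise_sd)`. With `noise_sd = 0` replicate values
#' equal the planted means exactly.
#'
#' @param config A [sim_config()]; uses `seed`, `noise_sd`,
#'   `n_replicates`.
#' @param plan A plan tibble as from [default_memory_plan()].
#' @return Long tibble: `gene`, `condition`, `replicate`, `fpkm`, with the
#'   plan attached as attribute `"plan"`.
#' @export
simulate_expression <- function(config = sim_config(),
                                plan = default_memory_plan()) {
  need <- c("gene", "role", MEMORY_CONDITIONS)
  if (!all(need %in% names(plan))) {
    abort(paste0("plan must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(plan$gene)) abort("plan lists a gene twice")
  bad_role <- setdiff(unique(plan$role),
                      c("memory", "responsive", "il32_like", "background"))
  if (length(bad_role) > 0) {
    abort(paste0("plan references unknown role: ", bad_role[1]))
  }
  long <- tidyr::pivot_longer(plan, cols = dplyr::all_of(MEMORY_CONDITIONS),
                              names_to = "condition", values_to = "mean")
  long <- tidyr::crossing(long, replicate = seq_len(config$n_replicates))
  set.seed(seed_for(config, 71L))
  long$fpkm <- long$mean * 2^rnorm(nrow(long), 0, config$noise_sd)
  out <- select(long, "gene", "condition", "replicate", "fpkm")
  out <- arrange(out, .data$gene, .data$condition, .data$replicate)
  attr(out, "plan") <- plan
  out
}

#' Simulate a complete study and optionally write it to disk
#'
#' Bundles the toy genome, t0/t12 methylation, occupancy and expression
#' for one config.
#'
#' @param config A [sim_config()].
#' @return List of class `memory_sim`: `config`, `genome`, `meth`
#'   (`$t0`, `$t12`), `occupancy`, `expression`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_toy_genome(config)
  meth <- simulate_methylation_dynamics(genome, config)
  occ <- simulate_occupancy(genome, meth$t0, config)
  expr <- simulate_expression(config)
  structure(list(config = config, genome = genome, meth = meth,
                 occupancy = occ, expression = expr),
            class = "memory_sim")
}

#' Write all simulated fixtures in their standard file formats
#'
#' Emits genome FASTA, peaks BED (0-based half-open), TSS TSV, t0/t12
#' methylation in Bismark coverage dialect, the expression TSV
#' (`gene<TAB>condition:replicate...`) and the occupancy bedGraph.
#'
#' @param sim A [simulate_study()] result.
#' @param outdir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "memory_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    peaks = file.path(outdir, "peaks.bed"),
    tss = file.path(outdir, "tss.tsv"),
    meth_t0 = file.path(outdir, "meth_t0.cov"),
    meth_t12 = file.path(outdir, "meth_t12.cov"),
    expression = file.path(outdir, "expression.tsv"),
    occupancy = file.path(outdir, "occupancy.bedgraph"))
  write_fasta(setNames(sim$genome$sequence, sim$genome$chrom),
              paths["genome"])
  write_bed(mutate(sim$genome$peaks, name = .data$peak_id),
            paths["peaks"])
  utils::write.table(
    data.frame(chrom = sim$genome$chrom, pos = sim$genome$genes$tss,
               strand = sim$genome$genes$strand,
               gene_id = sim$genome$genes$gene_id),
    paths["tss"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_bismark_cov(sim$meth$t0, paths["meth_t0"])
  write_bismark_cov(sim$meth$t12, paths["meth_t12"])
  write_expression(sim$expression, paths["expression"])
  write_bedgraph(sim$occupancy$track, paths["occupancy"])
  invisible(paths)
}

#' Read / write the expression TSV dialect
#'
#' Header is `gene` followed by `condition:replicate` columns; values are
#' FPKM.
#'
#' @param expr Long expression tibble (`gene`, `condition`, `replicate`,
#'   `fpkm`).
#' @param path File path.
#' @return `write_expression()`: `path` invisibly; `read_expression()`:
#'   the long tibble.
#' @export
write_expression <- function(expr, path) {
  wide <- tidyr::pivot_wider(
    mutate(expr, col = paste0(.data$condition, ":", .data$replicate)),
    id_cols = "gene", names_from = "col", values_from = "fpkm")
  utils::write.table(as.data.frame(wide), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  long <- tidyr::pivot_longer(as_tibble(df), -"gene",
                              names_to = "col", values_to = "fpkm")
  parts <- stringr::str_split_fixed(long$col, ":", 2)
  mutate(long, condition = parts[, 1],
         replicate = as.integer(parts[, 2])) |>
    select("gene", "condition", "replicate", "fpkm") |>
    arrange(.data$gene, .data$condition, .data$replicate)
}
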