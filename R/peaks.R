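# Motif-anchored scoring of p65 peaks as candidate memory modules.
# Coordinates are 0-based, half-open throughout; the motif center of an
# even-length motif is start + length %/% 2.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  paste(DNA_COMP[chars], collapse = "")
}

#' Scan a peak sequence for the best kappaB motif hit
#'
#' Log-odds scoring of a probability PWM against a uniform background on
#' both strands; returns the maximum-score hit, ties broken by leftmost
#' position and then the + strand. The log-odds score at offset i is
#' `sum_j log2(pwm[base(i + j), j] / 0.25)`; non-ACGT bases contribute 0.
#'
#' @param seq Peak DNA sequence.
#' @param pwm 4 x width probability matrix (rows A, C, G, T), columns
#'   summing to 1 (see [kb_pwm()], [read_pwm()]).
#' @param background Background base probability.
#' @return One-row tibble: `offset` (0-based start within `seq`),
#'   `width`, `score` (log2 odds), `strand`.
#' @examples
#' scan_kb_motif(paste0("AAAA", "GGGACTTTCC", "AAAA"), kb_pwm())
#' @export
scan_kb_motif <- function(seq, pwm, background = 0.25) {
  seq <- toupper(seq)
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) {
    abort(paste0("sequence length ", n, " shorter than motif width ", w))
  }
  if (any(abs(colSums(pwm) - 1) > 1e-6)) {
    abort("PWM columns must sum to 1")
  }
  lo <- log2(pwm / background)
  score_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, rownames(lo))  # NA for non-ACGT -> contributes 0
    n_off <- n - w + 1
    sc <- numeric(n_off)
    for (j in seq_len(w)) {
      contrib <- lo[cbind(idx[j:(j + n_off - 1)], j)]
      contrib[is.na(contrib)] <- 0
      sc <- sc + contrib
    }
    sc
  }
  fwd <- score_strand(seq)
  rev_sc <- rev(score_strand(revcomp(seq)))  # index by + strand offset
  cand <- tibble(
    offset = rep(0:(n - w), 2),
    strand = rep(c("+", "-"), each = n - w + 1),
    score = c(fwd, rev_sc))
  cand <- cand[order(-cand$score, cand$offset,
                     match(cand$strand, c("+", "-"))), ]
  tibble(offset = cand$offset[1], width = w, score = cand$score[1],
         strand = cand$strand[1])
}

#' Motif center coordinate of a kappaB hit
#'
#' @param peak_start 0-based peak start on the chromosome.
#' @param hit A [scan_kb_motif()] result.
#' @return Absolute 0-based motif center (`start + width %/% 2`).
#' @export
motif_center <- function(peak_start, hit) {
  as.integer(peak_start + hit$offset + hit$width %/% 2)
}

#' CpGs within the flank of a kappaB motif
#'
#' Positions of CpG Cs in the chromosome sequence with
#' `|position - motif_center| <= flank` (inclusive at the boundary),
#' sorted.
#'
#' @param genome_seq Chromosome sequence (string).
#' @param peak_start 0-based peak start.
#' @param hit [scan_kb_motif()] result for the peak.
#' @param flank Flank half-width in bp (default 250).
#' @return Sorted integer vector of 0-based CpG C positions.
#' @export
cpgs_in_flank <- function(genome_seq, peak_start, hit, flank = 250) {
  if (flank <= 0) abort("flank must be > 0")
  center <- motif_center(peak_start, hit)
  lo <- max(0L, center - as.integer(flank))
  hi <- min(nchar(genome_seq) - 1L, center + as.integer(flank) + 1L)
  sub <- substr(genome_seq, lo + 1L, hi + 1L)
  pos <- find_cpgs(sub) + lo
  sort(pos[abs(pos - center) <= flank])
}

#' Methylation summary of a CpG set
#'
#' Mean level and total methylation (M, methylated-CpG equivalents: the
#' sum of per-CpG levels) over the given positions, excluding CpGs under
#' the coverage floor. A peak whose CpGs are all filtered out gets an
#' explicit no-data sentinel (`NA` mean and M with `n_used = 0`), never a
#' silent 0.
#'
#' @param meth Per-CpG tibble (`pos`, `count_meth`, `count_unmeth`,
#'   optionally `chrom`).
#' @param positions 0-based CpG positions to summarise (non-empty).
#' @param min_cov Minimum coverage per CpG (default 5).
#' @param chrom Optional chromosome filter.
#' @return One-row tibble: `mean_level`, `M`, `n_used`.
#' @export
peak_methylation <- function(meth, positions, min_cov = 5, chrom = NULL) {
  if (length(positions) == 0) abort("positions must be non-empty")
  sub <- meth[meth$pos %in% positions, ]
  if (!is.null(chrom) && "chrom" %in% names(sub)) {
    sub <- sub[sub$chrom == chrom, ]
  }
  cov <- sub$count_meth + sub$count_unmeth
  sub <- sub[cov >= min_cov, ]
  if (nrow(sub) == 0) {
    return(tibble(mean_level = NA_real_, M = NA_real_, n_used = 0L))
  }
  lv <- sub$count_meth / (sub$count_meth + sub$count_unmeth)
  tibble(mean_level = mean(lv), M = sum(lv), n_used = nrow(sub))
}

#' Classify the initial methylation state of a peak
#'
#' Mean level >= 0.50 is methylated (inclusive); < 0.20 unmethylated;
#' anything between is intermediate; `NA` (no usable CpGs) propagates.
#'
#' @param level Numeric vector of mean methylation levels in \[0, 1\].
#' @return Character vector: `"methylated"`, `"unmethylated"`,
#'   `"intermediate"`, or `NA`.
#' @export
classify_initial_state <- function(level) {
  if (any(!is.na(level) & (level < 0 | level > 1))) {
    abort("levels must lie in [0, 1]")
  }
  dplyr::case_when(
    is.na(level) ~ NA_character_,
    level >= 0.50 ~ "methylated",
    level < 0.20 ~ "unmethylated",
    TRUE ~ "intermediate")
}

#' Score every peak as a candidate memory module
#'
#' The full motif-anchored accounting for a set of peaks: best kappaB
#' hit, CpG count within the +-`flank` bp of the motif center, mean and
#' total methylation at t0 (naive) and t12 (12-day treatment), total
#' demethylation `delta_M = M_t0 - M_t12`, and the initial-state class.
#' Peaks with no coverage-passing CpG keep `NA` scores and are excluded
#' from methylation-stratified analyses downstream.
#'
#' @param genome_seq Chromosome sequence.
#' @param peaks Tibble: `peak_id`, `chrom`, `start`, `end`.
#' @param pwm kappaB PWM (see [kb_pwm()]).
#' @param meth_t0,meth_t12 Per-CpG methylation tibbles.
#' @param flank Flank half-width around the motif center (default 250).
#' @param min_cov Per-CpG coverage floor (default 5).
#' @return Tibble, one row per peak: `peak_id`, `chrom`, `motif_start`,
#'   `motif_strand`, `motif_score`, `motif_center`, `n_cpg_flank`,
#'   `level_t0`, `level_t12`, `M_t0`, `M_t12`, `delta_M`,
#'   `initial_state`.
#' @export
score_peak_modules <- function(genome_seq, peaks, pwm, meth_t0, meth_t12,
                               flank = 250, min_cov = 5) {
  purrr::map(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    pseq <- substr(genome_seq, pk$start + 1L, pk$end)
    hit <- scan_kb_motif(pseq, pwm)
    center <- motif_center(pk$start, hit)
    cpg <- cpgs_in_flank(genome_seq, pk$start, hit, flank = flank)
    if (length(cpg) == 0) {
      m0 <- m12 <- tibble(mean_level = NA_real_, M = NA_real_,
                          n_used = 0L)
    } else {
      m0 <- peak_methylation(meth_t0, cpg, min_cov, chrom = pk$chrom)
      m12 <- peak_methylation(meth_t12, cpg, min_cov, chrom = pk$chrom)
    }
    tibble(peak_id = pk$peak_id, chrom = pk$chrom,
           motif_start = pk$start + hit$offset,
           motif_strand = hit$strand, motif_score = hit$score,
           motif_center = center,
           n_cpg_flank = length(cpg),
           level_t0 = m0$mean_level, level_t12 = m12$mean_level,
           M_t0 = m0$M, M_t12 = m12$M,
           delta_M = m0$M - m12$M,
           initial_state = classify_initial_state(m0$mean_level))
  }) |> bind_rows()
}

#' Group peaks by demethylation or total methylation
#'
#' `mode = "top_quartile"` implements the memory-module split: among
#' initially methylated peaks, those whose total demethylation `delta_M`
#' is strictly greater than the upper quartile (Q3, type-7 quantile) form
#' the `"topQ"` group, the rest `"rest"`. `mode = "quantile"` cuts
#' `n_bins` equal-count bins of the named statistic (bin 1 = lowest).
#'
#' @param scores [score_peak_modules()] tibble.
#' @param mode `"top_quartile"` or `"quantile"`.
#' @param stat Column to group on (default `"delta_M"`; e.g. `"M_t0"`
#'   for total-methylation quintiles).
#' @param n_bins Number of quantile bins (quantile mode).
#' @return `scores` with a `group` column; bin edges in attribute
#'   `"bin_edges"`.
#' @export
demethylation_grouping <- function(scores,
                                   mode = c("top_quartile", "quantile"),
                                   stat = "delta_M", n_bins = 4) {
  mode <- match.arg(mode)
  x <- scores[[stat]]
  if (any(is.na(x))) abort("scores contain no-data peaks; drop them first")
  if (mode == "top_quartile") {
    if (!all(scores$initial_state == "methylated")) {
      abort("top-quartile grouping is defined on initially methylated peaks only")
    }
    if (max(x) - min(x) < .Machine$double.eps) {
      warn("all values equal; top-quartile group is empty")
      scores$group <- "rest"
      attr(scores, "bin_edges") <- unname(x[1])
      return(scores)
    }
    q3 <- unname(quantile(x, 0.75, type = 7))
    scores$group <- ifelse(x > q3, "topQ", "rest")
    attr(scores, "bin_edges") <- q3
  } else {
    if (nrow(scores) < n_bins) {
      abort(paste0("fewer peaks (", nrow(scores), ") than bins (",
                   n_bins, ")"))
    }
    scores$group <- dplyr::ntile(x, n_bins)
    attr(scores, "bin_edges") <-
      unname(quantile(x, seq(0, 1, length.out = n_bins + 1), type = 7))
  }
  scores
}
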