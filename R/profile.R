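# Demethylation profiles around kappaB motifs, methylation-aware signal
# normalization, profile aggregation, eRNA RPKM and occupancy change.

#' Collect per-CpG levels by signed distance to the motif
#'
#' Joins scored peaks with t0/t12 per-CpG tables and expresses each CpG
#' by its signed distance to the motif center, oriented by the motif
#' strand (so "downstream of the motif" means the same thing for + and -
#' hits).
#'
#' @param scores [score_peak_modules()] tibble (needs `peak_id`, `chrom`,
#'   `motif_center`, `motif_strand`).
#' @param meth_t0,meth_t12 Per-CpG methylation tibbles (`chrom`, `pos`,
#'   `level`).
#' @param window Half-window in bp around the motif center.
#' @return Tibble: `peak_id`, `dist`, `level_t0`, `level_t12`.
#' @export
collect_cpg_profile <- function(scores, meth_t0, meth_t12, window = 1000) {
  purrr::map(seq_len(nrow(scores)), function(i) {
    pk <- scores[i, ]
    near0 <- meth_t0[meth_t0$chrom == pk$chrom &
                       abs(meth_t0$pos - pk$motif_center) <= window, ]
    if (nrow(near0) == 0) return(NULL)
    near12 <- meth_t12[meth_t12$chrom == pk$chrom, ]
    lev12 <- near12$level[match(near0$pos, near12$pos)]
    d <- near0$pos - pk$motif_center
    if (pk$motif_strand == "-") d <- -d
    tibble(peak_id = pk$peak_id, dist = d,
           level_t0 = near0$level, level_t12 = lev12)
  }) |> bind_rows()
}

#' Lowess demethylation profile around the motif
#'
#' Smooths per-CpG t0 and t12 levels, and their pointwise difference
#' (t0 - t12), against signed distance to the motif center. The
#' difference curve is the lowess of per-CpG differences (pairing is
#' defined at CpGs; smoothing after subtraction avoids grid mismatch).
#' Curves are tabulated on a fixed grid by linear interpolation.
#'
#' @param points Per-CpG tibble from [collect_cpg_profile()] (`dist`,
#'   `level_t0`, `level_t12`).
#' @param window Half-window in bp; points beyond it are dropped.
#' @param lowess_frac Lowess smoother span (default 0.3).
#' @param grid_by Grid step in bp for the tabulated curves.
#' @return Object of class `demeth_profile`: list with `points`,
#'   `curves` (tibble: `dist`, `t0`, `t12`, `diff`), `window`,
#'   `lowess_frac`.
#' @export
demethylation_profile <- function(points, window = 1000,
                                  lowess_frac = 0.3, grid_by = 10) {
  if (window <= 0) abort("window must be > 0")
  pts <- points[!is.na(points$level_t0) & !is.na(points$level_t12) &
                  abs(points$dist) <= window, ]
  if (nrow(pts) < 10) {
    abort(paste0("need >= 10 CpG observations for lowess, got ",
                 nrow(pts)))
  }
  grid <- seq(-window, window, by = grid_by)
  smooth_on_grid <- function(y) {
    lw <- lowess(pts$dist, y, f = lowess_frac)
    # rule = 2: hold the boundary value where the grid extends past the
    # outermost CpG
    approx(lw$x, lw$y, xout = grid, ties = mean, rule = 2)$y
  }
  curves <- tibble(dist = grid,
                   t0 = smooth_on_grid(pts$level_t0),
                   t12 = smooth_on_grid(pts$level_t12),
                   diff = smooth_on_grid(pts$level_t0 - pts$level_t12))
  structure(list(points = pts, curves = curves, window = window,
                 lowess_frac = lowess_frac),
            class = "demeth_profile")
}

#' @export
print.demeth_profile <- function(x, ...) {
  cat("<demeth_profile>", nrow(x$points), "CpG observations, +-",
      x$window, "bp, lowess span", x$lowess_frac, "\n")
  invisible(x)
}

#' @export
tidy.demeth_profile <- function(x, ...) {
  tidyr::pivot_longer(x$curves, -"dist", names_to = "curve",
                      values_to = "level")
}

#' Normalize signal tracks against initially unmethylated peaks
#'
#' Two-step normalization: each sample is first depth-normalized to
#' counts per million (values scaled to sum to 1e6), then multiplied by
#' a scale factor `s_j = grand mean / sample j mean`, where the means are
#' of the signal at initially unmethylated reference peaks (methylation
#' level < 20%) and the grand mean averages over samples. After scaling,
#' per-sample mean signal at the reference peaks is equal, so occupancy
#' comparisons across samples are not confounded by global efficiency.
#' The operation is idempotent.
#'
#' @param tracks Binned signal tibble: `sample`, `chrom`, `start`, `end`,
#'   `value`.
#' @param unmeth_peaks Tibble of initially unmethylated peak intervals
#'   (`chrom`, `start`, `end`); if it carries an `initial_state` column,
#'   rows are filtered to `"unmethylated"` first.
#' @return `tracks` with scaled `value`; scale factors in attribute
#'   `"scale_factors"`.
#' @export
normalize_signal <- function(tracks, unmeth_peaks) {
  stopifnot(all(c("sample", "chrom", "start", "end", "value") %in%
                  names(tracks)))
  if ("initial_state" %in% names(unmeth_peaks)) {
    unmeth_peaks <- unmeth_peaks[
      !is.na(unmeth_peaks$initial_state) &
        unmeth_peaks$initial_state == "unmethylated", ]
  }
  if (nrow(unmeth_peaks) == 0) {
    abort("need >= 1 initially unmethylated reference peak")
  }
  cpm <- tracks |>
    group_by(.data$sample) |>
    mutate(value = .data$value * 1e6 / sum(.data$value)) |>
    ungroup()
  at_ref <- overlaps_any(cpm, unmeth_peaks)
  ref_means <- cpm[at_ref, ] |>
    group_by(.data$sample) |>
    summarise(m = mean(.data$value), .groups = "drop")
  missing <- setdiff(unique(cpm$sample), ref_means$sample)
  if (length(missing) > 0 || any(ref_means$m <= 0)) {
    abort("a sample has zero signal at the unmethylated reference peaks")
  }
  grand <- mean(ref_means$m)
  s <- setNames(grand / ref_means$m, ref_means$sample)
  out <- mutate(cpm, value = .data$value * unname(s[.data$sample]))
  attr(out, "scale_factors") <- s
  out
}

#' Averaged signal profile around motif centers
#'
#' Mean binned signal across peaks in a window centered on each peak's
#' motif center, oriented by motif strand, optionally per group (and per
#' sample when the track carries several). Bin values are
#' coverage-weighted means of overlapping track intervals; uncovered
#' ground counts as 0.
#'
#' @param tracks Signal tibble: `chrom`, `start`, `end`, `value`, and
#'   optionally `sample`.
#' @param peaks Tibble with `chrom`, `motif_center`, optionally
#'   `motif_strand` and `group`.
#' @param half_window Half-window in bp (default 500: a 1 kb view).
#' @param bin Bin width in bp; must divide the window evenly.
#' @return Tibble: `sample` (if present), `group` (if present), `offset`
#'   (bin start relative to the motif center), `value` (mean over
#'   peaks).
#' @export
aggregate_profile <- function(tracks, peaks, half_window = 500, bin = 50) {
  if ((2 * half_window) %% bin != 0) {
    abort("bin width must divide the 2 * half_window window evenly")
  }
  if (!"sample" %in% names(tracks)) tracks$sample <- "signal"
  if (!"motif_strand" %in% names(peaks)) peaks$motif_strand <- "+"
  offsets <- seq(-half_window, half_window - bin, by = bin)
  per_peak <- purrr::map(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    tr <- tracks[tracks$chrom == pk$chrom, ]
    purrr::map(split(tr, tr$sample), function(trs) {
      vals <- vapply(offsets, function(off) {
        o <- if (pk$motif_strand == "-") -off - bin else off
        a <- pk$motif_center + o
        b <- a + bin
        ov <- pmin(trs$end, b) - pmax(trs$start, a)
        keep <- ov > 0
        if (!any(keep)) return(0)
        sum(trs$value[keep] * ov[keep]) / bin
      }, 0)
      tibble(sample = trs$sample[1], peak_i = i, offset = offsets,
             value = vals,
             group = if ("group" %in% names(pk)) pk$group else "all")
    }) |> bind_rows()
  }) |> bind_rows()
  per_peak |>
    group_by(.data$sample, .data$group, .data$offset) |>
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Enhancer-RNA RPKM over peak regions
#'
#' `RPKM = count / (peak length in kb * library size in millions)`.
#'
#' @param counts Tibble: `peak_id`, `sample`, `count` (reads mapped to
#'   the peak).
#' @param peaks Tibble with `peak_id`, `start`, `end` (bp).
#' @param library_sizes Named numeric vector of total mapped reads per
#'   sample.
#' @return `counts` with an `rpkm` column.
#' @export
erna_rpkm <- function(counts, peaks, library_sizes) {
  stopifnot(all(c("peak_id", "sample", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be >= 0")
  len <- setNames(peaks$end - peaks$start, peaks$peak_id)
  if (any(len <= 0)) abort("peak lengths must be > 0")
  libs <- library_sizes[counts$sample]
  if (any(is.na(libs)) || any(libs <= 0)) {
    abort("every sample needs a positive library size")
  }
  mutate(counts,
         rpkm = .data$count /
           ((unname(len[.data$peak_id]) / 1e3) * (unname(libs) / 1e6)))
}

#' Classify per-peak occupancy change between inductions
#'
#' Log2 ratio of second- vs first-induction signal at each peak (both
#' from [normalize_signal()]ed tracks); `|log2 ratio| >= log2(fold)`
#' splits peaks into higher/lower in the second induction (inclusive at
#' the threshold), the remainder is unchanged.
#'
#' @param signal Tibble: `peak_id`, `signal_first`, `signal_second`
#'   (positive).
#' @param fold Fold-change threshold (default 1.5).
#' @return `signal` with `log2_ratio` and `change` in
#'   `{"higher_in_second", "lower_in_second", "unchanged"}`.
#' @export
occupancy_change <- function(signal, fold = 1.5) {
  stopifnot(all(c("peak_id", "signal_first", "signal_second") %in%
                  names(signal)))
  if (any(signal$signal_first <= 0 | signal$signal_second <= 0)) {
    abort("signals must be > 0 (normalize first)")
  }
  thr <- log2(fold)
  mutate(signal,
         log2_ratio = log2(.data$signal_second / .data$signal_first),
         change = dplyr::case_when(
           .data$log2_ratio >= thr ~ "higher_in_second",
           .data$log2_ratio <= -thr ~ "lower_in_second",
           TRUE ~ "unchanged"))
}
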