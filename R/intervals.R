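# Interval operations on 0-based half-open tibbles. IRanges does the
# heavy lifting; coordinates are converted to its 1-based closed form at
# this boundary only.

as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# logical: does row i of a overlap (>= 1 bp) anything in b on the same
# chromosome?
overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0) next
    hits <- IRanges::overlapsAny(as_iranges(a[ai, ]),
                                 as_iranges(b[bi, ]))
    out[ai] <- hits
  }
  out
}

#' Merge peak sets into a consensus and remove blacklisted regions
#'
#' The union of both peak sets with overlapping or bookended intervals
#' merged; any merged interval overlapping the blacklist by >= 1 bp is
#' removed. This is the consensus-peak construction applied to the first-
#' and second-induction p65 peak calls.
#'
#' @param peaks_first,peaks_second Interval tibbles (`chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param blacklist Optional interval tibble of regions to exclude.
#' @return Consensus tibble `chrom`, `start`, `end`, sorted, with
#'   `peak_id` labels.
#' @export
merge_consensus_peaks <- function(peaks_first, peaks_second,
                                  blacklist = NULL) {
  all <- bind_rows(peaks_first[c("chrom", "start", "end")],
                   peaks_second[c("chrom", "start", "end")])
  if (nrow(all) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), peak_id = character()))
  }
  merged <- purrr::map(split(all, all$chrom), function(x) {
    r <- IRanges::reduce(as_iranges(x))
    tibble(chrom = x$chrom[1],
           start = IRanges::start(r) - 1L,
           end = IRanges::end(r))
  }) |> bind_rows() |> arrange(.data$chrom, .data$start)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    merged <- merged[!overlaps_any(merged, blacklist), ]
  }
  mutate(merged, peak_id = sprintf("consensus%04d", row_number()))
}

#' Define TNF-alpha-responsive elements
#'
#' TNF-alpha-induced p65 peaks co-occupied by H3K27ac. "Induced" means
#' present at 12 h of treatment with no >= 1 bp overlap with any 0 h p65
#' peak; co-occupancy means >= 1 bp overlap with an H3K27ac peak.
#' Intervals are half-open, so bookended peaks do not overlap.
#'
#' @param p65_12h p65 peak tibble at 12 h TNF-alpha.
#' @param h3k27ac H3K27ac peak tibble.
#' @param p65_0h Optional 0 h p65 peaks; when supplied, peaks already
#'   present at 0 h are not "induced" and are excluded.
#' @return Tibble of responsive elements (subset of `p65_12h` rows).
#' @export
define_responsive_elements <- function(p65_12h, h3k27ac, p65_0h = NULL) {
  induced <- if (!is.null(p65_0h) && nrow(p65_0h) > 0) {
    p65_12h[!overlaps_any(p65_12h, p65_0h), ]
  } else {
    p65_12h
  }
  induced[overlaps_any(induced, h3k27ac), ]
}

#' Link peaks to their nearest gene TSS
#'
#' Each peak is linked to the single nearest TSS on the same chromosome
#' by `|motif_center - TSS|`, dropped when the distance exceeds
#' `max_dist` (inclusive cap: a TSS at exactly `max_dist` is kept).
#' Distance ties are broken by the lexicographically smaller gene id.
#' The `within_10kb` flag marks links at `|distance| <= within_dist` for
#' the distance-stratified comparisons.
#'
#' @param peaks Tibble with `peak_id`, `chrom` and `motif_center`
#'   (absolute 0-based; see [score_peak_modules()]).
#' @param tss Tibble with `chrom`, `pos`, `gene_id`.
#' @param max_dist Maximum absolute peak-TSS distance (default 100 kb).
#' @param within_dist Distance for the `within_10kb` flag (default 10 kb).
#' @return Tibble: `peak_id`, `gene_id`, `distance` (signed,
#'   TSS - motif center), `within_10kb`.
#' @export
link_peaks_to_genes <- function(peaks, tss, max_dist = 100000,
                                within_dist = 10000) {
  if (nrow(tss) == 0) abort("TSS table is empty")
  stopifnot(all(c("peak_id", "chrom", "motif_center") %in% names(peaks)),
            all(c("chrom", "pos", "gene_id") %in% names(tss)))
  purrr::map(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    cand <- tss[tss$chrom == pk$chrom, ]
    if (nrow(cand) == 0) return(NULL)
    d <- cand$pos - pk$motif_center
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) {
      best <- best[order(cand$gene_id[best])][1]
    }
    if (abs(d[best]) > max_dist) return(NULL)
    tibble(peak_id = pk$peak_id, gene_id = cand$gene_id[best],
           distance = d[best],
           within_10kb = abs(d[best]) <= within_dist)
  }) |> bind_rows() |>
    (\(x) if (nrow(x) == 0) {
      tibble(peak_id = character(), gene_id = character(),
             distance = double(), within_10kb = logical())
    } else x)()
}
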