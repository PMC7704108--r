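# Brute-force oracles, written independently of the package internals:
# plain loops and boolean coverage vectors, no shared helpers.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exhaustive PWM scan: every offset, both strands, explicit tie rules
oracle_scan <- function(seq, pwm, background = 0.25) {
  w <- ncol(pwm)
  n <- nchar(seq)
  best <- list(score = -Inf, offset = NA, strand = NA)
  for (off in 0:(n - w)) {
    for (strand in c("+", "-")) {
      win <- substr(seq, off + 1, off + w)
      if (strand == "-") win <- oracle_revcomp(win)
      sc <- 0
      for (j in 1:w) {
        b <- substr(win, j, j)
        if (b %in% rownames(pwm)) {
          sc <- sc + unname(log2(pwm[b, j] / background))
        }
      }
      better <- sc > best$score + 1e-12
      tie <- abs(sc - best$score) <= 1e-12
      if (better ||
          (tie && off < best$offset) ||
          (tie && off == best$offset && strand == "+" &&
             best$strand == "-")) {
        best <- list(score = sc, offset = off, strand = strand)
      }
    }
  }
  best
}

# merge via a boolean coverage vector (bookended intervals fuse because
# they tile adjacent positions)
oracle_merge <- function(starts, ends) {
  if (length(starts) == 0) return(list(start = integer(0), end = integer(0)))
  L <- max(ends) + 2
  covered <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1
  keep <- r$values
  list(start = begins[keep] - 1L, end = stops[keep])
}

# does interval i of a overlap >= 1 bp with any interval of b?
oracle_overlaps_any <- function(a_start, a_end, b_start, b_end) {
  out <- logical(length(a_start))
  for (i in seq_along(a_start)) {
    for (j in seq_along(b_start)) {
      if (a_start[i] < b_end[j] && b_start[j] < a_end[i]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# all-pairs nearest-TSS search with the smaller-gene-id tie rule
oracle_nearest <- function(centers, tss_pos, gene_ids, max_dist) {
  res <- list()
  for (i in seq_along(centers)) {
    best_d <- Inf
    best_g <- NULL
    best_signed <- NA
    for (j in seq_along(tss_pos)) {
      d <- abs(tss_pos[j] - centers[i])
      if (d < best_d ||
          (d == best_d && !is.null(best_g) && gene_ids[j] < best_g)) {
        best_d <- d
        best_g <- gene_ids[j]
        best_signed <- tss_pos[j] - centers[i]
      }
    }
    if (is.finite(best_d) && best_d <= max_dist) {
      res[[length(res) + 1]] <- data.frame(peak = i, gene = best_g,
                                           distance = best_signed)
    }
  }
  do.call(rbind, res)
}

random_intervals <- function(n, max_pos = 1000, max_w = 120) {
  s <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = "chrT", start = s,
                 end = s + sample.int(max_w, n, replace = TRUE))
}

# a random probability PWM (columns sum to 1)
random_pwm <- function(width) {
  m <- matrix(stats::runif(4 * width, 0.05, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T")))
  sweep(m, 2, colSums(m), "/")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-buildable mini genome for dynamics/occupancy closed-form checks
mini_genome <- function(cpg_pos, p0, motif_start = 1000L,
                        peak_start = 800L, peak_end = 1400L, L = 2000L) {
  structure(list(
    chrom = "chrS", length = L,
    sequence = paste(rep("A", L), collapse = ""),
    peaks = tibble::tibble(peak_id = "pk1", chrom = "chrS",
                           start = peak_start, end = peak_end,
                           motif_start = motif_start, motif_strand = "+",
                           cpg_class = "high", meth_class = "methylated"),
    cpgs = tibble::tibble(peak_id = "pk1", pos = as.integer(cpg_pos),
                          p0 = p0),
    genes = tibble::tibble(gene_id = "gene001", tss = 100L, strand = "+")),
    class = "toy_genome")
}

# meth table with exact levels encoded as counts at a given coverage
meth_table <- function(pos, level, coverage = 100L, chrom = "chrS") {
  m <- round(level * coverage)
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 level = m / coverage, count_meth = as.integer(m),
                 count_unmeth = as.integer(coverage - m))
}
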