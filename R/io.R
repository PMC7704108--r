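#' Read a BED file of genomic intervals
#'
#' Intervals are 0-based, half-open, as in the BED standard. `track` and
#' `browser` header lines and `#` comments are skipped. Malformed rows are
#' rejected loudly with their line numbers; nothing is silently coerced.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines(c("track name=demo", "chr1\t0\t100\tpk1"), p)
#' read_bed(p)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)\\b|^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", idx[which(nf < 3)[1]],
                 ": fewer than 3 fields"))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("BED line ", idx[bad[1]], ": non-numeric start/end"))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(paste0("BED line ", idx[bad[1]],
                 ": requires 0 <= start < end, got [",
                 start[bad[1]], ", ", end[bad[1]], ")"))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  out
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  df <- as.data.frame(x[cols])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage file of per-CpG methylation
#'
#' Expects the six-column Bismark coverage dialect: chrom, start (1-based),
#' end, methylation percentage, methylated count, unmethylated count.
#' Positions are converted to 0-based internally; the methylation level is
#' recomputed from the counts (the percentage column is advisory) and a
#' disagreement above 0.5 percentage points triggers a warning.
#'
#' @param path Path to the coverage file.
#' @return A tibble with `chrom`, `pos` (0-based position of the CpG C),
#'   `level` (in \[0, 1\], `NA` at zero coverage), `count_meth`,
#'   `count_unmeth`.
#' @export
read_bismark_cov <- function(path) {
  if (!file.exists(path)) abort(paste0("coverage file not found: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  if (length(keep) == 0) {
    return(tibble(chrom = character(), pos = integer(), level = double(),
                  count_meth = integer(), count_unmeth = integer()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(paste0("coverage line ", keep[which(nf < 6)[1]],
                 ": expected 6 columns, got ", nf[which(nf < 6)[1]]))
  }
  getn <- function(j) suppressWarnings(
    as.numeric(vapply(fields, `[[`, "", j)))
  start1 <- getn(2)
  pct <- getn(4)
  cm <- getn(5)
  cu <- getn(6)
  bad <- which(is.na(start1) | is.na(cm) | is.na(cu))
  if (length(bad) > 0) {
    abort(paste0("coverage line ", keep[bad[1]], ": non-numeric field"))
  }
  bad <- which(cm < 0 | cu < 0)
  if (length(bad) > 0) {
    abort(paste0("coverage line ", keep[bad[1]], ": negative count"))
  }
  cov <- cm + cu
  level <- ifelse(cov > 0, cm / cov, NA_real_)
  stated <- pct / 100
  disagree <- which(cov > 0 & !is.na(stated) &
                      abs(level - stated) > 0.005)
  if (length(disagree) > 0) {
    warn(paste0(length(disagree), " record(s) disagree with their stated ",
                "methylation % by > 0.5 points (first at line ",
                keep[disagree[1]], "); counts take precedence"))
  }
  tibble(chrom = vapply(fields, `[[`, "", 1),
         pos = as.integer(start1) - 1L,
         level = level,
         count_meth = as.integer(cm),
         count_unmeth = as.integer(cu))
}

#' Write a per-CpG methylation table in Bismark coverage dialect
#'
#' Inverse of [read_bismark_cov()]: positions go out 1-based, the
#' percentage column is recomputed from counts (0 at zero coverage).
#'
#' @param meth Tibble with `chrom`, `pos`, `count_meth`, `count_unmeth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(meth, path) {
  cov <- meth$count_meth + meth$count_unmeth
  pct <- ifelse(cov > 0, 100 * meth$count_meth / cov, 0)
  df <- data.frame(meth$chrom, meth$pos + 1L, meth$pos + 1L,
                   formatC(pct, format = "fg", digits = 8),
                   meth$count_meth, meth$count_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings that move sequences in and out of plain
#' named character vectors, the form the rest of the package works with.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of DNA sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a position weight matrix from TSV
#'
#' Format: one row per motif position, tab-separated columns A, C, G, T
#' with a header line; each row (position) must sum to 1. Returned
#' transposed to the internal 4 x width orientation.
#'
#' @param path PWM TSV path.
#' @return 4 x width numeric matrix, rows A, C, G, T.
#' @export
read_pwm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    abort("PWM file must have columns A, C, G, T")
  }
  m <- t(as.matrix(df[need]))
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  if (any(abs(colSums(m) - 1) > 1e-6)) {
    abort("PWM positions must each sum to 1")
  }
  m
}

#' @param pwm 4 x width probability matrix (rows A, C, G, T).
#' @rdname read_pwm
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(t(pwm))
  names(df) <- c("A", "C", "G", "T")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bedGraph signal track
#'
#' @param track Tibble with `chrom`, `start`, `end`, `value` (and
#'   optionally `sample`, written as separate files suffixed by sample).
#' @param path Output path (or prefix when multiple samples).
#' @return Path(s) written, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if ("sample" %in% names(track) && length(unique(track$sample)) > 1) {
    paths <- vapply(split(track, track$sample), function(tr) {
      p <- sub("(\\.bedgraph)?$", paste0(".", tr$sample[1], ".bedgraph"),
               sub("\\.bedgraph$", "", path))
      write_bedgraph(tr[setdiff(names(tr), "sample")], p)
    }, "")
    return(invisible(paths))
  }
  df <- as.data.frame(track[c("chrom", "start", "end", "value")])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a set of result tables with a provenance header
#'
#' Each element of `results` is written as `<name>.tsv` under `outdir`,
#' rows sorted by the first column, preceded by commented provenance lines
#' (package version, config hash, seed) so identical inputs give
#' byte-identical files.
#'
#' @param results Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in the header.
#' @param config Optional config list; a short hash of it is recorded.
#' @param force Overwrite existing files; without it a collision errors.
#' @return Character vector of paths written, invisibly.
#' @export
write_reports <- function(results, outdir, seed = NA, config = NULL,
                          force = FALSE) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- if (is.null(config)) "none" else {
    raw <- serialize(unclass(config), NULL, version = 2)
    # cheap stable checksum; avoids a digest dependency
    sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
              .Machine$integer.max)
  }
  header <- c(
    paste0("# memoryscan ", as.character(utils::packageVersion("memoryscan"))),
    paste0("# config_hash: ", cfg_hash),
    paste0("# seed: ", seed))
  paths <- character(0)
  for (nm in names(results)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    if (file.exists(path) && !force) {
      abort(paste0("output exists (use force = TRUE): ", path))
    }
    df <- as.data.frame(results[[nm]])
    if (nrow(df) > 1) df <- df[order(df[[1]]), , drop = FALSE]
    con <- file(path, "w")
    writeLines(header, con)
    suppressWarnings(utils::write.table(
      df, con, sep = "\t", quote = FALSE, row.names = FALSE))
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a report written by [write_reports()]
#'
#' @param path Report TSV path.
#' @return Tibble of the table body (provenance comments skipped).
#' @export
read_report <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#",
                              stringsAsFactors = FALSE))
}
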