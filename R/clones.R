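#' Define a bisulfite amplicon locus
#'
#' A locus is the unconverted genomic reference of a bisulfite PCR
#' amplicon together with the 0-based offsets of the C of every CpG.
#' Loci are handled top-strand only, in the orientation of the bisulfite
#' PCR design.
#'
#' @param id Locus identifier (e.g. `"CMV"`, `"MER11B-left"`).
#' @param reference Unconverted reference sequence (A/C/G/T string).
#' @param cpg_pos Optional integer vector of 0-based CpG C offsets; found
#'   by scanning the reference when omitted. Each offset must index a C
#'   followed by a G.
#' @param label Optional region label.
#' @return A list of class `bis_locus` with fields `id`, `reference`,
#'   `cpg_pos`, `label`.
#' @examples
#' loc <- bis_locus("toy", "ACGTACGT")
#' loc$cpg_pos  # 1, 5 (0-based)
#' @export
bis_locus <- function(id, reference, cpg_pos = NULL, label = id) {
  reference <- toupper(reference)
  if (nchar(reference) == 0) abort("empty reference sequence")
  if (is.null(cpg_pos)) cpg_pos <- find_cpgs(reference)
  cpg_pos <- as.integer(cpg_pos)
  if (length(cpg_pos) == 0) abort("reference contains no CpG")
  if (is.unsorted(cpg_pos, strictly = TRUE)) {
    abort("CpG positions must be strictly increasing")
  }
  chars <- strsplit(reference, "")[[1]]
  ok <- chars[cpg_pos + 1] == "C" &
    c(chars, "")[cpg_pos + 2] == "G"
  if (!all(ok)) {
    abort(paste0("offset ", cpg_pos[which(!ok)[1]],
                 " does not index a CpG in the reference"))
  }
  structure(list(id = id, reference = reference, cpg_pos = cpg_pos,
                 label = label),
            class = "bis_locus")
}

#' Find CpG dinucleotides in a sequence
#'
#' @param seq DNA string.
#' @return 0-based positions of the C of each CG dinucleotide.
#' @export
find_cpgs <- function(seq) {
  as.integer(gregexpr("CG", toupper(seq), fixed = TRUE)[[1]]) |>
    (\(p) if (length(p) == 1 && p[1] == -1) integer(0) else p - 1L)()
}

#' Call the methylation pattern of one bisulfite clone
#'
#' Gapless comparison of a Sanger clone against the unconverted reference:
#' at each CpG C an observed C is called methylated (`M`), a T
#' unmethylated (`U`), anything else (including N) missing (`.`). The
#' non-CpG conversion rate (fraction of non-CpG reference Cs read as T)
#' and the mismatch rate at non-C reference positions are recorded for QC.
#' Clones are PCR amplicons of a fixed locus, so indel-bearing clones are
#' rejected by the length check rather than aligned.
#'
#' @param locus A [bis_locus()].
#' @param clone_seq Clone sequence, same length as the reference.
#' @param clone_id Identifier stored with the pattern.
#' @return A list of class `clone_pattern`: `clone_id`, `calls` (character
#'   vector over locus CpGs, values `"M"`, `"U"`, `"."`),
#'   `conversion_rate`, `mismatch_rate`.
#' @export
call_clone <- function(locus, clone_seq, clone_id = "clone") {
  stopifnot(inherits(locus, "bis_locus"))
  clone_seq <- toupper(clone_seq)
  if (nchar(clone_seq) == 0) abort("empty clone sequence")
  if (nchar(clone_seq) != nchar(locus$reference)) {
    abort(paste0("clone length ", nchar(clone_seq),
                 " != reference length ", nchar(locus$reference),
                 " (gapless comparison; indel clones are rejected)"))
  }
  ref <- strsplit(locus$reference, "")[[1]]
  obs <- strsplit(clone_seq, "")[[1]]
  cpg_i <- locus$cpg_pos + 1L
  calls <- rep(".", length(cpg_i))
  calls[obs[cpg_i] == "C"] <- "M"
  calls[obs[cpg_i] == "T"] <- "U"
  non_cpg_c <- setdiff(which(ref == "C"), cpg_i)
  conv <- if (length(non_cpg_c) > 0) {
    mean(obs[non_cpg_c] == "T")
  } else NA_real_
  non_c <- which(ref != "C")
  mism <- if (length(non_c) > 0) mean(obs[non_c] != ref[non_c]) else 0
  structure(list(clone_id = clone_id, calls = calls,
                 conversion_rate = conv, mismatch_rate = mism),
            class = "clone_pattern")
}

#' Assemble clone patterns into a clone set
#'
#' @param locus A [bis_locus()].
#' @param patterns List of `clone_pattern` objects for that locus.
#' @return A list of class `clone_set`: `locus`, `calls` (clones x CpGs
#'   character matrix), `qc` tibble (per-clone rates), and the QC
#'   thresholds applied so far (none yet).
#' @export
clone_set <- function(locus, patterns) {
  stopifnot(inherits(locus, "bis_locus"))
  bad <- vapply(patterns, function(p) {
    length(p$calls) != length(locus$cpg_pos)
  }, TRUE)
  if (any(bad)) abort("pattern call length differs from locus CpG count")
  ids <- vapply(patterns, `[[`, "", "clone_id")
  calls <- do.call(rbind, lapply(patterns, `[[`, "calls"))
  rownames(calls) <- ids
  qc <- tibble(
    clone_id = ids,
    conversion_rate = vapply(patterns, `[[`, 0, "conversion_rate"),
    mismatch_rate = vapply(patterns, `[[`, 0, "mismatch_rate"))
  structure(list(locus = locus, calls = calls, qc = qc,
                 thresholds = NULL, n_removed = 0L),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set> locus", x$locus$id, "-", nrow(x$calls), "clones x",
      length(x$locus$cpg_pos), "CpGs\n")
  invisible(x)
}

#' Filter clones on bisulfite QC
#'
#' Retains clones whose non-CpG conversion rate is at least
#' `min_conversion` and mismatch rate at most `max_mismatch`; conventional
#' bisulfite clone QC. A clone with no non-CpG C (conversion rate
#' undefined) is retained.
#'
#' @param clones A [clone_set()].
#' @param min_conversion Minimum non-CpG C->T conversion fraction.
#' @param max_mismatch Maximum mismatch fraction at non-C positions.
#' @return Filtered `clone_set`, with `n_removed` and the thresholds
#'   recorded.
#' @export
qc_filter <- function(clones, min_conversion = 0.95, max_mismatch = 0.10) {
  stopifnot(inherits(clones, "clone_set"))
  if (min_conversion < 0 || min_conversion > 1 ||
      max_mismatch < 0 || max_mismatch > 1) {
    abort("QC thresholds must lie in [0, 1]")
  }
  keep <- (is.na(clones$qc$conversion_rate) |
             clones$qc$conversion_rate >= min_conversion) &
    clones$qc$mismatch_rate <= max_mismatch
  out <- clones
  out$calls <- clones$calls[keep, , drop = FALSE]
  out$qc <- clones$qc[keep, ]
  out$thresholds <- list(min_conversion = min_conversion,
                         max_mismatch = max_mismatch)
  out$n_removed <- clones$n_removed + sum(!keep)
  out
}

#' Locus-level and per-CpG methylation of a clone set
#'
#' Pools methylated/unmethylated calls over all clones: the locus level is
#' `# M / (# M + # U)`; per-CpG levels are computed column-wise the same
#' way. Missing calls enter neither numerator nor denominator. The locus
#' level therefore equals the call-count-weighted mean of the per-CpG
#' levels.
#'
#' @param clones A [clone_set()].
#' @return A list of class `locus_level`: `locus_id`, `level`, `n_clones`,
#'   `n_meth`, `n_unmeth`, and `per_cpg` (tibble: `cpg_pos`, `level`,
#'   `n_meth`, `n_unmeth`).
#' @examples
#' loc <- bis_locus("toy", "ACGACGACGACG")
#' cs <- clone_set(loc, list(
#'   call_clone(loc, "ATGATGATGATG", "c1"),  # all U
#'   call_clone(loc, "ACGACGACGACG", "c2"))) # all M
#' locus_level(cs)$level  # 0.5
#' @export
locus_level <- function(clones) {
  stopifnot(inherits(clones, "clone_set"))
  m <- colSums(clones$calls == "M")
  u <- colSums(clones$calls == "U")
  if (sum(m) + sum(u) == 0) abort("all calls missing; no level defined")
  per_cpg <- tibble(cpg_pos = clones$locus$cpg_pos,
                    level = ifelse(m + u > 0, m / (m + u), NA_real_),
                    n_meth = unname(m), n_unmeth = unname(u))
  structure(list(locus_id = clones$locus$id,
                 level = sum(m) / (sum(m) + sum(u)),
                 n_clones = nrow(clones$calls),
                 n_meth = sum(m), n_unmeth = sum(u),
                 per_cpg = per_cpg),
            class = "locus_level")
}

#' @export
print.locus_level <- function(x, ...) {
  cat(sprintf("<locus_level> %s: %.1f%% (%d M / %d calls, %d clones)\n",
              x$locus_id, 100 * x$level, x$n_meth, x$n_meth + x$n_unmeth,
              x$n_clones))
  invisible(x)
}

LOLLIPOP_GLYPHS <- c(M = "●", U = "○", "." = "-")

#' Text lollipop matrix of a clone set
#'
#' Rows are clones, columns CpGs in genomic order; filled circles mark
#' methylated CpGs, open circles unmethylated ones, `-` missing calls.
#' Round-trips through [read_lollipop()] unchanged.
#'
#' @param clones A [clone_set()].
#' @param ascii Use `#`/`o` instead of Unicode circles.
#' @return Character vector, one row per clone, named by clone id.
#' @export
lollipop_matrix <- function(clones, ascii = FALSE) {
  stopifnot(inherits(clones, "clone_set"))
  if (nrow(clones$calls) == 0) abort("empty clone set")
  glyphs <- if (ascii) c(M = "#", U = "o", "." = "-") else LOLLIPOP_GLYPHS
  rows <- apply(clones$calls, 1, function(r) {
    paste(glyphs[r], collapse = "")
  })
  setNames(rows, rownames(clones$calls))
}

#' Write / read a lollipop text file
#'
#' @param clones A [clone_set()].
#' @param path File path.
#' @param ascii Use ASCII glyphs.
#' @return `write_lollipop()`: `path` invisibly. `read_lollipop()`: a
#'   tibble (`clone_id`, `calls` character matrix column order preserved)
#'   reconstructing the calls.
#' @export
write_lollipop <- function(clones, path, ascii = TRUE) {
  rows <- lollipop_matrix(clones, ascii = ascii)
  writeLines(paste(names(rows), rows, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_lollipop
#' @export
read_lollipop <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  glyph_rows <- vapply(parts, `[[`, "", 2)
  inv <- c("#" = "M", "o" = "U", "-" = ".",
           "●" = "M", "○" = "U")
  calls <- do.call(rbind, lapply(strsplit(glyph_rows, ""), function(g) {
    unname(inv[g])
  }))
  rownames(calls) <- ids
  calls
}

#' Summarise a clone set as a report row
#'
#' @param clones A [clone_set()] after QC.
#' @param n_failed Number of clones removed by QC (taken from the set).
#' @return One-row tibble: locus, clones passed/failed, locus level and
#'   comma-joined per-CpG levels.
#' @export
clone_report <- function(clones, n_failed = clones$n_removed) {
  ll <- locus_level(clones)
  tibble(locus = ll$locus_id,
         n_clones_pass = ll$n_clones,
         n_clones_fail = n_failed,
         locus_level = ll$level,
         per_cpg_levels = paste(sprintf("%.4f", ll$per_cpg$level),
                                collapse = ","))
}

#' @export
tidy.clone_set <- function(x, ...) {
  calls <- x$calls
  tibble(clone_id = rep(rownames(calls), each = ncol(calls)),
         cpg_pos = rep(x$locus$cpg_pos, times = nrow(calls)),
         call = as.vector(t(calls)))
}

#' @export
tidy.locus_level <- function(x, ...) {
  mutate(x$per_cpg, locus = x$locus_id, .before = 1)
}
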