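# Memory-gene classification from five-condition FPKM tables.
#
# Conditions follow the repeated-induction design: naive_0h, first_12h
# (first TNF-alpha induction), sustained_12d (memory consolidation),
# recovery_10d (stimulus withdrawal), second_12h (second induction).
# A pseudocount of 1 FPKM is applied to every ratio and log transform so
# all-zero genes stay well defined.

cond_means <- function(expr, conditions = NULL) {
  stopifnot(all(c("gene", "condition", "fpkm") %in% names(expr)))
  if (any(expr$fpkm < 0)) abort("FPKM values must be >= 0")
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, unique(expr$condition))
    if (length(missing) > 0) {
      abort(paste0("condition not present in expression table: ",
                   paste(missing, collapse = ", ")))
    }
  }
  expr |>
    group_by(.data$gene, .data$condition) |>
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop")
}

mean_of <- function(means, cond) {
  setNames(means$mean_fpkm[means$condition == cond],
           means$gene[means$condition == cond])
}

# Welch two-sided t on log2(FPKM + 1) across replicates. Degenerate
# zero-variance groups (possible at noise_sd = 0) get p = 0 when the
# group means differ and p = 1 when they coincide, the limiting values.
welch_log2 <- function(x, y) {
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  if (stats::sd(lx) < 1e-12 && stats::sd(ly) < 1e-12) {
    return(if (abs(mean(lx) - mean(ly)) < 1e-12) 1 else 0)
  }
  tryCatch(stats::t.test(lx, ly)$p.value, error = function(e) NA_real_)
}

# Moderated t (limma) on log2(FPKM + 1): with few replicates a per-gene
# variance estimate is degenerate, so variance is shrunk toward the
# transcriptome-wide value in the standard empirical-Bayes way. Falls
# back to the Welch limiting values when the whole table is noise-free.
moderated_log2 <- function(expr, genes) {
  sub <- expr[expr$condition %in% c("naive_0h", "first_12h"), ]
  wide <- tidyr::pivot_wider(
    mutate(sub, col = paste0(.data$condition, ":", .data$replicate),
           lfpkm = log2(.data$fpkm + 1)),
    id_cols = "gene", names_from = "col", values_from = "lfpkm")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$gene
  cond <- sub("^(.*):.*$", "\\1", colnames(mat))
  design <- stats::model.matrix(~ factor(cond, c("naive_0h", "first_12h")))
  fit <- limma::lmFit(mat, design)
  if (all(fit$sigma < 1e-10)) {
    diff <- abs(fit$coefficients[, 2])
    return(ifelse(diff < 1e-12, 1, 0)[genes])
  }
  fit <- limma::eBayes(fit)
  fit$p.value[genes, 2]
}

#' Call TNF-alpha-responsive genes
#'
#' A gene is responsive when its first-induction fold change exceeds
#' `fc_min` (strict `>`, pseudocount 1 on both means) with significance
#' `p < alpha` on log2(FPKM + 1) replicate values. The default test is
#' the empirical-Bayes moderated t (limma), which shares variance
#' information across genes — with two replicates per condition a purely
#' per-gene variance estimate is too unstable to clear `p < 0.01`.
#' `test = "welch"` gives the unmoderated per-gene Welch t, and
#' externally computed p-values (e.g. from a count-based differential
#' model) can be injected via `p_values`.
#'
#' @param expr Long expression tibble: `gene`, `condition`, `replicate`,
#'   `fpkm`; must contain conditions `naive_0h` and `first_12h`.
#' @param fc_min Fold-change threshold (default 2, strict).
#' @param alpha Significance level (default 0.01, strict).
#' @param pseudocount FPKM pseudocount for ratios.
#' @param test `"moderated"` (default) or `"welch"`.
#' @param p_values Optional named numeric vector of per-gene p-values
#'   overriding the built-in test.
#' @return Tibble: `gene`, `mean_naive`, `mean_first`, `fold_12h_vs_0h`,
#'   `p_value`, `responsive`.
#' @export
call_responsive <- function(expr, fc_min = 2, alpha = 0.01,
                            pseudocount = 1,
                            test = c("moderated", "welch"),
                            p_values = NULL) {
  test <- match.arg(test)
  means <- cond_means(expr, c("naive_0h", "first_12h"))
  genes <- sort(unique(expr$gene))
  m0 <- mean_of(means, "naive_0h")[genes]
  m1 <- mean_of(means, "first_12h")[genes]
  pv <- if (!is.null(p_values)) {
    unname(p_values[genes])
  } else if (test == "moderated") {
    unname(moderated_log2(expr, genes))
  } else {
    by_gene <- split(expr[expr$condition %in% c("naive_0h", "first_12h"), ],
                     expr$gene[expr$condition %in%
                                 c("naive_0h", "first_12h")])
    unname(vapply(genes, function(g) {
      d <- by_gene[[g]]
      welch_log2(d$fpkm[d$condition == "first_12h"],
                 d$fpkm[d$condition == "naive_0h"])
    }, 0))
  }
  fold <- (m1 + pseudocount) / (m0 + pseudocount)
  tibble(gene = genes,
         mean_naive = unname(m0), mean_first = unname(m1),
         fold_12h_vs_0h = unname(fold),
         p_value = pv,
         responsive = unname(fold > fc_min & !is.na(pv) & pv < alpha))
}

#' Call inflammatory transcriptional-memory genes
#'
#' Memory requires (i) responsiveness to the first induction, (ii) at
#' least `ratio_min`-fold higher expression in the second induction than
#' in the first (inclusive `>=`, pseudocount applied to both means), and
#' (iii) a mean second-induction FPKM above `fpkm_min` (strict `>`, the
#' floor is placed on the condition in which memory is asserted). The
#' recovery-baseline elevation is reported, not thresholded: genes like
#' IL32 with an elevated baseline but no stronger second induction are
#' rejected by criterion (ii).
#'
#' @param expr Long expression tibble; must contain `first_12h` and
#'   `second_12h` (and the [call_responsive()] conditions unless
#'   `responsive` is supplied).
#' @param responsive Result of [call_responsive()], or a character vector
#'   of responsive gene ids (must all appear in `expr`).
#' @param ratio_min Second/first induction ratio threshold (default 1.3,
#'   inclusive).
#' @param fpkm_min Second-induction mean FPKM floor (default 5, strict).
#' @param pseudocount FPKM pseudocount for ratios.
#' @return A tibble of class `memory_calls`, one row per gene: `gene`,
#'   `responsive`, `fold_12h_vs_0h`, `p_value`, `fold_second_vs_first`,
#'   `fpkm_second`, `baseline_fold_recovery_vs_naive`, `memory`.
#'   Thresholds are attached as attributes.
#' @examples
#' expr <- simulate_expression(sim_config(seed = 2, noise_sd = 0),
#'                             plan = default_memory_plan(50))
#' calls <- call_memory(expr)
#' dplyr::filter(calls, memory)$gene
#' @export
call_memory <- function(expr, responsive = call_responsive(expr),
                        ratio_min = 1.3, fpkm_min = 5, pseudocount = 1) {
  means <- cond_means(expr, c("first_12h", "second_12h"))
  genes <- sort(unique(expr$gene))
  if (is.character(responsive)) {
    unknown <- setdiff(responsive, genes)
    if (length(unknown) > 0) {
      abort(paste0("responsive set references unknown gene(s): ",
                   paste(head(unknown, 3), collapse = ", ")))
    }
    responsive <- tibble(gene = genes,
                         fold_12h_vs_0h = NA_real_, p_value = NA_real_,
                         responsive = genes %in% responsive)
  }
  unknown <- setdiff(responsive$gene, genes)
  if (length(unknown) > 0) {
    abort(paste0("responsive set references unknown gene(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  m1 <- mean_of(means, "first_12h")[genes]
  m2 <- mean_of(means, "second_12h")[genes]
  ratio <- (m2 + pseudocount) / (m1 + pseudocount)
  base <- baseline_elevation(expr, pseudocount = pseudocount)
  out <- tibble(gene = genes) |>
    left_join(select(responsive, "gene", "fold_12h_vs_0h", "p_value",
                     "responsive"),
              by = "gene") |>
    mutate(responsive = dplyr::coalesce(.data$responsive, FALSE),
           fold_second_vs_first = unname(ratio),
           fpkm_second = unname(m2)) |>
    left_join(base, by = "gene") |>
    mutate(memory = .data$responsive &
             .data$fold_second_vs_first >= ratio_min &
             .data$fpkm_second > fpkm_min)
  attr(out, "thresholds") <- list(ratio_min = ratio_min,
                                  fpkm_min = fpkm_min,
                                  pseudocount = pseudocount)
  class(out) <- c("memory_calls", class(out))
  out
}

#' Baseline elevation after stimulus withdrawal
#'
#' Per-gene ratio of recovery (10 days post-treatment) to naive mean
#' FPKM, pseudocounted; reported, not thresholded.
#'
#' @inheritParams call_memory
#' @return Tibble: `gene`, `baseline_fold_recovery_vs_naive`.
#' @export
baseline_elevation <- function(expr, pseudocount = 1) {
  means <- cond_means(expr, c("recovery_10d", "naive_0h"))
  genes <- sort(unique(expr$gene))
  mr <- mean_of(means, "recovery_10d")[genes]
  m0 <- mean_of(means, "naive_0h")[genes]
  tibble(gene = genes,
         baseline_fold_recovery_vs_naive =
           unname((mr + pseudocount) / (m0 + pseudocount)))
}

#' Transcriptome similarity between two conditions
#'
#' Pearson correlation of log2(mean FPKM + 1) across genes; the statistic
#' behind "naive vs memory-consolidated transcriptomes are extremely
#' similar".
#'
#' @inheritParams call_memory
#' @param cond_a,cond_b Condition labels to compare.
#' @return Scalar Pearson r.
#' @export
transcriptome_correlation <- function(expr, cond_a, cond_b) {
  means <- cond_means(expr, c(cond_a, cond_b))
  genes <- sort(unique(expr$gene))
  if (length(genes) < 3) abort("need >= 3 genes for a correlation")
  a <- log2(mean_of(means, cond_a)[genes] + 1)
  b <- log2(mean_of(means, cond_b)[genes] + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("zero variance in a condition; correlation undefined")
  }
  unname(cor(a, b))
}

#' Paired eRNA change test per peak group
#'
#' For each group of peaks, a paired two-tailed t-test on
#' log2(RPKM + 1) differences (second minus first induction), reporting
#' the effect direction. Degenerate all-equal differences give t = 0 and
#' p = 1 when centred on zero.
#'
#' @param erna Tibble: `peak_id`, `group`, `rpkm_first`, `rpkm_second`.
#' @return Tibble per group: `group`, `n`, `mean_log2_diff`, `statistic`,
#'   `df`, `p_value`, `direction`.
#' @export
erna_group_test <- function(erna) {
  stopifnot(all(c("peak_id", "group", "rpkm_first", "rpkm_second") %in%
                  names(erna)))
  pieces <- split(erna, erna$group)
  small <- names(pieces)[vapply(pieces, nrow, 0L) < 2]
  if (length(small) > 0) {
    abort(paste0("group ", small[1], " has fewer than 2 peaks"))
  }
  purrr::imap(pieces, function(gr, gname) {
    d <- log2(gr$rpkm_second + 1) - log2(gr$rpkm_first + 1)
    if (stats::sd(d) < 1e-12) {
      stat <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      p <- if (abs(mean(d)) < 1e-12) 1 else 0
      dfree <- length(d) - 1
    } else {
      tt <- stats::t.test(log2(gr$rpkm_second + 1),
                          log2(gr$rpkm_first + 1), paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
      dfree <- unname(tt$parameter)
    }
    tibble(group = gname, n = nrow(gr), mean_log2_diff = mean(d),
           statistic = stat, df = dfree, p_value = p,
           direction = if (mean(d) > 0) "up_in_second" else
             if (mean(d) < 0) "down_in_second" else "unchanged")
  }) |> bind_rows()
}

#' Fold difference in stimulus sensitivity between two doses
#'
#' The dose arithmetic behind the sensitivity claim: memory-consolidated
#' cells respond to `low` ng/mL as strongly as naive cells to `high`
#' ng/mL, i.e. a `high / low`-fold gain (125 for 50 vs 0.4 ng/mL).
#'
#' @param high,low Doses in the same units (ng/mL).
#' @return Scalar fold ratio.
#' @examples
#' dose_sensitivity_ratio(50, 0.4)  # 125
#' @export
dose_sensitivity_ratio <- function(high = 50, low = 0.4) {
  if (low <= 0 || high <= 0) abort("doses must be > 0")
  high / low
}

#' @export
tidy.memory_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "memory_calls")
  attr(out, "thresholds") <- NULL
  out
}

#' @export
glance.memory_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_genes = nrow(x),
         n_responsive = sum(x$responsive),
         n_memory = sum(x$memory),
         ratio_min = th$ratio_min,
         fpkm_min = th$fpkm_min)
}

#' @export
print.memory_calls <- function(x, ...) {
  cat(sprintf("<memory_calls> %d genes: %d responsive, %d memory\n",
              nrow(x), sum(x$responsive), sum(x$memory)))
  NextMethod()
}
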