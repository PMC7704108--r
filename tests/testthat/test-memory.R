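# Helper: build a long expression tibble from per-condition replicate
# values. `...` is gene = list(condition = c(rep values)).
expr_table <- function(...) {
  cases <- list(...)
  purrr::imap(cases, function(conds, g) {
    purrr::imap(conds, function(vals, cond) {
      tibble::tibble(gene = g, condition = cond,
                     replicate = seq_along(vals), fpkm = vals)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

flat <- function(v) list(naive_0h = v, first_12h = v, sustained_12d = v,
                         recovery_10d = v, second_12h = v)

test_that("responsiveness needs both the fold and the significance gate", {
  e <- expr_table(
    g_flat = flat(c(10, 10)),
    g_up = list(naive_0h = c(10, 10), first_12h = c(30, 30),
                sustained_12d = c(30, 30), recovery_10d = c(10, 10),
                second_12h = c(30, 30)))
  r <- call_responsive(e, test = "welch")
  expect_false(r$responsive[r$gene == "g_flat"])
  expect_equal(r$p_value[r$gene == "g_flat"], 1)
  # zero noise, 10 -> 30: pseudocounted fold 31/11, limiting p = 0
  up <- r[r$gene == "g_up", ]
  expect_equal(up$fold_12h_vs_0h, 31 / 11)
  expect_equal(up$p_value, 0)
  expect_true(up$responsive)
})

test_that("welch p-values match the closed-form t on log2(FPKM + 1)", {
  x0 <- c(9, 10, 11)
  x1 <- c(28, 30, 32)
  e <- expr_table(g = list(naive_0h = x0, first_12h = x1,
                           sustained_12d = x1, recovery_10d = x0,
                           second_12h = x1))
  r <- call_responsive(e, test = "welch")
  l0 <- log2(x0 + 1); l1 <- log2(x1 + 1)
  se <- sqrt(var(l0) / 3 + var(l1) / 3)
  tt <- (mean(l1) - mean(l0)) / se
  df <- se^4 / ((var(l0) / 3)^2 / 2 + (var(l1) / 3)^2 / 2)
  expect_equal(r$p_value, 2 * pt(-abs(tt), df))
})

test_that("a fold of exactly 2 is not responsive (strict threshold)", {
  # pseudocounted fold (2a + 2) / (a + 1) = 2 exactly
  e <- expr_table(g = list(naive_0h = c(10, 10), first_12h = c(21, 21),
                           sustained_12d = c(21, 21),
                           recovery_10d = c(10, 10),
                           second_12h = c(21, 21)))
  r <- call_responsive(e, p_values = c(g = 1e-9))
  expect_equal(r$fold_12h_vs_0h, 2)
  expect_false(r$responsive)
})

test_that("missing conditions are reported by name", {
  e <- expr_table(g = list(naive_0h = c(1, 1)))
  expect_error(call_responsive(e), "first_12h")
  expect_error(call_memory(expr_table(g = list(first_12h = c(1, 1))),
                           responsive = "g"),
               "second_12h")
})

test_that("memory requires responsiveness, the 1.3-fold gate (inclusive) and the FPKM floor", {
  mk <- function(first, second, naive = 1) {
    list(naive_0h = rep(naive, 2), first_12h = rep(first, 2),
         sustained_12d = rep(first, 2), recovery_10d = rep(naive, 2),
         second_12h = rep(second, 2))
  }
  # pseudocounted second/first ratio exactly 1.3: (14.3+1)/(10.78...)
  first <- 10
  second <- 1.3 * first + 0.3   # (second + 1) / (first + 1) = 1.3
  e <- expr_table(boundary = mk(first, second),
                  il32 = mk(80, 80, naive = 5),
                  silent_jump = mk(1, 50),
                  weak = mk(3, 300))
  e$fpkm[e$gene == "il32" & e$condition == "recovery_10d"] <- 25
  calls <- call_memory(e, responsive = c("boundary", "il32", "weak"))
  get <- function(g, col) calls[[col]][calls$gene == g]
  expect_equal(get("boundary", "fold_second_vs_first"), 1.3)
  expect_true(get("boundary", "memory"))          # inclusive >=
  # IL32-like: elevated recovery baseline but no stronger second induction
  expect_gt(get("il32", "baseline_fold_recovery_vs_naive"), 4)
  expect_false(get("il32", "memory"))
  # not responsive -> never memory, however large the second induction
  expect_false(get("silent_jump", "memory"))
  # responsive with ratio pass but second mean far above the FPKM floor
  expect_true(get("weak", "memory"))
  # FPKM floor is strict: mean second exactly 5 fails
  e2 <- expr_table(atfloor = mk(2, 5))
  c2 <- call_memory(e2, responsive = "atfloor")
  expect_false(c2$memory[c2$gene == "atfloor"])
})

test_that("raising thresholds never adds memory genes", {
  expr <- simulate_expression(sim_config(seed = 8),
                              plan = default_memory_plan(100))
  resp <- call_responsive(expr)
  base <- call_memory(expr, resp)
  for (rm in c(1.3, 1.6, 2, 3)) {
    for (fm in c(5, 20, 100)) {
      m <- call_memory(expr, resp, ratio_min = rm, fpkm_min = fm)
      expect_true(all(m$gene[m$memory] %in% base$gene[base$memory]))
    }
  }
})

test_that("classifier recovers the planted design with precision and recall 1", {
  for (s in c(2, 17)) {
    expr <- simulate_expression(sim_config(seed = s))
    plan <- attr(expr, "plan")
    calls <- call_memory(expr)
    expect_setequal(calls$gene[calls$memory],
                    plan$gene[plan$role == "memory"])
  }
})

test_that("unknown genes in the responsive set are rejected", {
  e <- expr_table(g = flat(c(1, 1)))
  expect_error(call_memory(e, responsive = "nope"), "unknown gene")
})

test_that("pseudocounts keep all-zero genes well defined", {
  e <- expr_table(zero = flat(c(0, 0)), other = flat(c(5, 5)))
  r <- call_responsive(e, test = "welch")
  expect_equal(r$fold_12h_vs_0h[r$gene == "zero"], 1)
  b <- baseline_elevation(e)
  expect_equal(b$baseline_fold_recovery_vs_naive[b$gene == "zero"], 1)
  calls <- call_memory(e, responsive = character(0))
  expect_false(any(calls$memory))
})

test_that("baseline elevation is the pseudocounted recovery/naive ratio", {
  e <- expr_table(g = list(naive_0h = c(2, 2), recovery_10d = c(10, 10),
                           first_12h = c(2, 2), second_12h = c(2, 2),
                           sustained_12d = c(2, 2)))
  b <- baseline_elevation(e)
  expect_equal(b$baseline_fold_recovery_vs_naive, 11 / 3)
})

test_that("fold-change calls are invariant to a common scale factor", {
  expr <- simulate_expression(sim_config(seed = 31),
                              plan = default_memory_plan(50))
  resp <- call_responsive(expr)
  scaled <- dplyr::mutate(expr, fpkm = fpkm * 1000)
  resp_s <- call_responsive(scaled, pseudocount = 1000)
  expect_equal(resp_s$responsive, resp$responsive)
})

test_that("transcriptome correlation matches hand-computed Pearson", {
  v <- c(3, 10, 40, 100, 7)
  w <- c(2, 12, 35, 90, 9)
  e <- expr_table(
    g1 = list(naive_0h = v[1], recovery_10d = w[1]),
    g2 = list(naive_0h = v[2], recovery_10d = w[2]),
    g3 = list(naive_0h = v[3], recovery_10d = w[3]),
    g4 = list(naive_0h = v[4], recovery_10d = w[4]),
    g5 = list(naive_0h = v[5], recovery_10d = w[5]))
  r <- transcriptome_correlation(e, "naive_0h", "recovery_10d")
  lv <- log2(v + 1); lw <- log2(w + 1)
  expect_equal(r, sum((lv - mean(lv)) * (lw - mean(lw))) /
                 sqrt(sum((lv - mean(lv))^2) * sum((lw - mean(lw))^2)))
  expect_equal(transcriptome_correlation(e, "naive_0h", "naive_0h"), 1)
  # exact anti-ordering on the log scale gives r = -1
  a <- c(1, 3, 7)   # log2(a + 1) = 1, 2, 3
  e2 <- expr_table(g1 = list(naive_0h = a[1], recovery_10d = a[3]),
                   g2 = list(naive_0h = a[2], recovery_10d = a[2]),
                   g3 = list(naive_0h = a[3], recovery_10d = a[1]))
  expect_equal(transcriptome_correlation(e2, "naive_0h", "recovery_10d"),
               -1)
  e3 <- expr_table(g1 = list(naive_0h = 1, recovery_10d = 1),
                   g2 = list(naive_0h = 1, recovery_10d = 2),
                   g3 = list(naive_0h = 1, recovery_10d = 3))
  expect_error(transcriptome_correlation(e3, "naive_0h", "recovery_10d"),
               "zero variance")
})

test_that("paired eRNA test matches the closed-form paired t", {
  base <- c(4, 6, 9, 14, 20)
  noise <- c(0.05, -0.1, 0.2, -0.05, 0.1)
  er <- tibble::tibble(
    peak_id = paste0("p", 1:5), group = "topQ",
    rpkm_first = base,
    rpkm_second = (base + 1) * 2^(1 + noise) - 1)  # log2 diff = 1 + noise
  res <- erna_group_test(er)
  d <- 1 + noise
  tt <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, tt, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(tt), 4), tolerance = 1e-10)
  expect_equal(res$direction, "up_in_second")
  # permuting peak order leaves the statistic unchanged
  res_perm <- erna_group_test(er[sample.int(5), ])
  expect_equal(res_perm$statistic, res$statistic)
  # all differences zero: t = 0, p = 1
  flat <- tibble::tibble(peak_id = paste0("p", 1:4), group = "rest",
                         rpkm_first = 1:4, rpkm_second = 1:4)
  res0 <- erna_group_test(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(erna_group_test(flat[1, ]), "fewer than 2")
})

test_that("the dose arithmetic gives the 125-fold sensitivity gain", {
  expect_equal(dose_sensitivity_ratio(50, 0.4), 125)
  expect_error(dose_sensitivity_ratio(50, 0), "> 0")
})

test_that("memory_calls supports tidy, glance and autoplot", {
  expr <- simulate_expression(sim_config(seed = 3),
                              plan = default_memory_plan(30))
  calls <- call_memory(expr)
  td <- tidy(calls)
  expect_false(inherits(td, "memory_calls"))
  gl <- glance(calls)
  expect_equal(gl$n_memory, sum(calls$memory))
  expect_equal(gl$ratio_min, 1.3)
  expect_s3_class(autoplot(calls), "ggplot")
})
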