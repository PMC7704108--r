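test_that("bisulfite clone simulation obeys its forcing probabilities", {
  loc <- simulate_locus_reference(n_cpg = 5, length_bp = 80)
  cfg <- sim_config(seed = 3, conversion_efficiency = 1,
                    sequencing_error_rate = 0)
  all_meth <- simulate_bisulfite_clones(loc, 1.0, 10, cfg)
  expect_equal(quantify_clone_sim(all_meth)$level, 1.0)
  all_unmeth <- simulate_bisulfite_clones(loc, 0.0, 10, cfg)
  expect_equal(quantify_clone_sim(all_unmeth)$level, 0.0)
  # with full conversion and no errors, non-CpG Cs are all T
  chars <- strsplit(all_meth$sequences[[1]], "")[[1]]
  ref <- strsplit(loc$reference, "")[[1]]
  non_cpg_c <- setdiff(which(ref == "C"), loc$cpg_pos + 1)
  expect_true(all(chars[non_cpg_c] == "T"))
})

test_that("per-CpG probability vector must match the CpG count", {
  loc <- simulate_locus_reference(n_cpg = 4, length_bp = 60)
  err <- expect_error(
    simulate_bisulfite_clones(loc, c(0.5, 0.5), 5, sim_config()),
    "length 2")
  expect_match(conditionMessage(err), "4 CpGs")
})

test_that("identical configs give bit-identical simulations", {
  cfg <- sim_config(seed = 11)
  loc <- simulate_locus_reference(6, 100)
  expect_identical(simulate_bisulfite_clones(loc, 0.5, 20, cfg),
                   simulate_bisulfite_clones(loc, 0.5, 20, cfg))
  expect_identical(simulate_toy_genome(cfg), simulate_toy_genome(cfg))
  g <- simulate_toy_genome(cfg)
  expect_identical(simulate_methylation_dynamics(g, cfg),
                   simulate_methylation_dynamics(g, cfg))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
})

test_that("clone estimator is calibrated to the binomial sampling CI", {
  # coverage of the 95% CI over 100 seeded replicates; the assertion
  # allows the 2-sigma estimation error of a rate estimated from 100
  # draws (0.95 - 2 * sqrt(0.95 * 0.05 / 100) ~= 0.906)
  loc <- simulate_locus_reference(17, 400)
  p <- 0.85
  n_calls <- 200 * 17
  ci <- 1.96 * sqrt(p * (1 - p) / n_calls)
  hits <- vapply(1:100, function(s) {
    est <- quantify_clone_sim(
      simulate_bisulfite_clones(loc, p, 200, sim_config(seed = s)))$level
    abs(est - p) <= ci
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("toy genome satisfies its structural invariants", {
  cfg <- sim_config(seed = 5, n_peaks = 10, n_genes = 9)
  g <- simulate_toy_genome(cfg)
  expect_true(all(g$peaks$start >= 0 & g$peaks$end <= g$length))
  # every peak embeds the kappaB consensus, verified on the emitted seq
  for (i in seq_len(nrow(g$peaks))) {
    pseq <- substr(g$sequence, g$peaks$start[i] + 1, g$peaks$end[i])
    expect_true(grepl("GGGACTTTCC", pseq, fixed = TRUE))
  }
  # CpG positions strictly increasing within each peak
  by_peak <- split(g$cpgs$pos, g$cpgs$peak_id)
  expect_true(all(vapply(by_peak, function(p) {
    length(p) < 2 || all(diff(p) > 0)
  }, TRUE)))
  # high-density peaks have >= 10 CpGs within +-250 bp of the motif,
  # recounted independently by scanning the emitted sequence
  high <- g$peaks[g$peaks$cpg_class == "high", ]
  for (i in seq_len(nrow(high))) {
    center <- high$motif_start[i] + 5
    win <- substr(g$sequence, center - 250 + 1, center + 250 + 2)
    n_cg <- lengths(regmatches(win, gregexpr("CG", win)))
    expect_gte(n_cg, 10)
  }
  # TSS distances to nearest motif center span the three strata
  centers <- g$peaks$motif_start + 5
  d <- vapply(g$genes$tss, function(t) min(abs(t - centers)), 0)
  expect_true(any(d < 1e4) && any(d >= 1e4 & d <= 1e5) && any(d > 1e5))
})

test_that("a genome too short for the requested features errors", {
  expect_error(simulate_toy_genome(sim_config(genome_length = 50000,
                                              n_peaks = 40)),
               "too short")
})

test_that("methylation dynamics follow the exponential demethylation law", {
  # CpG exactly at the motif center loses delta; one at lambda bp loses
  # delta / e (checked at high coverage so count noise is negligible)
  cfg <- sim_config(seed = 7, coverage = 200000, demethylation_scale = 0.4,
                    decay_length = 300)
  g <- mini_genome(cpg_pos = c(1005, 1305), p0 = c(0.9, 0.9))
  m <- simulate_methylation_dynamics(g, cfg)
  drop <- m$t0$true_level - m$t12$true_level
  expect_equal(drop[1], 0.4, tolerance = 1e-12)
  expect_equal(drop[1] / drop[2], exp(1), tolerance = 1e-12)
  obs_drop <- m$t0$level - m$t12$level
  expect_equal(obs_drop[1] / obs_drop[2], exp(1), tolerance = 0.02)
  expect_true(all(m$t12$level >= 0 & m$t12$level <= 1))
})

test_that("RELA-KO dynamics stay at the noise floor", {
  cfg <- sim_config(seed = 9, genotype = "RELA_KO")
  g <- simulate_toy_genome(cfg)
  m <- simulate_methylation_dynamics(g, cfg)
  expect_lte(abs(mean(m$t0$true_level - m$t12$true_level)), 0.05)
})

test_that("genotypes order mean demethylation as WT >= TET2_KO >= RELA_KO ~ TET_TKO ~ 0", {
  drops <- vapply(c("WT", "TET2_KO", "RELA_KO", "TET_TKO"), function(gt) {
    cfg <- sim_config(seed = 13, genotype = gt)
    g <- simulate_toy_genome(cfg)
    m <- simulate_methylation_dynamics(g, cfg)
    meth <- m$t0$true_level >= 0.5
    mean(m$t0$level[meth] - m$t12$level[meth])
  }, 0)
  expect_gte(drops[["WT"]], drops[["TET2_KO"]])
  expect_gte(drops[["TET2_KO"]], drops[["RELA_KO"]])
  expect_lte(abs(drops[["RELA_KO"]] - drops[["TET_TKO"]]), 0.05)
  expect_lte(abs(drops[["RELA_KO"]]), 0.05)
  expect_gt(drops[["WT"]], 0.1)
})

test_that("occupancy follows exp(-beta * M) exactly at zero noise", {
  cfg <- sim_config(seed = 2, noise_sd = 0, occupancy_decay = log(2) / 2,
                    coverage = 100)
  # two peaks with exact M = 0 and M = 2 (levels encoded in counts)
  g <- mini_genome(cpg_pos = c(1003, 1008), p0 = c(1, 1))
  g$peaks <- dplyr::bind_rows(
    g$peaks,
    dplyr::mutate(g$peaks, peak_id = "pk2", start = 1600L, end = 1900L,
                  motif_start = 1700L))
  meth <- meth_table(c(1003, 1008), c(1, 1))
  occ <- simulate_occupancy(g, meth, cfg, amplitude = 50)
  pk1 <- occ$peaks[occ$peaks$peak_id == "pk1", ]
  pk2 <- occ$peaks[occ$peaks$peak_id == "pk2", ]
  expect_equal(pk2$M, 0)
  expect_equal(pk2$summit_signal, 50)           # M = 0 -> full amplitude
  expect_equal(pk1$M, 2)
  expect_equal(pk2$summit_signal / pk1$summit_signal, 2)  # beta = ln2/2
})

test_that("occupancy grouped by total-methylation quintiles is monotone", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s)
    g <- simulate_toy_genome(cfg)
    m <- simulate_methylation_dynamics(g, cfg)
    occ <- simulate_occupancy(g, m$t0, cfg)
    q <- dplyr::ntile(occ$peaks$M, 5)
    means <- tapply(occ$peaks$summit_signal, q, mean)
    expect_true(all(diff(means) <= 1e-9))
  }
})

test_that("expression equals planted means at zero noise", {
  cfg <- sim_config(seed = 4, noise_sd = 0)
  plan <- default_memory_plan(n_background = 10)
  expr <- simulate_expression(cfg, plan)
  calcb <- expr[expr$gene == "CALCB_like", ]
  expect_equal(calcb$fpkm[calcb$condition == "sustained_12d"],
               rep(699, cfg$n_replicates))
  expect_equal(nrow(expr), nrow(plan) * 5 * cfg$n_replicates)
})

test_that("expression plan is validated", {
  bad <- default_memory_plan(5)
  bad$role[1] <- "hero"
  expect_error(simulate_expression(sim_config(), bad), "unknown role")
  dup <- default_memory_plan(5)
  dup$gene[2] <- dup$gene[1]
  expect_error(simulate_expression(sim_config(), dup), "twice")
})

test_that("simulated study writes all external formats and round-trips", {
  cfg <- sim_config(seed = 6, n_peaks = 4, n_genes = 4,
                    genome_length = 4e5)
  sim <- simulate_study(cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_simulation(sim, dir1)
  expect_true(all(file.exists(paths)))
  # methylation round-trip preserves counts and 0-based positions
  m <- read_bismark_cov(paths["meth_t0"])
  expect_equal(m$pos, sim$meth$t0$pos)
  expect_equal(m$count_meth, sim$meth$t0$count_meth)
  expect_equal(m$level, sim$meth$t0$level)
  # expression round-trip
  e <- read_expression(paths["expression"])
  expect_equal(e$fpkm, sim$expression$fpkm)
  # genome FASTA round-trip
  fa <- read_fasta(paths["genome"])
  expect_identical(unname(fa), sim$genome$sequence)
  # byte-reproducible given the same config
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
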