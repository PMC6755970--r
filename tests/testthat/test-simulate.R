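test_that("zero-effect zero-noise screens are exactly the baseline", {
  cfg <- screen_sim_config(n_probes = 160, n_plates = 2, n_cell_lines = 1,
                           row_effect_sd = 0, col_effect_sd = 0,
                           noise_sd = 0, hit_fraction = 0, rng_seed = 1)
  sim <- simulate_screen(cfg)
  for (p in sim$plates) {
    lib <- p$roles == "library"
    expect_equal(log2(p$values[lib]), rep(cfg$baseline_log2_rlu, sum(lib)))
    # death controls sit at baseline + the fixed negative effect
    dc <- p$roles == "death_control"
    expect_equal(log2(p$values[dc]),
                 rep(cfg$baseline_log2_rlu + cfg$death_effect_log2, sum(dc)))
  }
  expect_true(all(!sim$truth$is_hit))
})

test_that("simulation is bitwise reproducible under a seed", {
  cfg <- screen_sim_config(n_probes = 300, n_plates = 4, rng_seed = 1)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  cfg2 <- screen_sim_config(n_probes = 300, n_plates = 4, rng_seed = 2)
  expect_false(identical(simulate_screen(cfg2), a))
})

test_that("layout capacity and config invariants are enforced", {
  expect_error(screen_sim_config(n_probes = 1100, n_plates = 13),
               "capacity")
  expect_error(screen_sim_config(hit_fraction = 1.2))
  expect_error(screen_sim_config(noise_sd = -1))
  layout <- default_plate_layout()
  expect_equal(sum(layout == "library"), 80L)
  expect_equal(sum(layout == "negative_control"), 8L)
  expect_equal(sum(layout == "death_control"), 4L)
})

test_that("noiseless positional effects are recovered by the polish", {
  # additive row/column artifacts with no noise: median polish recovers
  # them exactly (median-centred) and leaves zero residuals
  cfg <- screen_sim_config(n_probes = 80, n_plates = 1, n_cell_lines = 1,
                           row_effect_sd = 0.5, col_effect_sd = 0.5,
                           noise_sd = 0, hit_fraction = 0, rng_seed = 5)
  sim <- simulate_screen(cfg)
  p <- sim$plates[[1]]
  y <- log2(p$values)
  y[p$roles != "library"] <- NA
  keep_col <- colSums(!is.na(y)) > 0
  fit <- median_polish(y[, keep_col], max_iter = 50, tol = 1e-12)
  expect_lt(max(abs(fit$residuals), na.rm = TRUE), 1e-9)
  expect_lt(abs(stats::median(fit$row_effects)), 1e-9)
  expect_lt(abs(stats::median(fit$col_effects)), 1e-9)
})

test_that("planted screen hits are recovered with high sensitivity", {
  # 20 planted hits at 8x the noise SD; sensitivity across 10 screens
  hits_found <- 0; hits_total <- 0
  for (s in 1:10) {
    cfg <- screen_sim_config(hit_fraction = 20 / 983,
                             hit_effect_log2 = 8 * 0.25, noise_sd = 0.25,
                             rng_seed = s)
    sim <- simulate_screen(cfg)
    res <- screen_bscore(sim$plates)
    true_hits <- unique(sim$truth$probe_id[sim$truth$is_hit])
    called <- res$hits$probe_id[res$hits$is_hit_any_line]
    hits_found <- hits_found + sum(true_hits %in% called)
    hits_total <- hits_total + length(true_hits)
  }
  expect_gte(hits_found / hits_total, 0.95)
})

test_that("hit recovery is at least that of a direct z-threshold oracle", {
  # small screens, effect 3x noise SD: B-score recovery must not fall
  # more than 5 percentage points below the oracle's recovery
  set.seed(36)
  noise_sd <- 0.25
  rec_b <- c(); rec_z <- c()
  for (s in 1:200) {
    cfg <- screen_sim_config(n_probes = 160, n_plates = 2,
                             n_cell_lines = 1, hit_fraction = 8 / 160,
                             hit_effect_log2 = 3 * noise_sd,
                             noise_sd = noise_sd, rng_seed = 5000 + s)
    sim <- simulate_screen(cfg)
    truth <- sim$truth[sim$truth$is_hit, ]
    res <- screen_bscore(sim$plates)
    called <- res$hits$probe_id[res$hits$is_hit_any_line]
    rec_b <- c(rec_b, mean(truth$probe_id %in% called))
    # oracle: same generative draw, direct z-thresholding of the planted
    # effect plus well noise at |z| >= 6
    z <- (truth$effect_log2 + stats::rnorm(nrow(truth), 0, noise_sd)) /
      noise_sd
    rec_z <- c(rec_z, mean(abs(z) >= 6))
  }
  expect_gte(mean(rec_b), mean(rec_z) - 0.05)
})

test_that("UTR simulation round-trips through the scanner", {
  mir <- mature_mir("m1", "UAGCUUAUCAGACUGAUGUUGA")  # 22-nt guide
  cfg <- utr_sim_config(length = 100, planted_sites = data.frame(
    mir_name = "m1", site_type = "6mer", start = 41L), rng_seed = 3)
  sim <- simulate_utr(cfg, list(mir))
  found <- find_seed_sites(mir, sim$utr)
  expect_equal(nrow(found), 1L)
  expect_equal(found$start, 41L)
  expect_equal(found$site_type, "6mer")

  # zero planted sites: scanner finds nothing
  empty <- simulate_utr(utr_sim_config(length = 300, rng_seed = 4),
                        list(mir))
  expect_equal(nrow(find_seed_sites(mir, empty$utr)), 0L)
  expect_equal(nrow(empty$truth), 0L)

  # seed reproducibility
  expect_identical(simulate_utr(cfg, list(mir))$utr$sequence,
                   sim$utr$sequence)

  # invalid plantings are rejected
  expect_error(utr_sim_config(length = 40, planted_sites = data.frame(
    mir_name = "m1", site_type = "8mer", start = 38L)), "out of range")
  expect_error(utr_sim_config(length = 100, planted_sites = data.frame(
    mir_name = c("m1", "m1"), site_type = c("8mer", "6mer"),
    start = c(20L, 25L))), "overlap")
})

test_that("random UTR configs equal the brute-force oracle (planted-site completeness)", {
  set.seed(37)
  for (rep in 1:50) {
    mirs <- lapply(1:2, function(i) mature_mir(paste0("m", i),
                                               random_mir_seq()))
    n_sites <- sample(0:3, 1)
    starts <- sort(sample(seq(10, 160, by = 15), n_sites))
    ps <- data.frame(
      mir_name = sample(c("m1", "m2"), n_sites, replace = TRUE),
      site_type = sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"),
                         n_sites, replace = TRUE),
      start = starts, stringsAsFactors = FALSE)
    cfg <- utr_sim_config(length = 200, planted_sites = ps,
                          rng_seed = rep)
    sim <- simulate_utr(cfg, mirs)
    for (m in mirs) {
      got <- find_seed_sites(m, sim$utr)
      exp <- oracle_scan(m$sequence, sim$utr$sequence)
      expect_equal(got[c("start", "end", "site_type")], exp,
                   ignore_attr = TRUE)
      tr <- sim$truth[sim$truth$mir_name == m$name, ]
      expect_equal(got[c("start", "end", "site_type")],
                   tr[c("start", "end", "site_type")], ignore_attr = TRUE)
    }
  }
})

test_that("qPCR simulation inverts exactly at zero noise", {
  cfg <- qpcr_sim_config(
    genes = c("PSA", "TMPRSS2"), samples = c("mock", "inhibitor"),
    true_fold = data.frame(gene = c("PSA", "TMPRSS2"),
                           sample = "inhibitor", fold = c(2, 0.25)),
    ct_noise_sd = 0, rng_seed = 1)
  ct <- simulate_qpcr(cfg)
  rel <- delta_delta_ct(ct, reference_genes = c("U18", "L19"),
                        calibrator_sample = "mock")
  expect_equal(rel$fold[rel$sample == "mock"], c(1, 1))
  expect_equal(rel$fold[rel$sample == "inhibitor" & rel$gene == "PSA"], 2)
  expect_equal(rel$fold[rel$sample == "inhibitor" &
                          rel$gene == "TMPRSS2"], 0.25)

  # all folds 1: every recovered fold is 1
  cfg1 <- qpcr_sim_config(genes = "G", samples = c("a", "b", "c"),
                          ct_noise_sd = 0, rng_seed = 2)
  rel1 <- delta_delta_ct(simulate_qpcr(cfg1), c("U18", "L19"), "a")
  expect_equal(rel1$fold, rep(1, 3))
})

test_that("noisy qPCR fold recovery matches the log-normal Monte-Carlo oracle", {
  sigma <- 0.2
  n_rep <- 1000
  folds <- vapply(seq_len(n_rep), function(i) {
    cfg <- qpcr_sim_config(genes = "G", samples = c("cal", "s"),
                           true_fold = data.frame(gene = "G", sample = "s",
                                                  fold = 4),
                           ct_noise_sd = sigma, rng_seed = 10000 + i)
    rel <- delta_delta_ct(simulate_qpcr(cfg), c("U18", "L19"), "cal")
    rel$fold[rel$sample == "s"]
  }, numeric(1))
  # ddCt for one target with two references: noise variance
  # 2 * (1 + 1/2) * sigma^2 = 3 sigma^2; the mean recovered fold carries
  # the log-normal bias E[2^-e] = exp((ln2 * )^2 * 3 sigma^2 / 2)
  set.seed(38)
  mc <- 4 * 2^(-stats::rnorm(2e5, 0, sqrt(3) * sigma))
  closed_form <- 4 * exp((log(2)^2) * 3 * sigma^2 / 2)
  expect_lt(abs(mean(folds) - mean(mc)), 0.05)
  expect_lt(abs(mean(folds) - closed_form), 0.05)
})
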