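test_that("dispersion estimation recovers the simulated value", {
  cfg <- sim_config(n_genes = 2000, module_sizes = c(shared_up = 0), effect = 0,
                    de_noise_frac = 0, dispersion = 0.1, dispersion_sdlog = 0.3,
                    seed = 7)
  sim <- simulate_experiment(cfg)
  fcm <- filter_low_expression(sim$counts)
  disp <- estimate_dispersions(fcm, sim$design, tmm_normalize(fcm))
  expect_gt(median(disp$tagwise), 0.05)
  expect_lt(median(disp$tagwise), 0.2)
  expect_true(all(disp$tagwise >= 1e-6))
  expect_equal(disp$shrink_weight, 10 / 22) # prior_df 10, residual df 12
})

test_that("dispersions collapse toward zero in the Poisson limit", {
  cfg <- sim_config(n_genes = 1500, module_sizes = c(shared_up = 0), effect = 0,
                    de_noise_frac = 0, dispersion = 1e-4, dispersion_sdlog = 0,
                    seed = 13)
  sim <- simulate_experiment(cfg)
  fcm <- filter_low_expression(sim$counts)
  disp <- estimate_dispersions(fcm, sim$design, tmm_normalize(fcm))
  expect_lte(median(disp$tagwise), 0.02)
})

test_that("constant counts within every cell hit the dispersion floor", {
  m <- matrix(rep(c(10, 20, 30, 40, 50, 60), each = 3), 1, 18, byrow = TRUE)
  m <- rbind(m, m * 2)
  dimnames(m) <- list(c("g1", "g2"), std_design()$sample_id)
  cm <- count_matrix(m)
  nf <- stats::setNames(rep(1, 18), cm$sample_ids)
  # library sizes are constant within each cell, so adjusted counts stay
  # constant within cells and the within-cell residuals vanish
  disp <- estimate_dispersions(cm, std_design(), nf)
  expect_equal(unname(disp$genewise), rep(1e-6, 2))
})

test_that("NB GLM testing matches an independent glm-based oracle", {
  skip_if_not_installed("MASS")
  sim <- simulate_experiment(sim_config(
    n_genes = 60, module_sizes = c(shared_up = 10), within_module_cor = 0.3,
    effect = 1.5, de_noise_frac = 0.2, seed = 21))
  fcm <- filter_low_expression(sim$counts)
  nf <- tmm_normalize(fcm)
  design <- sim$design
  disp <- estimate_dispersions(fcm, design, nf)
  contrast <- standard_contrasts()$interaction_day7
  de <- fit_and_test(fcm, nf, design, disp, contrast)

  grp <- factor(paste(design$population, design$infestation, sep = "."),
                levels = design_cells())
  off <- log(fcm$lib_sizes * as.numeric(nf))
  X <- model.matrix(~ 0 + grp)
  Z <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)[, -1]
  for (i in seq_len(20)) {
    y <- fcm$counts[i, ]
    if (all(y == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / disp$tagwise[i])
    full <- suppressWarnings(glm.fit(X, y, family = fam, offset = off))
    red <- suppressWarnings(glm.fit(X %*% Z, y, family = fam, offset = off))
    lfc <- sum(contrast * full$coefficients) / log(2)
    lrt <- red$deviance - full$deviance # equal-dispersion models: dev diff = 2*LLR
    p <- pchisq(max(0, lrt), 1, lower.tail = FALSE)
    expect_equal(de$log2FC[i], lfc, tolerance = 1e-4)
    expect_equal(de$p_raw[i], p, tolerance = 1e-4)
  }
})

test_that("degenerate genes and label symmetry behave as specified", {
  sim <- simulate_experiment(fixture_config(seed = 30, n_genes = 60))
  cm <- sim$counts
  cm$counts["g00001", ] <- 0
  cm <- count_matrix(cm$counts)
  design <- sim$design
  nf <- tmm_normalize(cm)
  disp <- estimate_dispersions(cm, design, nf)
  pop_contrast <- c(1, 1, 1, -1, -1, -1) / 3
  de <- fit_and_test(cm, nf, design, disp, pop_contrast)
  row0 <- de[de$gene_id == "g00001", ]
  expect_identical(row0$log2FC, 0)
  expect_identical(row0$p_raw, 1)

  swapped <- design
  swapped$population <- factor(
    ifelse(design$population == "kauai", "mangaia", "kauai"),
    levels = levels(design$population))
  de_sw <- fit_and_test(cm, nf, swapped, disp, pop_contrast)
  expect_equal(de_sw$log2FC, -de$log2FC, tolerance = 1e-6)
})

test_that("planted day-7 effects are detected with high power", {
  sim <- simulate_experiment(sim_config(
    n_genes = 1000, module_sizes = c(shared_up = 200), within_module_cor = 0.3,
    effect = 2, dispersion = 0.05, de_noise_frac = 0, seed = 11))
  fcm <- filter_low_expression(sim$counts)
  nf <- tmm_normalize(fcm)
  disp <- estimate_dispersions(fcm, sim$design, nf)
  de <- fit_and_test(fcm, nf, sim$design, disp, "kauai_day7_vs_control")
  planted <- de$gene_id %in% sim$modules$M1$gene_ids
  expect_gte(mean(de$p_adj[planted] < 0.05, na.rm = TRUE), 0.80)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  for (rep_ in 1:10) {
    p <- runif(50)
    p[sample(50, 5)] <- NA
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p, na.rm = TRUE))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("venn partition counts and direction agreement are exact", {
  mk <- function(sig, lfc) {
    data.frame(gene_id = sprintf("g%d", seq_along(sig)), log2FC = lfc,
               p_raw = ifelse(sig, 1e-6, 0.9), p_adj = ifelse(sig, 1e-5, 0.95))
  }
  a_sig <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b_sig <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  v <- venn_partition(mk(a_sig, c(1, -1, 2, 1, 1)), mk(b_sig, c(1, 1, 2, 1, 1)))
  expect_identical(v$unique_A, 1L)
  expect_identical(v$unique_B, 1L)
  expect_identical(v$shared, 2L)
  expect_equal(v$same_direction_pct, 50.0)
  # disjoint significant sets
  v0 <- venn_partition(mk(c(TRUE, FALSE), c(1, 1)), mk(c(FALSE, TRUE), c(1, 1)))
  expect_identical(v0$shared, 0L)
  expect_true(is.na(v0$same_direction_pct))
  # identical results
  vi <- venn_partition(mk(a_sig, c(1, -1, 2, 1, 1)), mk(a_sig, c(1, -1, 2, 1, 1)))
  expect_identical(vi$unique_A + vi$unique_B, 0L)
  expect_equal(vi$same_direction_pct, 100.0)
})

test_that("type-I error is calibrated on null data", {
  cfg <- sim_config(n_genes = 2000, module_sizes = c(shared_up = 0), effect = 0,
                    de_noise_frac = 0, dispersion = 0.1, seed = 7)
  sim <- simulate_experiment(cfg)
  fcm <- filter_low_expression(sim$counts)
  nf <- tmm_normalize(fcm)
  disp <- estimate_dispersions(fcm, sim$design, nf)
  de <- fit_and_test(fcm, nf, sim$design, disp, "interaction_day7")
  rate <- mean(de$p_raw < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})
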