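test_that("overlap matching is inclusive at the 10% boundary and splits matches", {
  genes <- sprintf("g%03d", 1:130)
  orig <- setNames(c(rep("O1", 100), rep("O2", 20), rep("unassigned", 10)), genes)
  # resampled module R1 shares exactly 10 of O1's 100 genes
  res <- setNames(rep("unassigned", 130), genes)
  res[1:10] <- "R1"
  sup <- match_modules(make_assignment(orig), make_assignment(res))
  expect_true(all(sup[1:10]))
  expect_false(any(sup[11:130]))
  # 9 of 100 is below the threshold
  res9 <- setNames(rep("unassigned", 130), genes)
  res9[1:9] <- "R1"
  expect_false(any(match_modules(make_assignment(orig), make_assignment(res9))))
  # one resampled module overlapping two original modules at >= 10% each:
  # genes divide by their original labels, both sets supported
  res2 <- setNames(rep("unassigned", 130), genes)
  res2[c(1:15, 101:105)] <- "R1" # 15/100 of O1 and 5/20 of O2
  sup2 <- match_modules(make_assignment(orig), make_assignment(res2))
  expect_true(all(sup2[c(1:15, 101:105)]))
  expect_false(any(sup2[c(16:100, 106:130)]))
  # the unassigned label never matches, however large the overlap
  resU <- setNames(rep("unassigned", 130), genes)
  supU <- match_modules(make_assignment(orig), make_assignment(resU))
  expect_false(any(supU))
})

test_that("reliability filtering is inclusive at 70% and counts replicates", {
  genes <- sprintf("g%02d", 1:40)
  orig <- setNames(c(rep("O1", 30), rep("unassigned", 10)), genes)
  # gene supported in exactly 175 of 250 replicates stays; 174 does not
  mk_rep <- function(support_g1) {
    res <- orig
    if (!support_g1) res["g01"] <- "unassigned"
    res
  }
  runs <- make_runs(c(replicate(175, mk_rep(TRUE), simplify = FALSE),
                      replicate(75, mk_rep(FALSE), simplify = FALSE)))
  cr <- consensus_filter(make_assignment(orig), runs, reliability = 0.70)
  expect_identical(unname(cr$labels["g01"]), "O1")
  expect_equal(unname(cr$reliability["g01"]), 0.7)
  runs174 <- make_runs(c(replicate(174, mk_rep(TRUE), simplify = FALSE),
                         replicate(76, mk_rep(FALSE), simplify = FALSE)))
  cr174 <- consensus_filter(make_assignment(orig), runs174, reliability = 0.70)
  expect_identical(unname(cr174$labels["g01"]), "unassigned")
  # originally unassigned genes stay unassigned whatever the bootstrap does
  expect_true(all(cr$labels[31:40] == "unassigned"))
})

test_that("identical replicates are a fixed point of the filter", {
  genes <- sprintf("g%02d", 1:50)
  orig <- setNames(c(rep("O1", 35), rep("unassigned", 15)), genes)
  runs <- make_runs(replicate(10, orig, simplify = FALSE))
  cr <- consensus_filter(make_assignment(orig), runs)
  expect_identical(cr$labels, orig)
  expect_true(all(cr$reliability[1:35] == 1))
})

test_that("raising the reliability threshold never grows a module", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:120)
  orig <- setNames(rep(c("O1", "O2", "unassigned"), each = 40), genes)
  runs <- make_runs(replicate(25, {
    res <- orig
    drop <- sample(120, 30)
    res[drop] <- "unassigned"
    res
  }, simplify = FALSE))
  sizes <- vapply(c(0.5, 0.7, 0.9), function(thr) {
    cr <- consensus_filter(make_assignment(orig), runs, reliability = thr)
    sum(cr$labels != "unassigned")
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("finalization merges, dissolves below the minimum size, and renumbers", {
  set.seed(8)
  base <- rnorm(18)
  mkmod <- function(n, profile, noise) t(replicate(n, profile + rnorm(18, 0, noise)))
  vals <- rbind(mkmod(40, base, 0.1), mkmod(35, base, 0.1),  # r > 0.85 pair
                mkmod(30, rnorm(18), 0.1),                    # exactly min size
                mkmod(29, rnorm(18), 0.1))                    # below min size
  dimnames(vals) <- list(sprintf("g%03d", 1:134), sprintf("s%d", 1:18))
  em <- make_em(vals)
  labels <- setNames(rep(c("A", "B", "C", "D"), c(40, 35, 30, 29)), rownames(vals))
  cr <- structure(list(labels = labels, original = labels,
                       reliability = setNames(rep(1, 134), names(labels)),
                       n_boot = 10),
                  class = "consensus_result")
  fin <- finalize_consensus(em, cr, merge_r = 0.85, min_size = 30)
  lab <- fin$labels
  expect_identical(length(unique(lab[1:75])), 1L)       # A and B merged
  expect_identical(unname(unique(lab[1:75])), "M1")     # largest after merge
  expect_identical(unname(unique(lab[76:105])), "M2")   # 30 genes kept
  expect_true(all(lab[106:134] == "unassigned"))        # 29 genes dissolved
  expect_identical(sort(fin$audit$module), c("A", "B", "C", "D"))
  expect_identical(fin$audit$demoted[fin$audit$module == "D"], 29L)
})

test_that("merging is strict at r = 0.85 in consensus finalization", {
  # two modules whose gene profiles are exact copies of two base vectors with
  # correlation exactly 0.85: eigengene correlation equals it, so a strict
  # rule must not merge
  set.seed(10)
  u <- scale(rnorm(18))[, 1]
  z <- scale(residuals(lm(rnorm(18) ~ u)))[, 1]
  v <- 0.85 * u + sqrt(1 - 0.85^2) * z
  vals <- rbind(t(replicate(30, u)), t(replicate(30, v)))
  dimnames(vals) <- list(sprintf("g%02d", 1:60), sprintf("s%d", 1:18))
  em <- make_em(vals)
  labels <- setNames(rep(c("A", "B"), each = 30), rownames(vals))
  cr <- structure(list(labels = labels, original = labels,
                       reliability = setNames(rep(1, 60), names(labels)),
                       n_boot = 1),
                  class = "consensus_result")
  fin <- finalize_consensus(em, cr, merge_r = 0.85, min_size = 30)
  expect_identical(length(setdiff(unique(fin$labels), "unassigned")), 2L)
  # whereas a clearly higher correlation merges
  v9 <- 0.95 * u + sqrt(1 - 0.95^2) * z
  vals2 <- rbind(t(replicate(30, u)), t(replicate(30, v9)))
  dimnames(vals2) <- dimnames(vals)
  fin2 <- finalize_consensus(make_em(vals2), cr, merge_r = 0.85, min_size = 30)
  expect_identical(length(setdiff(unique(fin2$labels), "unassigned")), 1L)
})

test_that("bootstrap runs are deterministic, full-size and stability-revealing", {
  em <- make_em(fixture_em()$values[1:250, ])
  runs <- suppressWarnings(bootstrap_networks(em, n_boot = 3, beta = 6, seed = 42))
  runs2 <- suppressWarnings(bootstrap_networks(em, n_boot = 3, beta = 6, seed = 42))
  expect_identical(lapply(runs, `[[`, "sample_idx"), lapply(runs2, `[[`, "sample_idx"))
  expect_true(all(vapply(runs, function(r) length(r$sample_idx), 0L) == 18L))
  expect_identical(runs[[1]]$assignment$labels, runs2[[1]]$assignment$labels)

  # strong planted modules: most replicates recover a module overlapping each
  # truth module by >= 50%
  sim <- fixture_sim()
  truth_mods <- sim$modules
  hits <- vapply(runs, function(r) {
    lab <- r$assignment$labels
    all(vapply(truth_mods, function(m) {
      g <- intersect(m$gene_ids, names(lab))
      if (length(g) < 10) return(TRUE)
      tab <- table(lab[g])
      tab <- tab[names(tab) != "unassigned"]
      length(tab) > 0 && max(tab) >= 0.5 * length(g)
    }, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("the consensus can only demote: final labels refine the original", {
  em <- make_em(fixture_em()$values[1:250, ])
  cr <- suppressWarnings(bootstrap_consensus(em, n_boot = 5, seed = 17))
  orig <- attr(cr, "original_assignment")$labels
  # originally unassigned genes never gain a label
  expect_true(all(cr$labels[orig == "unassigned"] == "unassigned"))
  # each final module is a union of (subsets of) original modules
  for (m in setdiff(unique(cr$labels), "unassigned")) {
    src <- unique(orig[cr$labels == m])
    expect_false("unassigned" %in% src)
  }
  expect_lte(length(setdiff(unique(cr$labels), "unassigned")),
             length(setdiff(unique(orig), "unassigned")))
  expect_true(all(cr$reliability >= 0 & cr$reliability <= 1))
})

test_that("zero bootstrap replicates are rejected", {
  em <- make_em(fixture_em()$values[1:50, ])
  expect_error(bootstrap_networks(em, n_boot = 0, beta = 6), ">=1 replicate")
  expect_error(consensus_filter(make_assignment(setNames("O1", "g1")), list()),
               ">=1 replicate")
})
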