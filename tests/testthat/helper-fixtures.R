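# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; expensive objects are memoized per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small count matrix with explicit values
tiny_counts <- function(values = rbind(c(1, 2), c(0, 5), c(3, 3)),
                        genes = sprintf("g%d", seq_len(nrow(values))),
                        samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  count_matrix(values)
}

# the packaged-scale simulated experiment used across tests (2,000 genes)
fixture_sim <- function() memo("fixture_sim", simulate_experiment(fixture_config(seed = 1)))

# its preprocessed network-input expression matrix
fixture_em <- function() memo("fixture_em", {
  sim <- fixture_sim()
  fcm <- filter_low_expression(sim$counts)
  variance_prefilter(log_cpm(fcm, tmm_normalize(fcm)))
})

# a fabricated module_assignment (no clustering involved)
make_assignment <- function(labels) {
  structure(list(labels = labels, dendrogram = NULL, cut_height = NA_real_),
            class = "module_assignment")
}

# fabricated bootstrap runs from a list of label vectors
make_runs <- function(label_list) {
  lapply(seq_along(label_list), function(i)
    structure(list(replicate = i, sample_idx = NULL,
                   assignment = make_assignment(label_list[[i]])),
              class = "bootstrap_run"))
}

# --- independent oracles -----------------------------------------------------

# brute-force TMM factor for one sample vs reference, straight from the
# doubly-trimmed weighted-mean definition, written gene by gene
oracle_tmm_factor <- function(obs, ref, lib_obs, lib_ref,
                              logratio_trim = 0.30, sum_trim = 0.05) {
  keep <- which(obs > 0 & ref > 0)
  M <- A <- w <- numeric(0)
  for (g in keep) {
    po <- obs[g] / lib_obs
    pr <- ref[g] / lib_ref
    M <- c(M, log2(po / pr))
    A <- c(A, 0.5 * (log2(po) + log2(pr)))
    w <- c(w, (lib_obs - obs[g]) / (lib_obs * obs[g]) +
              (lib_ref - ref[g]) / (lib_ref * ref[g]))
  }
  n <- length(M)
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  sel <- which(rM >= loM & rM <= hiM & rA >= loA & rA <= hiA)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  t_ <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { t_[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    t_[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_
}

# literal step-up BH definition
oracle_bh <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  out <- rep(NA_real_, length(p))
  if (!m) return(out)
  o <- order(p[ok])
  adj <- p[ok][o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out[ok[o]] <- pmin(adj, 1)
  out
}

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_fisher <- function(N, n_ann, n_sel, ov) {
  ks <- ov:min(n_ann, n_sel)
  sum(choose(n_ann, ks) * choose(N - n_ann, n_sel - ks)) / choose(N, n_sel)
}

# brute-force per-pair Bray-Curtis
oracle_bray <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(x[i, ] - x[j, ])); den <- sum(x[i, ] + x[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# expression matrix built directly from a value matrix
make_em <- function(values) {
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), prior_count = 0.5),
            class = "expression_matrix")
}

# standard 18-sample design
std_design <- function() {
  design_table(data.frame(
    sample_id = sprintf("%s_%s_r%d", rep(c("kauai", "mangaia"), each = 9),
                        rep(rep(c("control", "day4", "day7"), each = 3), 2),
                        rep(1:3, 6)),
    population = rep(c("kauai", "mangaia"), each = 9),
    infestation = rep(rep(c("control", "day4", "day7"), each = 3), 2)
  ))
}

# eigengene-style score vector with exact cell means and pooled SD 1:
# within-cell noise pattern (-1, 0, 1) gives pooled SD sqrt(12/12) = 1
scores_from_cells <- function(kauai, mangaia, design = std_design()) {
  mu <- c(kauai, mangaia) # control, day4, day7 per population
  cell <- as.integer(interaction(design$infestation, design$population))
  # interaction(infestation, population): levels control/day4/day7 x kauai, mangaia
  s <- mu[cell] + rep(c(-1, 0, 1), 6)
  stats::setNames(s, design$sample_id)
}
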