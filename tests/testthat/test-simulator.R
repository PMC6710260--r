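small_params <- function(...) {
  args <- list(preset = "small", n_genomes = 8, clones_per_subpool = 200,
               genome_length = 2e6)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

test_that("community generation normalises abundances deterministically", {
  p <- small_params(seed = 5)
  com <- simulate_community(p)
  expect_equal(sum(com$genomes$abundance), 1.0)
  expect_equal(nrow(com$domains), 8 * 4)
  # deterministic: same seed, identical truth
  com2 <- simulate_community(p)
  expect_identical(com$domains, com2$domains)
  expect_identical(com$genomes, com2$genomes)
  # different seed, different sequences
  com3 <- simulate_community(small_params(seed = 6))
  expect_false(identical(com$domains$seq, com3$domains$seq))
  # BGC spans respect the stated spacing range
  for (b in unique(com$domains$bgc_id)) {
    d <- com$domains[com$domains$bgc_id == b, ]
    gaps <- diff(d$start)
    expect_true(all(gaps >= 2000 & gaps <= 8000))
  }
  # infeasible spacing is a parameter error
  expect_error(simulate_community(
    sim_params(genome_length = 5000,
               inter_domain_spacing = c(4000, 4000), seed = 1)),
    "parameter error")
})

test_that("generated domains are mutually far below clustering thresholds", {
  com <- simulate_community(small_params(seed = 7, n_genomes = 3))
  seqs <- com$domains$seq
  for (i in 1:(length(seqs) - 1)) {
    ids <- vapply((i + 1):length(seqs), function(j)
      pairwise_identity(seqs[i], seqs[j]), numeric(1))
    expect_true(all(ids < 0.85))
  }
})

test_that("library dealing balances subpools and follows abundances", {
  p <- small_params(seed = 11)
  com <- simulate_community(p)
  ct <- simulate_library(com)
  expect_equal(nrow(ct), p$n_subpools * p$clones_per_subpool)
  sizes <- table(ct$subpool_id)
  expect_equal(length(sizes), p$n_subpools)
  expect_lte(max(sizes) - min(sizes), 1L)
  # insert lengths live in the truncation window
  lens <- ct$end - ct$start
  expect_true(all(lens >= 20000 & lens <= 45000))
  # genome sampling matches abundances within 3 binomial SE
  n <- nrow(ct)
  for (g in seq_len(p$n_genomes)) {
    a <- com$genomes$abundance[g]
    obs <- sum(ct$genome_id == com$genomes$genome_id[g]) / n
    se <- sqrt(a * (1 - a) / n)
    expect_lt(abs(obs - a), 3 * se + 1e-9)
  }
})

test_that("co-capture frequencies follow the closed-form geometry", {
  expect_equal(cocapture_probability(0, 38000), 1.0)
  expect_equal(cocapture_probability(38000, 38000), 0.0)
  expect_equal(cocapture_probability(19000, 38000), 0.5)
  expect_equal(cocapture_probability(50000, 38000), 0.0)

  # empirical check: two domains d apart, fixed-length inserts
  L <- 38000; ell <- 230; d <- 10000
  p <- sim_params(n_genomes = 1, n_bgcs_per_genome = 1,
                  domains_per_bgc = c(2, 2),
                  inter_domain_spacing = c(d, d), insert_sd = 0,
                  genome_length = 4e5, n_subpools = 96,
                  clones_per_subpool = 120, dropout = 0, seed = 13)
  com <- simulate_community(p)
  ct <- simulate_library(com)
  truth <- simulated_truth(com, ct)
  hits <- truth$domain_hits
  n_a <- length(hits[[1]])
  co <- length(intersect(hits[[1]], hits[[2]]))
  expected <- cocapture_probability(d, L - ell)
  se <- sqrt(expected * (1 - expected) / n_a)
  expect_gt(n_a, 500)
  expect_lt(abs(co / n_a - expected), 3 * se)
})

test_that("noise-free direct mode projects clone content exactly", {
  p <- small_params(seed = 15, dropout = 0)
  com <- simulate_community(p)
  ct <- simulate_library(com)
  truth <- simulated_truth(com, ct)
  om <- emit_observations(com, ct, truth, mode = "direct", min_wells = 0)
  P <- presence(om)
  for (i in seq_len(nrow(com$domains))) {
    pools <- sort(unique(ct$subpool_id[truth$domain_hits[[i]]]))
    expect_setequal(om$subpools[as.logical(P[com$domains$domain_id[i], ])],
                    pools)
  }
})

test_that("dropout thins detections at the configured rate", {
  p <- small_params(seed = 17, dropout = 0.3)
  com <- simulate_community(p)
  ct <- simulate_library(com)
  truth <- simulated_truth(com, ct)
  om <- emit_observations(com, ct, truth, mode = "direct", min_wells = 0)
  present <- sum(vapply(seq_len(nrow(com$domains)), function(i)
    length(unique(ct$subpool_id[truth$domain_hits[[i]]])), 0))
  detected <- sum(presence(om))
  rate <- detected / present
  se <- sqrt(0.7 * 0.3 / present)
  expect_lt(abs(rate - 0.7), 3 * se)
})

test_that("recovery scoring applies its conventions", {
  p <- small_params(seed = 19)
  run <- simulate_run(p, mode = "direct")
  om <- run$observations
  links <- detect_links(om)
  sc <- score_recovery(links, run$truth, om$variants)
  expect_true(sc$precision >= 0 && sc$precision <= 1)

  # perfect prediction built from the detectable truth itself
  det <- run$truth$true_pairs[run$truth$true_pairs$n_subpools_co >= 3, ]
  perfect <- data.frame(variant_a = det$domain_a,
                        variant_b = det$domain_b)
  sp <- score_recovery(perfect, run$truth, om$variants)
  expect_equal(sp$precision, 1.0)
  expect_equal(sp$recall, 1.0)

  # empty prediction: recall 0, precision reported 1 with a support flag
  empty <- data.frame(variant_a = character(), variant_b = character())
  se <- score_recovery(empty, run$truth, om$variants)
  expect_equal(se$recall, 0)
  expect_equal(se$precision, 1)
  expect_true(se$zero_support)

  # random predictions agree with brute-force set arithmetic
  set.seed(23)
  ids <- om$variants$variant_id
  rnd <- data.frame(variant_a = sample(ids, 10, TRUE),
                    variant_b = sample(ids, 10, TRUE))
  rnd <- rnd[rnd$variant_a != rnd$variant_b, ]
  sr <- score_recovery(rnd, run$truth, om$variants)
  truth_keys <- paste(run$truth$true_pairs$domain_a,
                      run$truth$true_pairs$domain_b)
  pred_keys <- unique(paste(pmin(rnd$variant_a, rnd$variant_b),
                            pmax(rnd$variant_a, rnd$variant_b)))
  expect_equal(sr$n_predicted, length(pred_keys))
  expect_equal(sr$precision, mean(pred_keys %in% truth_keys))
})

test_that("run artifacts are written with a parameter manifest", {
  dir <- tempfile()
  p <- sim_params(preset = "small", seed = 25, n_genomes = 4,
                  clones_per_subpool = 50, genome_length = 1e6)
  run <- simulate_run(p, mode = "direct", out_dir = dir)
  expect_true(file.exists(file.path(dir, "truth_domains.tsv")))
  expect_true(file.exists(file.path(dir, "truth_pairs.tsv")))
  expect_true(file.exists(file.path(dir, "occurrence.tsv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 25L)
  expect_equal(man$n_subpools, 384L)
  om <- read_occurrence(file.path(dir, "occurrence.tsv"))
  expect_equal(nrow(om$counts), nrow(run$observations$counts))
})
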