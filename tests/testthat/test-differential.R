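make_counts <- function(mat, ids = sprintf("m%02d", seq_len(nrow(mat)))) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(mirna_id = ids), tibble::as_tibble(mat))
}

two_group_samples <- function(n_per = 3, compartment = "EV") {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(2 * n_per)),
    compartment = compartment,
    condition = rep(c("CONT", "CAVIN1"), each = n_per),
    replicate = rep(paste0("R", seq_len(n_per)), 2)
  )
}

test_that("low-count filter keeps exactly the boundary and is idempotent", {
  mat <- rbind(rep(5, 4),   # total 20: kept
               c(5, 5, 5, 4),  # total 19: removed
               rep(0, 4))
  counts <- make_counts(mat)
  out <- suppressMessages(filter_low_counts(counts, 20))
  expect_equal(out$mirna_id, "m01")
  expect_equal(suppressMessages(filter_low_counts(out, 20)), out)
  expect_equal(filter_low_counts(counts, 0), counts)
})

test_that("size factors respect symmetry and elementwise scaling", {
  m <- matrix(rpois(40, 50), 20, 2)
  counts <- make_counts(cbind(m[, 1], m[, 1]))
  sf <- estimate_size_factors(counts)
  expect_equal(sf$size_factor, c(1, 1))

  counts2 <- make_counts(cbind(m[, 1], 2L * m[, 1]))
  sf2 <- estimate_size_factors(counts2)
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf2$size_factor))), 1, tolerance = 1e-12)
})

test_that("size factors equal the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_count_experiment(sim_config(n_mirna = 80, n_exported = 10,
                                              seed = 21))
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$mirna_id
  ours <- estimate_size_factors(sim$counts)$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("identical groups give log2fc 0 and p 1", {
  row <- c(10, 20, 30, 10, 20, 30)
  counts <- make_counts(matrix(rep(row, each = 1), nrow = 1))
  res <- nb_differential(counts, two_group_samples(), "EV")
  expect_equal(res$log2fc, 0, tolerance = 1e-9)
  expect_equal(res$wald_p, 1, tolerance = 1e-9)
})

test_that("true log2 fold changes are recovered without systematic bias", {
  ests <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      mu <- 200
      y <- c(rnbinom(3, mu = mu, size = 20), rnbinom(3, mu = 2 * mu, size = 20))
      counts <- make_counts(matrix(y, nrow = 1))
      nb_differential(counts, two_group_samples(), "EV",
                      size_factors = tibble::tibble(
                        sample_id = sprintf("s%02d", 1:6),
                        size_factor = rep(1, 6)))$log2fc
    })
  }, numeric(1))
  expect_gt(median(ests), 0.8)
  expect_lt(median(ests), 1.2)
})

test_that("null simulation keeps the Wald type-I error near nominal", {
  # 2000 miRNA-tests under the null, NB dispersion 0.05, n = 3 + 3
  sim <- simulate_count_experiment(sim_config(n_mirna = 2000, n_exported = 0,
                                              dispersion = 0.05, seed = 17))
  kept <- suppressMessages(filter_low_counts(sim$counts, 20))
  res <- nb_differential(kept, sim$samples, "EV")
  rate <- mean(res$wald_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("BH q-values are a monotone transform of the p-value order", {
  sim <- simulate_count_experiment(sim_config(n_mirna = 60, n_exported = 10,
                                              seed = 12))
  kept <- suppressMessages(filter_low_counts(sim$counts, 20))
  res <- nb_differential(kept, sim$samples, "EV")
  ord <- order(res$wald_p)
  expect_true(all(diff(res$bh_q[ord]) >= -1e-12))
  expect_gte(min(res$bh_q), min(res$wald_p))
  expect_equal(res$bh_q, p.adjust(res$wald_p, "BH"))
})

test_that("scaling one sample moves its size factor but not the estimates", {
  withr::local_seed(3)
  m <- matrix(rnbinom(50 * 6, mu = 150, size = 20), 50, 6)
  counts <- make_counts(m)
  scaled <- m
  scaled[, 2] <- 3L * scaled[, 2]
  counts_scaled <- make_counts(scaled)
  sf0 <- estimate_size_factors(counts)$size_factor
  sf1 <- estimate_size_factors(counts_scaled)$size_factor
  # factor for the scaled sample triples relative to the others
  rel0 <- sf0[2] / exp(mean(log(sf0[-2])))
  rel1 <- sf1[2] / exp(mean(log(sf1[-2])))
  expect_equal(rel1 / rel0, 3, tolerance = 1e-10)
  # the NB likelihood is only asymptotically invariant to count scaling
  # (3y with offset log 3 is not the same likelihood as y), so estimates
  # are compared at a finite-count bound rather than exactly
  r0 <- nb_differential(counts, two_group_samples(), "EV")
  r1 <- nb_differential(counts_scaled, two_group_samples(), "EV")
  expect_lt(max(abs(r1$log2fc - r0$log2fc)), 0.05)
  expect_gt(cor(r1$log2fc, r0$log2fc), 0.999)
})

test_that("empirical controls are null-dominated, deterministic, and capped", {
  sim <- simulate_count_experiment(sim_config(n_mirna = 150, n_exported = 30,
                                              export_effect = -3,
                                              dispersion = 0.05, seed = 19))
  kept <- suppressMessages(filter_low_counts(sim$counts, 20))
  ctrl <- suppressMessages(select_empirical_controls(kept, sim$samples, 30))
  truth <- sim$truth$is_exported[match(ctrl, sim$truth$mirna_id)]
  expect_gte(mean(!truth), 0.9)
  ctrl2 <- suppressMessages(select_empirical_controls(kept, sim$samples, 30))
  expect_identical(ctrl, ctrl2)
  all_ids <- suppressMessages(suppressWarnings(
    select_empirical_controls(kept, sim$samples, 10000)))
  expect_setequal(all_ids, kept$mirna_id)
})

test_that("RUV offsets are zero at k = 0 and recover a planted batch factor", {
  sim <- simulate_count_experiment(sim_config(n_mirna = 100, n_exported = 0,
                                              dispersion = 0.02, seed = 23))
  kept <- suppressMessages(filter_low_counts(sim$counts, 20))
  z0 <- ruv_normalize(kept, sim$samples, controls = kept$mirna_id[1:20], k = 0)
  expect_true(all(z0$offsets == 0))

  # plant one batch factor loaded on the controls
  controls <- kept$mirna_id[1:30]
  batch <- withr::with_seed(1, rnorm(12, 0, 0.8))
  m <- as.matrix(kept[-1])
  m[1:30, ] <- round(sweep(m[1:30, ], 2, exp(batch), "*"))
  batched <- dplyr::bind_cols(tibble::tibble(mirna_id = kept$mirna_id),
                              tibble::as_tibble(m))
  ruv <- ruv_normalize(batched, sim$samples, controls, k = 1)
  expect_gte(abs(cor(ruv$factors$W1, batch)), 0.9)

  expect_error(ruv_normalize(kept, sim$samples, controls[1:2], k = 2),
               class = "mirexport_parameter_error")
})

test_that("RUV offsets are equivariant under sample permutation", {
  sim <- simulate_count_experiment(sim_config(n_mirna = 60, n_exported = 0,
                                              seed = 31))
  kept <- suppressMessages(filter_low_counts(sim$counts, 20))
  controls <- kept$mirna_id[1:15]
  ruv <- ruv_normalize(kept, sim$samples, controls, k = 1)
  perm <- c(4:12, 1:3)
  kept_perm <- kept[c("mirna_id", names(kept)[-1][perm])]
  ruv_perm <- ruv_normalize(kept_perm, sim$samples, controls, k = 1)
  expect_equal(ruv_perm$offsets, ruv$offsets[, colnames(ruv_perm$offsets)],
               tolerance = 1e-8)
})
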