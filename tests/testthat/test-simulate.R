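test_that("count experiment is deterministic and has the declared shape", {
  cfg <- sim_config(n_mirna = 40, n_exported = 6, n_replicates = 3, seed = 9)
  a <- simulate_count_experiment(cfg)
  b <- simulate_count_experiment(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$counts), 40)
  expect_equal(length(setdiff(names(a$counts), "mirna_id")), 4 * 3)
  expect_setequal(unique(a$samples$compartment), c("cell", "EV"))
  expect_setequal(unique(a$samples$condition), c("CONT", "CAVIN1"))
  expect_true(all(vapply(a$counts[-1], function(x) all(x >= 0 & x == floor(x)),
                         logical(1))))
})

test_that("zero exported miRNAs yields an all-false truth table", {
  cfg <- sim_config(n_mirna = 25, n_exported = 0, seed = 2)
  sim <- simulate_count_experiment(cfg)
  expect_false(any(sim$truth$is_exported))
})

test_that("export effect shifts EV-CONT counts so CAVIN1 EVs look depleted", {
  cfg <- sim_config(n_mirna = 200, n_exported = 100, export_effect = -2,
                    dispersion = 0.02, baseline_logsd = 0.2, seed = 4)
  sim <- simulate_count_experiment(cfg)
  m <- as.matrix(sim$counts[-1])
  sf <- sim$samples$true_size_factor
  norm <- sweep(m, 2, sf, "/")
  ev_cont <- rowMeans(norm[, sim$samples$compartment == "EV" &
                             sim$samples$condition == "CONT"])
  ev_cav <- rowMeans(norm[, sim$samples$compartment == "EV" &
                            sim$samples$condition == "CAVIN1"])
  lfc <- log2(ev_cav / ev_cont)
  expect_lt(median(lfc[sim$truth$is_exported]), -1.5)
  expect_lt(abs(median(lfc[!sim$truth$is_exported])), 0.3)
})

test_that("invalid configurations raise parameter errors naming the field", {
  expect_error(sim_config(n_mirna = 10, n_exported = 11), "n_exported",
               class = "mirexport_parameter_error")
  expect_error(sim_config(motif_plant_prob = 1.2), "motif_plant_prob",
               class = "mirexport_parameter_error")
  expect_error(sim_config(background_freqs = c(0.3, 0.3, 0.3, 0.3)),
               "background_freqs", class = "mirexport_parameter_error")
  expect_error(sim_config(dispersion = -1), "dispersion",
               class = "mirexport_parameter_error")
})

test_that("plant probability 1 with a literal consensus forces exact matches", {
  cfg <- sim_config(n_mirna = 30, n_exported = 12, motif_consensus = "AUUGCA",
                    motif_plant_prob = 1, seq_length_range = c(20L, 24L),
                    seed = 5)
  sim <- simulate_count_experiment(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  exported <- sq$sequences$sequence[sq$truth$is_exported]
  expect_equal(sum(grepl("AUUGCA", exported, fixed = TRUE)), 12)
  expect_true(all(sq$truth$motif_planted[sq$truth$is_exported]))
  # planted offsets point at a true occurrence
  for (i in which(sq$truth$motif_planted)) {
    pos <- sq$truth$planted_position[i] + 1L
    expect_equal(substr(sq$sequences$sequence[i], pos, pos + 5L), "AUUGCA")
  }
})

test_that("no motif is forced when nothing is exported", {
  cfg <- sim_config(n_mirna = 15, n_exported = 0, motif_plant_prob = 1, seed = 3)
  sim <- simulate_count_experiment(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  expect_false(any(sq$truth$motif_planted))
})

test_that("a motif longer than the shortest sequence is rejected", {
  cfg <- sim_config(n_mirna = 5, n_exported = 1,
                    motif_consensus = paste(rep("A", 30), collapse = ""),
                    seq_length_range = c(18L, 20L), seed = 1)
  sim <- simulate_count_experiment(cfg)
  expect_error(simulate_sequences(cfg, sim$truth), "longer",
               class = "mirexport_parameter_error")
})

test_that("background base usage stays inside exact binomial 99% intervals", {
  cfg <- sim_config(n_mirna = 500, n_exported = 0,
                    seq_length_range = c(20L, 20L),
                    background_freqs = c(0.25, 0.25, 0.25, 0.25), seed = 8)
  sim <- simulate_count_experiment(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  bases <- strsplit(paste(sq$sequences$sequence, collapse = ""), "")[[1]]
  n <- length(bases)
  expect_gte(n, 10000)
  for (b in c("A", "C", "G", "U")) {
    k <- sum(bases == b)
    ci <- stats::binom.test(k, n, p = 0.25, conf.level = 0.99)$conf.int
    expect_true(ci[1] <= 0.25 && 0.25 <= ci[2])
  }
})

test_that("intensity generator plants recoverable effects and honest nulls", {
  # type-I behaviour: no signal, expected false positives about alpha * n
  fp <- vapply(1:10, function(s) {
    sim <- simulate_intensity_table(80, 8, 0, noise_sd = 0.5, seed = s)
    sum(ttest_volcano(sim$intensities, sim$groups)$significant)
  }, numeric(1))
  expect_gt(mean(fp), 0.02 * 80)
  expect_lt(mean(fp), 0.10 * 80)

  # power: strong planted effects are recovered
  hits <- vapply(1:20, function(s) {
    sim <- simulate_intensity_table(40, 8, 10, effect_log2 = 3,
                                    noise_sd = 0.2, seed = s)
    res <- ttest_volcano(sim$intensities, sim$groups)
    mean(res$significant[sim$truth$is_signal])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("binding curve generator satisfies the Hill half-response identity", {
  curve <- simulate_binding_curve(kd = 5e-6, hill = 1.3, top = 2, bottom = 0.4,
                                  concentrations = c(5e-6, 1e-6, 1e-5, 1e-7,
                                                     5e-5, 1e-4),
                                  noise_sd = 0)
  at_kd <- curve$response[curve$concentration == 5e-6]
  expect_equal(at_kd, (2 + 0.4) / 2, tolerance = 1e-12)
  # different seeds move only the noise, not the noiseless component
  a <- simulate_binding_curve(kd = 5e-6, noise_sd = 0.1, seed = 1)
  b <- simulate_binding_curve(kd = 5e-6, noise_sd = 0.1, seed = 2)
  expect_identical(a$response_true, b$response_true)
  expect_false(identical(a$response, b$response))
})

test_that("droplet generator is seed-deterministic with sane positives", {
  a <- simulate_droplets(1000, 20000, seed = 3)
  b <- simulate_droplets(1000, 20000, seed = 3)
  expect_identical(a, b)
  expect_true(a$positive_droplets >= 0 && a$positive_droplets <= 20000)
})
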