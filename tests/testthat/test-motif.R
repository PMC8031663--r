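test_that("background frequencies match direct counting", {
  expect_equal(unname(build_background(tibble::tibble(sequence = "AAAA"))),
               c(1, 0, 0, 0))
  expect_equal(unname(build_background(tibble::tibble(sequence = "ACGU"))),
               rep(0.25, 4))
  rnd <- random_sequences(15, 20, seed = 2)
  counted <- table(factor(strsplit(paste(rnd$sequence, collapse = ""),
                                   "")[[1]],
                          levels = c("A", "C", "G", "U")))
  expect_equal(unname(build_background(rnd)),
               unname(as.numeric(counted) / sum(counted)))
  expect_error(build_background(tibble::tibble(sequence = character())),
               class = "mirexport_value_error")
})

planted_fixture <- function(seed, n = 30, n_planted = 20, word = "AUUGCA") {
  cfg <- sim_config(n_mirna = n, n_exported = n_planted,
                    motif_consensus = word, motif_plant_prob = 1,
                    seq_length_range = c(22L, 22L), seed = seed)
  sim <- simulate_count_experiment(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  list(sequences = sq$sequences, truth = sq$truth)
}

test_that("ZOOPS EM recovers a planted 6-mer and its site offsets", {
  fx <- planted_fixture(seed = 5)
  model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 1))
  expect_gte(consensus_overlap(model$consensus, "AUUGCA"), 5)
  sp <- dplyr::inner_join(model$site_posteriors, fx$truth, by = "mirna_id")
  planted <- sp[sp$motif_planted, ]
  expect_gte(sum(planted$best_position == planted$planted_position), 16)
})

test_that("EM objective is non-decreasing on every iteration", {
  for (seed in 1:5) {
    fx <- planted_fixture(seed = seed, n = 15, n_planted = 8)
    model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = seed))
    expect_true(all(diff(model$obj_trace) >= -1e-9))
  }
})

test_that("PWM rows are stochastic and strictly positive after fitting", {
  fx <- planted_fixture(seed = 9)
  model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 2))
  expect_equal(unname(rowSums(model$pwm)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(model$pwm > 0))
  expect_true(model$lambda >= 0 && model$lambda <= 1)
  post <- model$site_posteriors
  expect_true(all(post$site_posterior >= 0 & post$no_site_mass >= 0))
})

test_that("identical sequences drive the best window to point masses", {
  seqs <- tibble::tibble(mirna_id = sprintf("s%d", 1:12),
                         sequence = rep("ACGUACGUACGUACGUACGU", 12))
  model <- zoops_em(seqs, 4, config = zoops_config(seed = 1))
  expect_true(all(apply(model$pwm, 1, max) > 0.95))
})

test_that("EM is deterministic and invariant to input sequence order", {
  fx <- planted_fixture(seed = 13)
  a <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 4))
  b <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 4))
  expect_identical(a$pwm, b$pwm)
  expect_identical(a$loglik, b$loglik)
  perm <- withr::with_seed(1, sample(nrow(fx$sequences)))
  c_ <- zoops_em(fx$sequences[perm, ], 6, config = zoops_config(seed = 4))
  expect_equal(c_$pwm, a$pwm, tolerance = 1e-12)
  expect_equal(c_$loglik, a$loglik, tolerance = 1e-9)
})

test_that("sequences shorter than the width are rejected by name", {
  seqs <- tibble::tibble(mirna_id = c("ok", "short"),
                         sequence = c("ACGUACGU", "ACG"))
  expect_error(zoops_em(seqs, 6), "short", class = "mirexport_value_error")
})

test_that("consensus calling follows the single/double/any base rules", {
  pwm <- rbind(c(0.9, 0.03, 0.04, 0.03),
               c(0.05, 0.45, 0.45, 0.05),
               c(0.25, 0.25, 0.25, 0.25),
               c(0.1, 0.1, 0.1, 0.7),
               c(0.55, 0.05, 0.35, 0.05))
  colnames(pwm) <- c("A", "C", "G", "U")
  # row 5: top 0.55 < 2 * 0.35, top-two sum 0.9 >= 0.75 -> "r" (A/G)
  expect_equal(consensus_from_pwm(pwm), "AsnUr")
})

test_that("width scan picks a width near the planted one with its consensus", {
  fx <- planted_fixture(seed = 3)
  model <- suppressWarnings(
    discover_motif(fx$sequences,
                   config = zoops_config(w_min = 4, w_max = 10,
                                         n_shuffles = 30, seed = 1))
  )
  expect_true(model$width %in% 5:7)
  expect_gte(consensus_overlap(model$consensus, "AUUGCA"), 5)
})

test_that("discovery is deterministic under a fixed seed", {
  fx <- planted_fixture(seed = 8, n = 20, n_planted = 14)
  cfg <- zoops_config(w_min = 5, w_max = 7, n_shuffles = 25, seed = 6)
  a <- suppressWarnings(discover_motif(fx$sequences, config = cfg))
  b <- suppressWarnings(discover_motif(fx$sequences, config = cfg))
  expect_identical(glance(a), glance(b))
  expect_identical(a$pwm, b$pwm)
})

test_that("e-value saturates at its floor for a strongly planted motif", {
  fx <- planted_fixture(seed = 2, n = 30, n_planted = 30)
  model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 1))
  e <- motif_evalue(model, fx$sequences, n_shuffles = 60, seed = 3)
  expect_equal(as.numeric(e), 1 / 61)
})

test_that("e-value scales linearly with the number of widths scanned", {
  fx <- planted_fixture(seed = 4, n = 12, n_planted = 6)
  model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 1))
  e1 <- motif_evalue(model, fx$sequences, n_shuffles = 30, seed = 5,
                     n_widths = 1)
  e7 <- motif_evalue(model, fx$sequences, n_shuffles = 30, seed = 5,
                     n_widths = 7)
  expect_equal(as.numeric(e7) / as.numeric(e1), 7, tolerance = 1e-12)
})

test_that("serialised motif models round-trip through the text format", {
  fx <- planted_fixture(seed = 6, n = 12, n_planted = 8)
  model <- zoops_em(fx$sequences, 6, config = zoops_config(seed = 2))
  model$e_value <- 0.025
  tf <- withr::local_tempfile(fileext = ".txt")
  write_motif_model(model, tf)
  back <- read_motif_model(tf)
  expect_equal(back$width, model$width)
  expect_equal(back$consensus, model$consensus)
  expect_lt(abs(back$lambda - model$lambda), 1e-6)
  expect_lt(max(abs(back$pwm - model$pwm)), 1e-6)
  expect_lt(abs(back$e_value - 0.025), 1e-9)
})

test_that("tidy and glance expose the PWM and the fit summary", {
  fx <- planted_fixture(seed = 7, n = 10, n_planted = 5)
  model <- zoops_em(fx$sequences, 5, config = zoops_config(seed = 1))
  td <- tidy(model)
  expect_equal(nrow(td), 5 * 4)
  expect_equal(sum(td$probability), 5, tolerance = 1e-9)
  gl <- glance(model)
  expect_equal(gl$width, 5)
  expect_true(is.character(gl$consensus))
})

test_that("e-values are honestly calibrated on background-only inputs", {
  evs <- vapply(1:20, function(s) {
    seqs <- random_sequences(30, 22, seed = 200 + s)
    model <- zoops_em(seqs, 6, config = zoops_config(seed = s))
    as.numeric(motif_evalue(model, seqs, n_shuffles = 49, seed = s))
  }, numeric(1))
  expect_gt(median(evs), 0.05)
  expect_lte(mean(evs <= 0.05), 0.10)
})
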