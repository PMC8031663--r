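#' Configuration for the synthetic paired cell/EV miRNA experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the design of a paired-compartment small-RNA experiment in a prostate
#' cancer cell model: two conditions (`CONT`, control cells expressing
#' non-caveolar CAV1; `CAVIN1`, cells re-expressing CAVIN1) profiled in both
#' whole cells and their extracellular vesicles (EVs), three biological
#' replicates each, with a subset of miRNAs carrying both a planted
#' EV-export effect and a planted sequence motif.
#'
#' @param n_mirna Number of miRNAs to simulate.
#' @param n_exported Number of selectively exported miRNAs (must not exceed
#'   `n_mirna`).
#' @param n_replicates Biological replicates per compartment x condition group.
#' @param baseline_logmean,baseline_logsd Per-miRNA baseline abundance is
#'   drawn as `2^N(baseline_logmean, baseline_logsd)` expected counts.
#' @param dispersion Negative-binomial dispersion `alpha` in the
#'   `variance = mu + alpha * mu^2` parameterisation (0 gives Poisson counts).
#' @param export_effect Expected log2 fold change (CAVIN1 vs CONT) of EV
#'   counts for exported miRNAs. Mechanically the shift `-export_effect` is
#'   added to the log2 mean of the EV/CONT samples only, so that CAVIN1 EVs
#'   are depleted relative to CONT EVs for negative values (CAVIN1 suppresses
#'   export) and the downstream classifier's `<=` thresholds fire.
#' @param motif_consensus Degenerate IUPAC RNA string planted into exported
#'   sequences. The default mirrors a 6-nt A/C-G/U/G/any/A signal of the kind
#'   recovered from selectively exported miRNA sets.
#' @param motif_plant_prob Probability that an exported miRNA receives a
#'   motif instance (about 21/47 in the motivating data).
#' @param seq_length_range Integer `c(min, max)` sequence length in nt;
#'   mature miRNAs run roughly 18-25 nt.
#' @param background_freqs Background base frequencies (A, C, G, U); must sum
#'   to 1.
#' @param libsize_range Per-sample library size factors are drawn log-uniform
#'   in this range to exercise normalisation.
#' @param seed Integer seed; every generator is a pure function of its seed.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_mirna = 50, n_exported = 8, seed = 1)
sim_config <- function(n_mirna = 300,
                       n_exported = 47,
                       n_replicates = 3,
                       baseline_logmean = 7,
                       baseline_logsd = 1.5,
                       dispersion = 0.1,
                       export_effect = -2,
                       motif_consensus = "AsUGnA",
                       motif_plant_prob = 21 / 47,
                       seq_length_range = c(18L, 25L),
                       background_freqs = c(0.25, 0.25, 0.25, 0.25),
                       libsize_range = c(0.5, 2),
                       seed = 1L) {
  n_mirna <- check_count(n_mirna, "n_mirna", min = 1L)
  n_exported <- check_count(n_exported, "n_exported", min = 0L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  if (n_exported > n_mirna) {
    abort("'n_exported' must not exceed 'n_mirna'", class = "mirexport_parameter_error")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("'dispersion' must be a real >= 0", class = "mirexport_parameter_error")
  }
  check_prob(motif_plant_prob, "motif_plant_prob")
  if (length(background_freqs) != 4L || any(background_freqs < 0) ||
      abs(sum(background_freqs) - 1) > 1e-9) {
    abort("'background_freqs' must be a 4-vector summing to 1",
          class = "mirexport_parameter_error")
  }
  if (length(seq_length_range) != 2L || seq_length_range[1] > seq_length_range[2] ||
      seq_length_range[1] < 1) {
    abort("'seq_length_range' must be c(min, max) with 1 <= min <= max",
          class = "mirexport_parameter_error")
  }
  # validates the IUPAC content early so errors name the field
  tryCatch(lapply(strsplit(motif_consensus, "")[[1]], iupac_allowed),
           error = function(e) abort("'motif_consensus' is not a valid IUPAC RNA string",
                                     class = "mirexport_parameter_error"))
  structure(list(
    n_mirna = n_mirna, n_exported = n_exported, n_replicates = n_replicates,
    baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
    dispersion = dispersion, export_effect = export_effect,
    motif_consensus = motif_consensus, motif_plant_prob = motif_plant_prob,
    seq_length_range = as.integer(seq_length_range),
    background_freqs = background_freqs, libsize_range = libsize_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

nb_draw <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate the paired cell/EV count experiment
#'
#' Draws a negative-binomial count matrix over the four groups
#' (cell/EV x CONT/CAVIN1) times `n_replicates`, with per-sample library-size
#' factors and a planted EV-export effect on `n_exported` miRNAs (see
#' [sim_config()] for the direction convention). Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble, `mirna_id` plus one column per
#'   sample), `samples` (tibble: `sample_id`, `compartment`, `condition`,
#'   `replicate`, `true_size_factor`), and `truth` (tibble: `mirna_id`,
#'   `is_exported`).
#' @export
#' @examples
#' sim <- simulate_count_experiment(sim_config(n_mirna = 40, n_exported = 5, seed = 7))
#' dim(sim$counts)
simulate_count_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("'config' must be a sim_config", class = "mirexport_parameter_error")
  }
  with_seed(config$seed, {
    n <- config$n_mirna
    mirna_id <- sprintf("syn-miR-%03d", seq_len(n))
    is_exported <- c(rep(TRUE, config$n_exported), rep(FALSE, n - config$n_exported))

    groups <- expand.grid(
      replicate = paste0("R", seq_len(config$n_replicates)),
      condition = c("CONT", "CAVIN1"),
      compartment = c("cell", "EV"),
      stringsAsFactors = FALSE
    )
    samples <- tibble(
      sample_id = paste(groups$compartment, groups$condition, groups$replicate, sep = "_"),
      compartment = groups$compartment,
      condition = groups$condition,
      replicate = groups$replicate,
      true_size_factor = exp(runif(nrow(groups), log(config$libsize_range[1]),
                                   log(config$libsize_range[2])))
    )

    base_log2 <- rnorm(n, config$baseline_logmean, config$baseline_logsd)
    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(mirna_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      shift <- ifelse(
        is_exported & samples$compartment[j] == "EV" & samples$condition[j] == "CONT",
        -config$export_effect, 0
      )
      mu <- 2^(base_log2 + shift) * samples$true_size_factor[j]
      counts[, j] <- nb_draw(n, mu, config$dispersion)
    }

    list(
      counts = tibble(mirna_id = mirna_id) |>
        dplyr::bind_cols(as_tibble(counts)),
      samples = samples,
      truth = tibble(mirna_id = mirna_id, is_exported = is_exported)
    )
  })
}

instantiate_consensus <- function(consensus) {
  vapply(strsplit(consensus, "")[[1]], function(code) {
    allowed <- iupac_allowed(code)
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1)) |> paste(collapse = "")
}

#' Simulate mature miRNA sequences with a planted motif
#'
#' One RNA sequence per miRNA in the truth table, lengths uniform in
#' `config$seq_length_range`, bases i.i.d. from `config$background_freqs`.
#' Each exported miRNA receives, with probability `config$motif_plant_prob`,
#' one instantiation of `config$motif_consensus` (degenerate positions sampled
#' uniformly among the allowed bases) written over the background bases at a
#' uniform random offset, so lengths stay fixed.
#'
#' @param config A [sim_config()].
#' @param truth Truth tibble from [simulate_count_experiment()] (columns
#'   `mirna_id`, `is_exported`).
#' @return A list with `sequences` (tibble: `mirna_id`, `sequence`) and
#'   `truth` augmented with `motif_planted` and 0-based `planted_position`
#'   (`NA` when no motif was planted).
#' @export
simulate_sequences <- function(config, truth) {
  if (!inherits(config, "sim_config")) {
    abort("'config' must be a sim_config", class = "mirexport_parameter_error")
  }
  motif_w <- nchar(config$motif_consensus)
  if (motif_w > config$seq_length_range[1]) {
    abort("'motif_consensus' is longer than the minimum sequence length",
          class = "mirexport_parameter_error")
  }
  with_seed(config$seed + 1L, {
    n <- nrow(truth)
    len_choices <- seq(config$seq_length_range[1], config$seq_length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    planted <- logical(n)
    position <- rep(NA_integer_, n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      codes <- sample.int(4L, lens[i], replace = TRUE, prob = config$background_freqs)
      if (truth$is_exported[i] && runif(1) < config$motif_plant_prob) {
        start <- sample.int(lens[i] - motif_w + 1L, 1L)
        codes[start:(start + motif_w - 1L)] <- seq_to_codes(
          instantiate_consensus(config$motif_consensus)
        )
        planted[i] <- TRUE
        position[i] <- start - 1L
      }
      seqs[i] <- codes_to_seq(codes)
    }
    list(
      sequences = tibble(mirna_id = truth$mirna_id, sequence = seqs),
      truth = dplyr::mutate(truth, motif_planted = planted, planted_position = position)
    )
  })
}

#' Simulate a two-group protein intensity table
#'
#' Log-normal intensities for `n_proteins` proteins over two groups of
#' `n_per_group` samples (labelled `early` and `metastatic`), with the first
#' `n_signal` proteins shifted by `effect_log2` (recycled; signs may differ
#' per protein) in the metastatic group.
#'
#' @param n_proteins,n_per_group,n_signal Table dimensions; `n_signal <=
#'   n_proteins` and `n_per_group >= 2`.
#' @param effect_log2 Log2 shift(s) applied to signal proteins in the
#'   metastatic group; scalar or length `n_signal`.
#' @param noise_sd Within-group SD on the log2 scale.
#' @param baseline_log2,baseline_sd Per-protein baseline log2 intensity
#'   distribution.
#' @param seed Integer seed.
#' @return A list with `intensities` (tibble: `protein_id` plus sample
#'   columns), `groups` (tibble: `sample_id`, `group`) and `truth` (tibble:
#'   `protein_id`, `is_signal`, `effect_log2`).
#' @export
simulate_intensity_table <- function(n_proteins, n_per_group, n_signal,
                                     effect_log2 = 2, noise_sd = 0.5,
                                     baseline_log2 = 10, baseline_sd = 1.5,
                                     seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  n_signal <- check_count(n_signal, "n_signal", min = 0L)
  if (n_signal > n_proteins) {
    abort("'n_signal' must not exceed 'n_proteins'", class = "mirexport_parameter_error")
  }
  effects <- rep(effect_log2, length.out = max(n_signal, 1L))
  with_seed(seed, {
    protein_id <- sprintf("PROT%04d", seq_len(n_proteins))
    sample_id <- c(paste0("early_", seq_len(n_per_group)),
                   paste0("met_", seq_len(n_per_group)))
    group <- rep(c("early", "metastatic"), each = n_per_group)
    base <- rnorm(n_proteins, baseline_log2, baseline_sd)
    shift <- numeric(n_proteins)
    if (n_signal > 0) shift[seq_len(n_signal)] <- effects[seq_len(n_signal)]
    mat <- matrix(0, n_proteins, length(sample_id),
                  dimnames = list(protein_id, sample_id))
    for (j in seq_along(sample_id)) {
      mu <- base + if (group[j] == "metastatic") shift else 0
      mat[, j] <- 2^(mu + rnorm(n_proteins, 0, noise_sd))
    }
    list(
      intensities = tibble(protein_id = protein_id) |> dplyr::bind_cols(as_tibble(mat)),
      groups = tibble(sample_id = sample_id, group = group),
      truth = tibble(protein_id = protein_id,
                     is_signal = seq_len(n_proteins) <= n_signal,
                     effect_log2 = shift)
    )
  })
}

#' Simulate a Hill-equation dose-response curve
#'
#' `response = bottom + (top - bottom) * x^h / (kd^h + x^h)` plus Gaussian
#' noise, emulating a microscale thermophoresis (MST) dose series.
#'
#' @param kd Dissociation constant (> 0, same units as `concentrations`).
#' @param hill Hill coefficient `h`.
#' @param top,bottom Upper/lower response asymptotes.
#' @param concentrations Positive ligand concentrations (>= 6 points).
#' @param noise_sd Gaussian noise SD on the response.
#' @param seed Integer seed.
#' @return A tibble with `concentration`, `response`, `response_true`.
#' @export
simulate_binding_curve <- function(kd, hill = 1, top = 1, bottom = 0,
                                   concentrations = 150e-6 / 2^(0:11),
                                   noise_sd = 0, seed = 1L) {
  if (!is.numeric(kd) || kd <= 0) {
    abort("'kd' must be > 0", class = "mirexport_parameter_error")
  }
  if (length(concentrations) < 6L || any(concentrations <= 0)) {
    abort("'concentrations' must be >= 6 positive values",
          class = "mirexport_parameter_error")
  }
  with_seed(seed, {
    x <- sort(concentrations)
    f <- bottom + (top - bottom) * x^hill / (kd^hill + x^hill)
    tibble(concentration = x,
           response_true = f,
           response = f + rnorm(length(x), 0, noise_sd))
  })
}

#' Simulate droplet digital PCR partitions
#'
#' Partitions template at a true concentration into `n_droplets` droplets of
#' volume `droplet_volume`; each droplet is positive when it receives at
#' least one copy (copies per droplet are Poisson with mean
#' `copies_per_ul * droplet_volume`).
#'
#' @param copies_per_ul True template concentration (copies/uL).
#' @param n_droplets Number of droplets.
#' @param droplet_volume Droplet volume in uL (QX200 convention 8.5e-4).
#' @param seed Integer seed.
#' @return A tibble with `positive_droplets`, `total_droplets`,
#'   `droplet_volume`.
#' @export
simulate_droplets <- function(copies_per_ul, n_droplets = 20000L,
                              droplet_volume = 8.5e-4, seed = 1L) {
  n_droplets <- check_count(n_droplets, "n_droplets", min = 1L)
  if (copies_per_ul < 0) {
    abort("'copies_per_ul' must be >= 0", class = "mirexport_parameter_error")
  }
  with_seed(seed, {
    p_pos <- 1 - exp(-copies_per_ul * droplet_volume)
    k <- rbinom(1L, n_droplets, p_pos)
    tibble(positive_droplets = k, total_droplets = n_droplets,
           droplet_volume = droplet_volume)
  })
}

#' Synthetic stand-in for a pair of compartment log2 fold-change tables
#'
#' Builds the kind of per-miRNA log2FC table pair a paired cell/EV
#' differential analysis produces: `n_common` miRNAs shared by the two
#' compartments (plus compartment-only extras that a join must drop), of
#' which exactly `n_selected` planted rows satisfy the selective-export
#' criterion (`log2fc_ev <= -1` and `FE <= -0.5`), including a named
#' miR-148a-3p analogue. Entirely synthetic: its purpose is recovery testing
#' of the classifier, not reproduction of any real table.
#'
#' @param n_common Number of miRNAs present in both compartment tables.
#' @param n_selected Number of planted selectively exported rows.
#' @param n_ev_only,n_cell_only Extra single-compartment rows.
#' @param seed Integer seed.
#' @return A list with `ev` and `cell` tibbles (`mirna_id`, `log2fc`) and
#'   `selected_ids`.
#' @export
synthetic_log2fc_tables <- function(n_common = 317, n_selected = 47,
                                    n_ev_only = 23, n_cell_only = 13,
                                    seed = 42) {
  if (n_selected > n_common) {
    abort("'n_selected' must not exceed 'n_common'",
          class = "mirexport_parameter_error")
  }
  with_seed(seed, {
    ids <- sprintf("syn-miR-%04d", seq_len(n_common))
    ids[1] <- "syn-miR-148a-3p"
    sel <- seq_len(n_selected)
    ev <- numeric(n_common); cell <- numeric(n_common)
    ev[sel] <- runif(n_selected, -4, -1)              # log2fc_ev <= -1
    cell[sel] <- ev[sel] + runif(n_selected, 0.5, 3)  # fe <= -0.5
    for (i in seq(n_selected + 1L, n_common)) {
      repeat {
        e <- runif(1, -4, 4); c0 <- runif(1, -4, 4)
        if (!(e <= -1 && (e - c0) <= -0.5)) break
      }
      ev[i] <- e; cell[i] <- c0
    }
    extra_ev <- tibble(
      mirna_id = sprintf("evonly-miR-%03d", seq_len(n_ev_only)),
      log2fc = runif(n_ev_only, -4, 4)
    )
    extra_cell <- tibble(
      mirna_id = sprintf("cellonly-miR-%03d", seq_len(n_cell_only)),
      log2fc = runif(n_cell_only, -4, 4)
    )
    list(
      ev = dplyr::bind_rows(tibble(mirna_id = ids, log2fc = ev), extra_ev),
      cell = dplyr::bind_rows(tibble(mirna_id = ids, log2fc = cell), extra_cell),
      selected_ids = ids[sel]
    )
  })
}

#' Synthetic stand-in for a SWATH-style plasma-EV proteomics table
#'
#' A two-group (8 early vs 8 metastatic) log-normal intensity table of
#' `n_proteins` proteins with 16 planted differential proteins, 5 of them
#' increased in the metastatic group, plus an hnRNPK analogue whose
#' metastatic intensities are its early intensities scaled by exactly
#' `2^2.47`, so the mean-based log2 fold change is known by construction.
#' Entirely synthetic; built for recovery testing of the group comparison.
#'
#' @param seed Integer seed.
#' @param n_proteins Table size (default 1150).
#' @return As [simulate_intensity_table()]: `intensities`, `groups`, `truth`.
#' @export
synthetic_swath_table <- function(seed = 7, n_proteins = 1150) {
  sim <- simulate_intensity_table(
    n_proteins = n_proteins, n_per_group = 8, n_signal = 16,
    effect_log2 = c(rep(2.2, 5), rep(-2.2, 11)), noise_sd = 0.35,
    seed = seed
  )
  hk <- with_seed(seed + 1L, 2^rnorm(8, 10, 0.4))
  idx <- which(sim$truth$is_signal & sim$truth$effect_log2 > 0)[1]
  sim$intensities$protein_id[idx] <- "hnRNPK-analogue"
  sim$truth$protein_id[idx] <- "hnRNPK-analogue"
  early_cols <- sim$groups$sample_id[sim$groups$group == "early"]
  met_cols <- sim$groups$sample_id[sim$groups$group == "metastatic"]
  sim$intensities[idx, early_cols] <- as.list(hk)
  sim$intensities[idx, met_cols] <- as.list(hk * 2^2.47)
  sim
}
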