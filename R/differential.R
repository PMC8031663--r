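#' Settings for differential miRNA abundance
#'
#' @param min_total_count Minimum summed count across all samples for a miRNA
#'   to be retained (miRNAs with *less than* this total are removed, so a
#'   miRNA at exactly the threshold is kept).
#' @param ruv_k Number of unwanted-variation factors (0 disables RUV).
#' @param n_empirical_controls Number of empirical control miRNAs for RUV;
#'   `NULL` means 20% of retained miRNAs.
#' @param alpha FDR level used downstream.
#' @param pool_dispersion If `TRUE`, replace per-miRNA method-of-moments
#'   dispersions by their 20%-trimmed mean across miRNAs (stabilises n = 3
#'   designs).
#' @return A `diff_config` list.
#' @export
diff_config <- function(min_total_count = 20, ruv_k = 1,
                        n_empirical_controls = NULL, alpha = 0.05,
                        pool_dispersion = FALSE) {
  check_count(min_total_count, "min_total_count", min = 0L)
  check_count(ruv_k, "ruv_k", min = 0L)
  check_prob(alpha, "alpha")
  structure(list(min_total_count = min_total_count, ruv_k = ruv_k,
                 n_empirical_controls = n_empirical_controls, alpha = alpha,
                 pool_dispersion = pool_dispersion),
            class = "diff_config")
}

count_cols <- function(counts) setdiff(names(counts), "mirna_id")

count_matrix <- function(counts) {
  m <- as.matrix(counts[count_cols(counts)])
  rownames(m) <- counts$mirna_id
  m
}

#' Remove low-abundance miRNAs
#'
#' Retains exactly the miRNAs whose summed count across all samples is at
#' least `min_total`; input order is preserved and the filter is idempotent.
#'
#' @param counts Count tibble (`mirna_id` plus sample columns).
#' @param min_total Threshold on the total count.
#' @return The filtered count tibble.
#' @export
filter_low_counts <- function(counts, min_total = 20) {
  totals <- rowSums(count_matrix(counts))
  kept <- counts[totals >= min_total, , drop = FALSE]
  dropped <- nrow(counts) - nrow(kept)
  if (dropped > 0) {
    inform(sprintf("filter_low_counts: removed %d of %d miRNAs (total < %g)",
                   dropped, nrow(counts), min_total))
  }
  kept
}

#' Median-of-ratios size factors
#'
#' Computes per-sample size factors against a geometric-mean pseudo-reference
#' built from miRNAs with all-positive counts, then rescales so the factors
#' have geometric mean 1. When no miRNA is positive in every sample the
#' function falls back to total-count scaling (with a message).
#'
#' @param counts Count tibble.
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_matrix(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    inform("estimate_size_factors: no miRNA positive in all samples; falling back to total-count scaling")
    sf <- colSums(m)
  } else {
    logref <- rowMeans(log(m[allpos, , drop = FALSE]))
    sf <- apply(m[allpos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - logref)))
  }
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

moment_dispersion <- function(y, offs, group) {
  # method-of-moments on offset-corrected counts, pseudo-count 0.5 here only
  z <- (y + 0.5) / exp(offs)
  ests <- vapply(split(z, group), function(zg) {
    m <- mean(zg); v <- var(zg)
    if (!is.finite(v) || m <= 0) return(NA_real_)
    (v - m) / m^2
  }, numeric(1))
  a <- mean(ests, na.rm = TRUE)
  if (!is.finite(a)) a <- 0
  max(a, 1e-8)
}

#' Negative-binomial Wald test for one compartment
#'
#' Per-miRNA NB log-linear model of counts on condition (CONT reference, so
#' positive log2 fold changes mean higher in CAVIN1) with known offsets
#' (log size factors plus optional RUV components). Dispersion comes from a
#' method-of-moments estimator with a floor of 1e-8 (optionally pooled by
#' trimmed mean across miRNAs); the condition coefficient is tested by a Wald
#' statistic with observed-information standard errors, referred to a t
#' distribution with `n_samples - 2` degrees of freedom (small-sample
#' calibration at n = 3 per group), and Benjamini-Hochberg adjusted across
#' the retained miRNAs.
#'
#' @param counts Count tibble (already filtered).
#' @param samples Sample metadata tibble (`sample_id`, `compartment`,
#'   `condition`).
#' @param compartment `"EV"` or `"cell"`; the test runs within this
#'   compartment only.
#' @param size_factors Tibble from [estimate_size_factors()]; `NULL`
#'   recomputes them from the supplied counts.
#' @param ruv_offsets Optional miRNA x sample offset matrix (natural-log
#'   scale) from [ruv_normalize()].
#' @param config A [diff_config()].
#' @return A tibble with `mirna_id`, `base_mean`, `log2fc`, `se`, `wald_p`,
#'   `bh_q`, `contrast`. miRNA rows that are all-zero within the compartment
#'   are excluded with a message.
#' @export
nb_differential <- function(counts, samples, compartment = c("EV", "cell"),
                            size_factors = NULL, ruv_offsets = NULL,
                            config = diff_config()) {
  compartment <- match.arg(compartment)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  m <- count_matrix(counts)
  keep_samp <- samples$sample_id[samples$compartment == compartment]
  keep_samp <- intersect(colnames(m), keep_samp)
  if (length(keep_samp) < 4L) {
    abort(sprintf("need at least 2 samples per condition in compartment '%s'", compartment),
          class = "mirexport_parameter_error")
  }
  m <- m[, keep_samp, drop = FALSE]
  cond <- samples$condition[match(keep_samp, samples$sample_id)]
  cond <- factor(cond, levels = c("CONT", "CAVIN1"))
  if (any(is.na(cond)) || length(unique(cond)) < 2L) {
    abort("both CONT and CAVIN1 must be present", class = "mirexport_parameter_error")
  }
  sf <- size_factors$size_factor[match(keep_samp, size_factors$sample_id)]
  off_base <- log(sf)
  nz <- rowSums(m) > 0
  if (any(!nz)) {
    inform(sprintf("nb_differential: excluded %d all-zero miRNA rows in '%s'",
                   sum(!nz), compartment))
  }
  ids <- rownames(m)[nz]
  n <- length(keep_samp)
  df_t <- n - 2L

  disp <- vapply(ids, function(id) {
    offs <- off_base + if (is.null(ruv_offsets)) 0 else ruv_offsets[id, keep_samp]
    moment_dispersion(m[id, ], offs, cond)
  }, numeric(1))
  if (isTRUE(config$pool_dispersion)) {
    disp[] <- max(mean(disp, trim = 0.2), 1e-8)
  }

  res <- purrr::map_dfr(seq_along(ids), function(i) {
    id <- ids[i]
    y <- m[id, ]
    offs <- off_base + if (is.null(ruv_offsets)) 0 else ruv_offsets[id, keep_samp]
    fit <- suppressWarnings(tryCatch(
      stats::glm(y ~ cond + offset(offs),
                 family = MASS::negative.binomial(theta = 1 / disp[i])),
      error = function(e) NULL
    ))
    if (is.null(fit)) {
      return(tibble(mirna_id = id, base_mean = mean(y / exp(offs)),
                    log2fc = NA_real_, se = NA_real_, wald_p = NA_real_))
    }
    # dispersion fixed at 1: the NB variance already carries the
    # overdispersion through theta, so no Pearson rescaling of the SEs
    sm <- suppressWarnings(summary(fit, dispersion = 1)$coefficients)
    beta <- sm["condCAVIN1", "Estimate"]
    se_nat <- sm["condCAVIN1", "Std. Error"]
    z <- if (se_nat > 0) beta / se_nat else 0
    p <- 2 * pt(-abs(z), df = df_t)
    tibble(mirna_id = id, base_mean = mean(y / exp(offs)),
           log2fc = beta / log(2), se = se_nat / log(2), wald_p = p)
  })
  res$bh_q <- p.adjust(res$wald_p, method = "BH")
  res$contrast <- compartment
  res
}

#' Select empirical control miRNAs
#'
#' Runs a first-pass differential test per compartment with no RUV factors
#' and returns the `n_controls` miRNAs least associated with condition (the
#' largest per-miRNA minimum p-value across compartments). Deterministic.
#'
#' @param counts,samples Count and metadata tibbles.
#' @param n_controls Number of controls; capped (with a warning) at the
#'   number of retained miRNAs.
#' @param config A [diff_config()].
#' @return Character vector of control miRNA ids.
#' @export
select_empirical_controls <- function(counts, samples, n_controls,
                                      config = diff_config()) {
  comps <- intersect(c("EV", "cell"), unique(samples$compartment))
  first_pass <- purrr::map(comps, function(cp) {
    nb_differential(counts, samples, compartment = cp, config = config)
  })
  p_by_id <- purrr::map_dfr(first_pass, ~ .x[c("mirna_id", "wald_p")]) |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(score = min(.data$wald_p, na.rm = TRUE), .groups = "drop")
  if (n_controls > nrow(p_by_id)) {
    warn(sprintf("n_controls capped at %d retained miRNAs", nrow(p_by_id)))
    n_controls <- nrow(p_by_id)
  }
  p_by_id |>
    dplyr::arrange(dplyr::desc(.data$score), .data$mirna_id) |>
    dplyr::slice_head(n = n_controls) |>
    dplyr::pull("mirna_id")
}

#' RUV-style unwanted-variation offsets
#'
#' Factor analysis (singular value decomposition) of the row-centred log
#' counts of the control miRNAs yields `k` per-sample unwanted-variation
#' factors; every miRNA's centred log counts are then regressed on those
#' factors and the fitted component is returned as a known offset matrix for
#' the NB test. `k = 0` returns all-zero offsets.
#'
#' @param counts Count tibble.
#' @param samples Sample metadata tibble (used for ordering only).
#' @param controls Character vector of control miRNA ids (non-empty when
#'   `k > 0`).
#' @param k Number of factors; must satisfy `k < min(#controls, #samples)`.
#' @param size_factors Optional size-factor tibble; `NULL` recomputes.
#' @return A list with `offsets` (miRNA x sample matrix, natural-log scale)
#'   and `factors` (tibble of per-sample scores `W1..Wk`).
#' @export
ruv_normalize <- function(counts, samples, controls, k = 1,
                          size_factors = NULL) {
  m <- count_matrix(counts)
  if (k == 0) {
    return(list(
      offsets = matrix(0, nrow(m), ncol(m), dimnames = dimnames(m)),
      factors = tibble(sample_id = colnames(m))
    ))
  }
  if (length(controls) == 0L) {
    abort("'controls' must be non-empty when k > 0", class = "mirexport_parameter_error")
  }
  controls <- intersect(rownames(m), controls)
  if (k >= min(length(controls), ncol(m))) {
    abort("'k' must be smaller than both the number of controls and of samples",
          class = "mirexport_parameter_error")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  logm <- log(sweep(m, 2, sf, "/") + 0.5)
  yc <- logm[controls, , drop = FALSE]
  yc <- yc - rowMeans(yc)
  sv <- svd(yc)
  w <- sv$v[, seq_len(k), drop = FALSE]          # samples x k scores
  ylog <- logm - rowMeans(logm)
  beta <- t(solve(crossprod(w), crossprod(w, t(ylog))))  # miRNA x k loadings
  offsets <- beta %*% t(w)
  dimnames(offsets) <- dimnames(m)
  factors <- tibble(sample_id = colnames(m))
  for (j in seq_len(k)) factors[[paste0("W", j)]] <- w[, j]
  list(offsets = offsets, factors = factors)
}

#' Run the EV and cell contrasts end to end
#'
#' Convenience wrapper: filters low counts, estimates size factors, selects
#' empirical controls, computes RUV offsets and runs [nb_differential()] in
#' both compartments.
#'
#' @param counts,samples Count and metadata tibbles.
#' @param config A [diff_config()].
#' @return A list with `ev`, `cell` (result tibbles), `retained` ids,
#'   `size_factors`, `controls` and `ruv` (offset list).
#' @export
differential_pair <- function(counts, samples, config = diff_config()) {
  kept <- filter_low_counts(counts, config$min_total_count)
  sf <- estimate_size_factors(kept)
  n_ctrl <- config$n_empirical_controls %||% max(1L, round(0.2 * nrow(kept)))
  ruv <- NULL
  offsets <- NULL
  controls <- character(0)
  if (config$ruv_k > 0) {
    controls <- select_empirical_controls(kept, samples, n_ctrl, config = config)
    ruv <- ruv_normalize(kept, samples, controls, k = config$ruv_k,
                         size_factors = sf)
    offsets <- ruv$offsets
  }
  list(
    ev = nb_differential(kept, samples, "EV", size_factors = sf,
                         ruv_offsets = offsets, config = config),
    cell = nb_differential(kept, samples, "cell", size_factors = sf,
                           ruv_offsets = offsets, config = config),
    retained = kept$mirna_id,
    size_factors = sf,
    controls = controls,
    ruv = ruv
  )
}
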