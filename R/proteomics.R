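#' Mean-based log2 fold change for one protein
#'
#' `log2(mean_metastatic / mean_early)` using arithmetic means of the
#' normalised intensities, the convention for SWATH group comparisons.
#'
#' @param intensities Intensity tibble (`protein_id` plus sample columns).
#' @param groups Group tibble (`sample_id`, `group` in `early`/`metastatic`).
#' @param protein_id Protein to compute.
#' @return The log2 fold change (numeric scalar).
#' @export
group_log2fc <- function(intensities, groups, protein_id) {
  row <- intensities[intensities$protein_id == protein_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("protein '%s' not found (or duplicated)", protein_id),
          class = "mirexport_value_error")
  }
  early <- unlist(row[groups$sample_id[groups$group == "early"]])
  met <- unlist(row[groups$sample_id[groups$group == "metastatic"]])
  if (length(early) == 0L || length(met) == 0L) {
    abort("both groups must be non-empty", class = "mirexport_value_error")
  }
  m_early <- mean(early)
  m_met <- mean(met)
  if (m_early <= 0 || m_met <= 0) {
    abort("group means must be positive for a log2 ratio",
          class = "mirexport_value_error")
  }
  log2(m_met / m_early)
}

#' Per-protein t-tests and volcano classification
#'
#' For every protein: mean-based log2 fold change (metastatic over early) and
#' a two-sided unpaired t-test on the normalised intensities. Raw p-values
#' are compared to `alpha` with no multiple-testing correction (the volcano
#' convention for this kind of cohort comparison); `direction` is `up`/`down`
#' from the sign of the log2 fold change for significant proteins, `none`
#' otherwise. Proteins with zero variance in both groups and equal means get
#' `p = 1` (logged).
#'
#' @param intensities,groups As in [group_log2fc()].
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   equal-variance Student test (default `FALSE`).
#' @return A `protein_stats` tibble: `protein_id`, `mean_early`, `mean_met`,
#'   `log2fc`, `t_stat`, `p`, `significant`, `direction`.
#' @export
ttest_volcano <- function(intensities, groups, alpha = 0.05, welch = FALSE) {
  check_prob(alpha, "alpha")
  early_cols <- groups$sample_id[groups$group == "early"]
  met_cols <- groups$sample_id[groups$group == "metastatic"]
  if (length(early_cols) < 2L || length(met_cols) < 2L) {
    abort("need at least 2 samples per group", class = "mirexport_parameter_error")
  }
  n_degenerate <- 0L
  res <- purrr::map_dfr(seq_len(nrow(intensities)), function(i) {
    early <- unlist(intensities[i, early_cols])
    met <- unlist(intensities[i, met_cols])
    if (sd(early) == 0 && sd(met) == 0) {
      if (mean(early) == mean(met)) {
        n_degenerate <<- n_degenerate + 1L
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- list(statistic = Inf * sign(mean(met) - mean(early)), p.value = 0)
      }
    } else {
      fit <- t.test(met, early, var.equal = !welch)
      tt <- list(statistic = unname(fit$statistic), p.value = fit$p.value)
    }
    tibble(protein_id = intensities$protein_id[i],
           mean_early = mean(early), mean_met = mean(met),
           log2fc = log2(mean(met) / mean(early)),
           t_stat = tt$statistic, p = tt$p.value)
  })
  if (n_degenerate > 0) {
    inform(sprintf("ttest_volcano: %d zero-variance identical proteins set to p = 1",
                   n_degenerate))
  }
  res$significant <- res$p < alpha
  res$direction <- dplyr::case_when(
    res$significant & res$log2fc > 0 ~ "up",
    res$significant & res$log2fc < 0 ~ "down",
    .default = "none"
  )
  attr(res, "alpha") <- alpha
  attr(res, "welch") <- welch
  class(res) <- c("protein_stats", class(res))
  res
}

#' @export
autoplot.protein_stats <- function(object, label_up = TRUE, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$log2fc, y = -log2(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, ...) +
    ggplot2::geom_hline(yintercept = -log2(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "log2FC (metastatic / early)", y = "-log2 p",
                  colour = paste0("p < ", alpha))
  if (label_up) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(object, .data$direction == "up"),
      ggplot2::aes(label = .data$protein_id),
      vjust = -0.6, size = 2.8, show.legend = FALSE
    )
  }
  p
}
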