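#' Fold enrichment of EV over cellular change
#'
#' The selective-export statistic: `FE = log2FC_EV - log2FC_cell`. A miRNA
#' whose EV abundance drops more than its cellular abundance under the same
#' perturbation has negative FE.
#'
#' @param log2fc_ev,log2fc_cell Finite log2 fold changes (CAVIN1 vs CONT)
#'   from the EV and cell contrasts; vectorised.
#' @return `log2fc_ev - log2fc_cell`.
#' @export
#' @examples
#' compute_fold_enrichment(-1.5, 0.2)
compute_fold_enrichment <- function(log2fc_ev, log2fc_cell) {
  if (any(!is.finite(log2fc_ev)) || any(!is.finite(log2fc_cell))) {
    abort("fold enrichment requires finite log2 fold changes",
          class = "mirexport_value_error")
  }
  log2fc_ev - log2fc_cell
}

#' Classification thresholds for selective export
#'
#' The default thresholds flag miRNAs at least two-fold *decreased* in EVs
#' under CAVIN1 (`log2fc_ev <= -1`) and depleted in EVs relative to cells
#' (`FE <= -0.5`); both comparisons are inclusive, so boundary rows select.
#' `direction = "up"` mirrors the test with `>=` and sign-flipped thresholds.
#'
#' @param tau_ev Threshold on the EV log2 fold change.
#' @param tau_fe Threshold on the fold enrichment.
#' @param direction `"down"` (default) or `"up"`.
#' @return An `export_config` list.
#' @export
export_config <- function(tau_ev = -1, tau_fe = -0.5,
                          direction = c("down", "up")) {
  structure(list(tau_ev = tau_ev, tau_fe = tau_fe,
                 direction = match.arg(direction)),
            class = "export_config")
}

#' Classify selectively exported miRNAs
#'
#' Applies the combined fold-enrichment criterion to a per-miRNA table of EV
#' and cellular log2 fold changes: a miRNA is selected when *both*
#' `log2fc_ev <= tau_ev` and `FE = log2fc_ev - log2fc_cell <= tau_fe` hold
#' (inclusive; mirrored for `direction = "up"`). Rows with a missing value in
#' either column are excluded with a message (FE is undefined for them).
#' Output order equals input order.
#'
#' @param table Tibble with columns `mirna_id`, `log2fc_ev`, `log2fc_cell`.
#' @param config An [export_config()].
#' @return A tibble with `mirna_id`, `log2fc_ev`, `log2fc_cell`, `fe`,
#'   `selected`, of class `export_table`.
#' @export
#' @examples
#' classify_selective_export(
#'   tibble::tibble(mirna_id = c("a", "b"),
#'                  log2fc_ev = c(-1.5, -0.5),
#'                  log2fc_cell = c(0.2, -1.0))
#' )
classify_selective_export <- function(table, config = export_config()) {
  stopifnot(all(c("mirna_id", "log2fc_ev", "log2fc_cell") %in% names(table)))
  if (anyDuplicated(table$mirna_id)) {
    abort("duplicate miRNA ids in classification input",
          class = "mirexport_value_error")
  }
  ok <- is.finite(table$log2fc_ev) & is.finite(table$log2fc_cell)
  if (any(!ok)) {
    inform(sprintf("classify_selective_export: excluded %d rows with missing log2FC",
                   sum(!ok)))
    table <- table[ok, , drop = FALSE]
  }
  fe <- compute_fold_enrichment(table$log2fc_ev, table$log2fc_cell)
  selected <- if (config$direction == "down") {
    table$log2fc_ev <= config$tau_ev & fe <= config$tau_fe
  } else {
    table$log2fc_ev >= -config$tau_ev & fe >= -config$tau_fe
  }
  out <- tibble(mirna_id = table$mirna_id,
                log2fc_ev = table$log2fc_ev,
                log2fc_cell = table$log2fc_cell,
                fe = fe,
                selected = selected)
  class(out) <- c("export_table", class(out))
  attr(out, "config") <- config
  out
}

#' Join the EV and cell contrasts into a classification input
#'
#' Inner-joins the two differential result tibbles on `mirna_id`; miRNAs
#' present in only one compartment are dropped with a message.
#'
#' @param ev,cell Result tibbles from [nb_differential()].
#' @return A tibble with `mirna_id`, `log2fc_ev`, `log2fc_cell`.
#' @export
join_contrasts <- function(ev, cell) {
  joined <- dplyr::inner_join(
    dplyr::select(ev, "mirna_id", log2fc_ev = "log2fc"),
    dplyr::select(cell, "mirna_id", log2fc_cell = "log2fc"),
    by = "mirna_id"
  )
  dropped <- nrow(ev) + nrow(cell) - 2L * nrow(joined)
  if (dropped > 0) {
    inform(sprintf("join_contrasts: %d single-compartment records dropped", dropped))
  }
  joined
}

#' @export
autoplot.export_table <- function(object, ...) {
  cfg <- attr(object, "config") %||% export_config()
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc_cell, y = .data$log2fc_ev,
                               colour = .data$selected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = cfg$tau_fe,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = cfg$tau_ev, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_point(alpha = 0.7, ...) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "log2FC cell (CAVIN1 vs CONT)",
                  y = "log2FC EV (CAVIN1 vs CONT)",
                  colour = "selected")
}
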