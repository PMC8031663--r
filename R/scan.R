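#' Percent-of-range similarity of a sequence to a motif
#'
#' Scores every width-W window of the sequence with the log-odds sum
#' `S = sum_pos log(theta[pos, base] / theta0[base])` and maps it to a
#' percentage of the attainable range: `100 * (S - S_min) / (S_max - S_min)`,
#' where `S_max`/`S_min` are the per-window maximum and minimum of the same
#' sum. 100 means the window takes the PWM's argmax base at every position;
#' 0 means the argmin base throughout. For a point-mass PWM this reduces to
#' the fraction of consensus matches. Returns the window maximising the
#' similarity (leftmost on ties).
#'
#' Because the attainable minimum otherwise depends on near-zero PWM entries
#' (which reflect the discovery pseudocounts, not the motif), the PWM is
#' regularised before the log-odds are formed: each row is blended with
#' `pseudo` parts background, `theta_scan = (theta + pseudo * theta0) /
#' (1 + pseudo)`. This bounds the per-column floor, keeps the argmax window
#' at 100, and preserves the fraction-of-matches reduction for point-mass
#' PWMs.
#'
#' @param sequence A single RNA string of length >= the motif width.
#' @param model A `motif_model` (or anything with `pwm` and `background`).
#' @param mirna_id Optional id carried into the result.
#' @param pseudo Background mass blended into each PWM row (default 0.25).
#' @return A one-row tibble: `mirna_id`, `best_position` (0-based),
#'   `similarity` (percent), `matched_subsequence`.
#' @export
similarity_score <- function(sequence, model, mirna_id = NA_character_,
                             pseudo = 0.25) {
  W <- nrow(model$pwm)
  if (nchar(sequence) < W) {
    abort(sprintf("sequence '%s' is shorter than the motif width %d",
                  mirna_id, W),
          class = "mirexport_value_error")
  }
  theta <- (model$pwm + pseudo * matrix(model$background, W, 4, byrow = TRUE)) /
    (1 + pseudo)
  logLR <- log(theta) - matrix(log(model$background), W, 4, byrow = TRUE)
  codes <- seq_to_codes(sequence)
  n_win <- length(codes) - W + 1L
  s <- numeric(n_win)
  for (w in seq_len(W)) s <- s + logLR[w, ][codes[w:(w + n_win - 1L)]]
  s_max <- sum(apply(logLR, 1, max))
  s_min <- sum(apply(logLR, 1, min))
  sim <- unname(100 * (s - s_min) / (s_max - s_min))
  best <- which.max(sim)  # leftmost tie
  tibble(mirna_id = mirna_id,
         best_position = best - 1L,
         similarity = sim[best],
         matched_subsequence = substr(sequence, best, best + W - 1L))
}

#' Scan a sequence set against a motif
#'
#' One hit record per scannable sequence; `above_threshold` is strict
#' (`similarity > threshold`, matching an "over X%" rule). Sequences shorter
#' than the motif width are reported as non-scannable with `NA` similarity
#' and a message.
#'
#' @param sequences Tibble with `mirna_id` and `sequence`.
#' @param model A `motif_model`.
#' @param threshold Similarity threshold in percent (default 70).
#' @param pseudo Background mass for the scan log-odds (see
#'   [similarity_score()]).
#' @return A `scan_hits` tibble: `mirna_id`, `best_position`, `similarity`,
#'   `matched_subsequence`, `above_threshold`, `scannable`.
#' @export
scan_set <- function(sequences, model, threshold = 70, pseudo = 0.25) {
  W <- nrow(model$pwm)
  scannable <- nchar(sequences$sequence) >= W
  if (any(!scannable)) {
    inform(sprintf("scan_set: %d sequences shorter than width %d are not scannable (%s)",
                   sum(!scannable), W,
                   paste(sequences$mirna_id[!scannable], collapse = ", ")))
  }
  hits <- purrr::map2_dfr(sequences$sequence, sequences$mirna_id, function(s, id) {
    if (nchar(s) < W) {
      tibble(mirna_id = id, best_position = NA_integer_,
             similarity = NA_real_, matched_subsequence = NA_character_)
    } else {
      similarity_score(s, model, mirna_id = id, pseudo = pseudo)
    }
  })
  hits$above_threshold <- !is.na(hits$similarity) & hits$similarity > threshold
  hits$scannable <- scannable
  attr(hits, "threshold") <- threshold
  class(hits) <- c("scan_hits", class(hits))
  hits
}

hypergeom_upper_tail <- function(k, K, N, n) {
  # P[X >= k] drawing n from a population of N with K successes
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Motif enrichment of a foreground against a background set
#'
#' Counts above-threshold sequences in a foreground and a background set and
#' reports the enrichment score (ratio of hit fractions), the overlapping
#' hypergeometric tail (drawing `fg_total` from a population of `bg_total`
#' with `bg_hits` successes), and a disjoint group-specificity variant in
#' which the foreground is first removed from the background when `fg` is a
#' subset of `bg` (drawing `fg_total` from the remaining
#' `bg_total - fg_total` population with `bg_hits - fg_hits` successes). The
#' headline p-value is the disjoint variant.
#'
#' @param fg,bg Foreground and background sequence tibbles (`mirna_id`,
#'   `sequence`); `fg` may be contained in `bg`.
#' @param model A `motif_model`.
#' @param threshold Similarity threshold in percent.
#' @param pseudo Background mass for the scan log-odds (see
#'   [similarity_score()]).
#' @return A one-row tibble: `fg_total`, `fg_hits`, `bg_total`, `bg_hits`,
#'   `enrichment_score`, `hypergeom_p`, `church_specificity_p`.
#' @export
enrichment_test <- function(fg, bg, model, threshold = 70, pseudo = 0.25) {
  fg_scan <- scan_set(fg, model, threshold, pseudo = pseudo)
  bg_scan <- scan_set(bg, model, threshold, pseudo = pseudo)
  fg_total <- sum(fg_scan$scannable)
  bg_total <- sum(bg_scan$scannable)
  fg_hits <- sum(fg_scan$above_threshold)
  bg_hits <- sum(bg_scan$above_threshold)

  fg_frac <- fg_hits / fg_total
  bg_frac <- bg_hits / bg_total
  score <- if (bg_hits == 0) {
    if (fg_hits > 0) Inf else NaN
  } else {
    fg_frac / bg_frac
  }
  hyper_p <- hypergeom_upper_tail(fg_hits, bg_hits, bg_total, fg_total)

  nested <- all(fg$mirna_id %in% bg$mirna_id)
  church_p <- if (nested && bg_total > fg_total) {
    hypergeom_upper_tail(fg_hits, bg_hits - fg_hits, bg_total - fg_total, fg_total)
  } else {
    hypergeom_upper_tail(fg_hits, fg_hits + bg_hits, fg_total + bg_total, fg_total)
  }

  tibble(fg_total = fg_total, fg_hits = fg_hits,
         bg_total = bg_total, bg_hits = bg_hits,
         enrichment_score = score,
         hypergeom_p = hyper_p,
         church_specificity_p = church_p)
}

#' Positional alignment report for above-threshold hits
#'
#' Emits `mirna_id`, `best_position`, `matched_subsequence` and `similarity`
#' for every above-threshold hit, sorted by id - the table behind
#' "no positional preference" summaries.
#'
#' @param hits A `scan_hits` tibble from [scan_set()].
#' @return A tibble (possibly empty, header only when written).
#' @export
positional_alignment_report <- function(hits) {
  hits |>
    dplyr::filter(.data$above_threshold) |>
    dplyr::select("mirna_id", "best_position", "matched_subsequence",
                  "similarity") |>
    dplyr::arrange(.data$mirna_id)
}

#' @export
autoplot.scan_hits <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 70
  ggplot2::ggplot(dplyr::filter(object, .data$scannable),
                  ggplot2::aes(x = .data$similarity,
                               fill = .data$above_threshold)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, ...) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#0072B2")) +
    ggplot2::labs(x = "similarity to motif (%)", y = "sequences",
                  fill = paste0("> ", thr, "%"))
}
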