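#' Settings for ZOOPS motif discovery
#'
#' Controls the expectation-maximisation search for a single ungapped motif
#' under the zero-or-one-occurrence-per-sequence (ZOOPS) site model over
#' widths `w_min..w_max`.
#'
#' @param w_min,w_max Motif width range (mature miRNAs are short, so small
#'   widths; defaults 4 and 10).
#' @param n_restarts Random EM starts per width, in addition to one start
#'   seeded from each distinct observed substring of the width (capped at
#'   `seed_cap`, sampled deterministically from the sequence content).
#' @param max_iter,tol EM stopping rule: relative change of the (penalised)
#'   log likelihood below `tol`, or `max_iter` iterations.
#' @param pseudocount Total Dirichlet mass added to each PWM row, distributed
#'   proportionally to the background frequencies.
#' @param seed Integer seed for the restart RNG (combined with a
#'   content-derived key so results do not depend on input order).
#' @param seed_cap Maximum number of substring-seeded starts per width.
#' @param screen_iter,n_refine All starts run `screen_iter` EM iterations;
#'   the best `n_refine` by likelihood are run to convergence.
#' @param n_shuffles Shuffled replicates for the empirical e-value.
#' @return A `zoops_config` list.
#' @export
zoops_config <- function(w_min = 4, w_max = 10, n_restarts = 20,
                         max_iter = 200, tol = 1e-6, pseudocount = 0.01,
                         seed = 1L, seed_cap = 500, screen_iter = 2,
                         n_refine = 5, n_shuffles = 200) {
  w_min <- check_count(w_min, "w_min", min = 1L)
  w_max <- check_count(w_max, "w_max", min = w_min)
  if (tol <= 0) abort("'tol' must be > 0", class = "mirexport_parameter_error")
  structure(list(w_min = w_min, w_max = w_max, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol, pseudocount = pseudocount,
                 seed = as.integer(seed), seed_cap = seed_cap,
                 screen_iter = screen_iter, n_refine = n_refine,
                 n_shuffles = n_shuffles),
            class = "zoops_config")
}

#' Pooled mononucleotide background frequencies
#'
#' 0-order background estimated from the input sequences themselves.
#'
#' @param sequences Tibble with a `sequence` column (or a character vector).
#' @return Named numeric 4-vector (A, C, G, U) summing to 1.
#' @export
build_background <- function(sequences) {
  seqs <- if (is.character(sequences)) sequences else sequences$sequence
  if (length(seqs) == 0L) {
    abort("cannot build a background from an empty sequence set",
          class = "mirexport_value_error")
  }
  codes <- unlist(lapply(seqs, seq_to_codes))
  freqs <- tabulate(codes, nbins = 4L) / length(codes)
  setNames(freqs, RNA_BASES)
}

# Stack every width-W window of the coded sequences into an integer matrix.
prep_windows <- function(codes_list, W) {
  per <- lengths(codes_list) - W + 1L
  X <- matrix(0L, sum(per), W)
  row <- 0L
  for (i in seq_along(codes_list)) {
    s <- codes_list[[i]]
    for (w in seq_len(W)) {
      X[row + seq_len(per[i]), w] <- s[w:(w + per[i] - 1L)]
    }
    row <- row + per[i]
  }
  list(X = X, seq_idx = rep(seq_along(codes_list), per), m = per)
}

window_scores <- function(X, logLR) {
  s <- numeric(nrow(X))
  for (w in seq_len(ncol(X))) s <- s + logLR[w, ][X[, w]]
  s
}

# One EM run from a given start; returns the fitted state and objective trace.
zoops_em_run <- function(win, n_seq, theta, lambda, theta0, pc_row,
                         max_iter, tol, bg_const) {
  X <- win$X; seq_idx <- win$seq_idx; m <- win$m
  W <- ncol(X)
  obj_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logLR <- log(theta) - matrix(log(theta0), W, 4, byrow = TRUE)
    r <- exp(window_scores(X, logLR))
    rs <- as.numeric(rowsum(r, seq_idx))
    denom <- (1 - lambda) + (lambda / m) * rs
    loglik <- sum(log(denom)) + bg_const
    z <- (lambda / m[seq_idx]) * r / denom[seq_idx]

    tot_z <- sum(z)
    cnt <- matrix(0, W, 4)
    for (w in seq_len(W)) {
      cnt[w, ] <- vapply(1:4, function(b) sum(z[X[, w] == b]), numeric(1))
    }
    theta <- (cnt + matrix(pc_row, W, 4, byrow = TRUE)) / (tot_z + sum(pc_row))
    lambda <- min(max(tot_z / n_seq, 1e-8), 1 - 1e-8)

    obj <- loglik + sum(matrix(pc_row, W, 4, byrow = TRUE) * log(theta))
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) <= tol * (abs(obj_old) + 1e-12)) {
      converged <- TRUE
      obj_old <- obj
      break
    }
    obj_old <- obj
  }
  # final E-step quantities under the final parameters
  logLR <- log(theta) - matrix(log(theta0), W, 4, byrow = TRUE)
  r <- exp(window_scores(X, logLR))
  rs <- as.numeric(rowsum(r, seq_idx))
  denom <- (1 - lambda) + (lambda / m) * rs
  loglik <- sum(log(denom)) + bg_const
  list(theta = theta, lambda = lambda, loglik = loglik,
       obj = obj_old, obj_trace = obj_trace, converged = converged,
       r = r, denom = denom)
}

dirichlet1_rows <- function(n, k = 4L) {
  g <- matrix(-log(runif(n * k)), n, k)
  g / rowSums(g)
}

seed_theta <- function(wmer_codes, theta0, match_prob = 0.55) {
  W <- length(wmer_codes)
  theta <- matrix(rep(theta0, each = W), W, 4)
  for (w in seq_len(W)) {
    rest <- theta[w, ]
    rest[wmer_codes[w]] <- 0
    theta[w, ] <- rest / sum(rest) * (1 - match_prob)
    theta[w, wmer_codes[w]] <- match_prob
  }
  theta
}

#' Fit a ZOOPS motif of fixed width by expectation-maximisation
#'
#' The ZOOPS model assumes each sequence carries at most one motif site: with
#' probability `lambda` a site sits at one of the `L - W + 1` start positions
#' (uniform prior), otherwise the whole sequence is background. The E-step
#' computes per-start responsibilities proportional to
#' `lambda/(L-W+1) * prod theta[pos, base] / prod theta0[base]` (no-site mass
#' proportional to `1 - lambda`); the M-step re-estimates the PWM from
#' responsibility-weighted base counts plus background-proportional
#' pseudocounts, and `lambda` from the total site mass. Multiple starts are
#' used: one seeded from each distinct observed W-mer (capped) plus random
#' restarts; all starts are screened for a few iterations and the best few
#' refined to convergence. Deterministic given `config$seed` and invariant to
#' input sequence order.
#'
#' @param sequences Tibble with `mirna_id` and `sequence`; every sequence
#'   must be at least `W` long.
#' @param W Motif width.
#' @param background Background 4-vector; `NULL` uses [build_background()].
#' @param config A [zoops_config()].
#' @return A `motif_model`: list with `width`, `pwm` (W x 4, rows summing to
#'   1), `background`, `lambda`, `loglik`, `llr` (log-likelihood ratio vs the
#'   background-only model), `obj_trace` (penalised objective per iteration
#'   of the winning run, non-decreasing), `site_posteriors` (tibble with the
#'   best start position, its responsibility and the no-site mass per
#'   sequence), `consensus`, `e_value` (`NA` until calibrated) and
#'   `converged`.
#' @export
zoops_em <- function(sequences, W, background = NULL, config = zoops_config()) {
  W <- check_count(W, "W", min = 1L)
  too_short <- nchar(sequences$sequence) < W
  if (any(too_short)) {
    abort(sprintf("sequence '%s' is shorter than the motif width %d",
                  sequences$mirna_id[too_short][1], W),
          class = "mirexport_value_error")
  }
  theta0 <- background %||% build_background(sequences)
  theta0 <- pmax(theta0, 1e-9)
  theta0 <- theta0 / sum(theta0)
  codes_list <- lapply(sequences$sequence, seq_to_codes)
  win <- prep_windows(codes_list, W)
  n_seq <- length(codes_list)
  pc_row <- config$pseudocount * theta0
  bg_const <- sum(log(theta0)[unlist(codes_list)])

  # starts: distinct W-mers (sorted; deterministically subsampled past the
  # cap) + random restarts, RNG keyed to sequence content not order
  wmers <- sort(unique(apply(win$X, 1, paste, collapse = "")))
  key <- (config$seed + content_key(sequences$sequence)) %% 2147483647
  starts <- with_seed(key, {
    if (length(wmers) > config$seed_cap) {
      wmers <- sort(sample(wmers, config$seed_cap))
    }
    seeded <- lapply(wmers, function(s) {
      list(theta = seed_theta(as.integer(strsplit(s, "")[[1]]), theta0),
           lambda = 0.5)
    })
    random <- lapply(seq_len(config$n_restarts), function(i) {
      list(theta = dirichlet1_rows(W), lambda = runif(1, 0.2, 0.8))
    })
    c(seeded, random)
  })

  screened <- vapply(starts, function(st) {
    zoops_em_run(win, n_seq, st$theta, st$lambda, theta0, pc_row,
                 max_iter = config$screen_iter, tol = 0, bg_const = bg_const)$obj
  }, numeric(1))
  top <- order(-screened)[seq_len(min(config$n_refine, length(starts)))]
  best <- NULL
  for (i in top) {
    fit <- zoops_em_run(win, n_seq, starts[[i]]$theta, starts[[i]]$lambda,
                        theta0, pc_row, max_iter = config$max_iter,
                        tol = config$tol, bg_const = bg_const)
    if (is.null(best) || fit$obj > best$obj) best <- fit
  }

  # per-sequence site posteriors under the fitted model
  z <- (best$lambda / win$m[win$seq_idx]) * best$r / best$denom[win$seq_idx]
  z_by_seq <- split(z, win$seq_idx)
  site_posteriors <- tibble(
    mirna_id = sequences$mirna_id,
    best_position = vapply(z_by_seq, which.max, integer(1)) - 1L,
    site_posterior = vapply(z_by_seq, max, numeric(1)),
    no_site_mass = (1 - best$lambda) / best$denom
  )

  pwm <- best$theta
  dimnames(pwm) <- list(position = seq_len(W), base = RNA_BASES)
  structure(list(
    width = W,
    pwm = pwm,
    background = theta0,
    lambda = best$lambda,
    loglik = best$loglik,
    llr = best$loglik - bg_const,
    obj_trace = best$obj_trace,
    site_posteriors = site_posteriors,
    consensus = consensus_from_pwm(pwm),
    e_value = NA_real_,
    n_widths_scanned = 1L,
    converged = best$converged
  ), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("ZOOPS motif model: width %d, consensus %s\n", x$width, x$consensus))
  cat(sprintf("  lambda = %.3f, log-likelihood ratio = %.2f, e-value = %s\n",
              x$lambda, x$llr,
              if (is.na(x$e_value)) "not calibrated" else format(x$e_value)))
  invisible(x)
}

#' Degenerate IUPAC consensus of a PWM
#'
#' Per column: the single base (uppercase) when its probability is at least
#' 0.5 and at least twice the runner-up; the two-base IUPAC code (lowercase,
#' e.g. `s` = C/G) when the top two sum to at least 0.75; otherwise `n`.
#'
#' @param pwm A W x 4 probability matrix with columns A, C, G, U.
#' @return A degenerate RNA string of length W.
#' @export
consensus_from_pwm <- function(pwm) {
  code2 <- c("AG" = "r", "CU" = "y", "CG" = "s", "AU" = "w",
             "GU" = "k", "AC" = "m")
  vapply(seq_len(nrow(pwm)), function(w) {
    p <- pwm[w, ]
    ord <- order(-p)
    if (p[ord[1]] >= 0.5 && p[ord[1]] >= 2 * p[ord[2]]) {
      RNA_BASES[ord[1]]
    } else if (p[ord[1]] + p[ord[2]] >= 0.75) {
      pair <- paste(sort(RNA_BASES[ord[1:2]]), collapse = "")
      unname(code2[pair])
    } else {
      "n"
    }
  }, character(1)) |> paste(collapse = "")
}

shuffle_sequences <- function(seqs) {
  vapply(seqs, function(s) {
    codes <- seq_to_codes(s)
    codes_to_seq(codes[sample.int(length(codes))])
  }, character(1), USE.NAMES = FALSE)
}

#' Empirical e-value for a fitted motif
#'
#' Calibrates the motif's log-likelihood ratio (fitted ZOOPS model vs the
#' background-only model) against `n_shuffles` mononucleotide-shuffled copies
#' of the input set, with the EM re-run at the same width on every shuffle
#' (lighter start/iteration settings). The e-value is
#' `(1 + #[shuffled LLR >= observed]) / (1 + n_shuffles)` times the number of
#' widths scanned (Bonferroni over widths), so the smallest reportable value
#' is `n_widths / (1 + n_shuffles)`.
#'
#' @param model A fitted `motif_model`.
#' @param sequences The sequence tibble the model was fitted to.
#' @param n_shuffles Number of shuffled replicates (a warning is issued below
#'   20).
#' @param seed Integer seed for the shuffles.
#' @param n_widths Width-scan multiplier (defaults to the model's record).
#' @return The empirical e-value (numeric scalar).
#' @export
motif_evalue <- function(model, sequences, n_shuffles = 200, seed = 1L,
                         n_widths = model$n_widths_scanned) {
  if (n_shuffles < 20) {
    warn("motif_evalue: fewer than 20 shuffles gives a coarse calibration")
  }
  cheap <- zoops_config(w_min = model$width, w_max = model$width,
                        n_restarts = 5, max_iter = 40, tol = 1e-5,
                        seed_cap = 60, screen_iter = 1, n_refine = 1,
                        seed = seed)
  null_llr <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      shuf <- tibble(mirna_id = sequences$mirna_id,
                     sequence = shuffle_sequences(sequences$sequence))
      fit <- zoops_em(shuf, model$width, background = model$background,
                      config = cheap)
      fit$llr
    }, numeric(1))
  })
  e <- (1 + sum(null_llr >= model$llr)) / (1 + n_shuffles) * n_widths
  attr(e, "shuffle_z") <- (model$llr - mean(null_llr)) /
    max(sd(null_llr), .Machine$double.eps)
  e
}

#' Discover the best motif across a width range
#'
#' Runs [zoops_em()] for every width in `config$w_min..config$w_max`
#' (sequences shorter than a width are dropped for that width, with a
#' message), calibrates each candidate with [motif_evalue()], and returns the
#' minimum-e-value model; ties are broken by higher log likelihood, then
#' smaller width. Only the single best motif is reported.
#'
#' @param sequences Tibble with `mirna_id` and `sequence`.
#' @param config A [zoops_config()].
#' @param background Optional background 4-vector; `NULL` pools from input.
#' @return The winning `motif_model` with its `e_value` set and
#'   `n_widths_scanned` recorded.
#' @export
discover_motif <- function(sequences, config = zoops_config(),
                           background = NULL) {
  widths <- seq(config$w_min, config$w_max)
  widths <- widths[widths <= max(nchar(sequences$sequence))]
  if (length(widths) == 0L) {
    abort("no feasible motif width for these sequences",
          class = "mirexport_value_error")
  }
  theta0 <- background %||% build_background(sequences)
  candidates <- lapply(widths, function(W) {
    usable <- sequences[nchar(sequences$sequence) >= W, , drop = FALSE]
    if (nrow(usable) < nrow(sequences)) {
      inform(sprintf("discover_motif: width %d drops %d too-short sequences",
                     W, nrow(sequences) - nrow(usable)))
    }
    model <- zoops_em(usable, W, background = theta0, config = config)
    e <- motif_evalue(model, usable, n_shuffles = config$n_shuffles,
                      seed = config$seed, n_widths = length(widths))
    model$e_value <- as.numeric(e)
    model$shuffle_z <- attr(e, "shuffle_z")
    model$n_widths_scanned <- length(widths)
    model
  })
  evals <- vapply(candidates, function(m) m$e_value, numeric(1))
  # e-values are discrete and often tie at the Bonferroni floor; raw log
  # likelihoods are not comparable across widths (wider models always score
  # higher through the lambda/m site-position term), so ties go to the
  # candidate furthest above its own shuffle null, then to the smaller width
  zs <- vapply(candidates, function(m) m$shuffle_z, numeric(1))
  best <- order(evals, -zs, widths)[1]
  candidates[[best]]
}

#' @export
tidy.motif_model <- function(x, ...) {
  as_tibble(x$pwm) |>
    dplyr::mutate(position = seq_len(x$width), .before = 1) |>
    tidyr::pivot_longer(-"position", names_to = "base", values_to = "probability")
}

#' @export
glance.motif_model <- function(x, ...) {
  tibble(width = x$width, consensus = x$consensus, lambda = x$lambda,
         loglik = x$loglik, llr = x$llr, e_value = x$e_value,
         converged = x$converged)
}

#' @export
autoplot.motif_model <- function(object, ...) {
  df <- tidy(object)
  # information-content scaling, the conventional logo-style height
  ic <- df |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(ic = 2 + sum(.data$probability * log2(.data$probability)),
                  height = .data$probability * .data$ic) |>
    dplyr::ungroup()
  ggplot2::ggplot(ic, ggplot2::aes(x = factor(.data$position), y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "motif position", y = "information content (bits)",
                  title = paste("consensus:", object$consensus))
}

#' Serialise a motif model to a text block
#'
#' Stable plain-text format (width, lambda, e-value, background, PWM rows to
#' 6 decimals, consensus) consumed by the scanner.
#'
#' @param model A `motif_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_model <- function(model, path) {
  lines <- c(
    sprintf("width\t%d", model$width),
    sprintf("lambda\t%.6f", model$lambda),
    sprintf("e_value\t%s", format(model$e_value, digits = 6)),
    sprintf("consensus\t%s", model$consensus),
    paste0("background\t", paste(sprintf("%.6f", model$background), collapse = "\t")),
    vapply(seq_len(model$width), function(w) {
      paste0("pwm\t", paste(sprintf("%.6f", model$pwm[w, ]), collapse = "\t"))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialised motif model
#'
#' @param path Path written by [write_motif_model()].
#' @return A `motif_model` (without site posteriors or likelihood trace).
#' @export
read_motif_model <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  keys <- vapply(fields, `[[`, character(1), 1)
  val <- function(k) fields[[match(k, keys)]][-1]
  pwm <- do.call(rbind, lapply(fields[keys == "pwm"],
                               function(f) as.numeric(f[-1])))
  dimnames(pwm) <- list(position = seq_len(nrow(pwm)), base = RNA_BASES)
  structure(list(
    width = as.integer(val("width")),
    pwm = pwm,
    background = setNames(as.numeric(val("background")), RNA_BASES),
    lambda = as.numeric(val("lambda")),
    loglik = NA_real_, llr = NA_real_, obj_trace = numeric(0),
    site_posteriors = NULL,
    consensus = val("consensus"),
    e_value = suppressWarnings(as.numeric(val("e_value"))),
    n_widths_scanned = 1L,
    converged = NA
  ), class = "motif_model")
}
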