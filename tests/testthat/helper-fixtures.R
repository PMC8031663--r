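# Shared fixture builders; everything is generated in code at test time.

# Point-mass motif model for a literal RNA word, uniform background.
point_mass_model <- function(word, eps = 1e-6) {
  codes <- match(strsplit(word, "")[[1]], c("A", "C", "G", "U"))
  W <- length(codes)
  pwm <- matrix(eps / 3, W, 4, dimnames = list(position = seq_len(W),
                                               base = c("A", "C", "G", "U")))
  for (w in seq_len(W)) pwm[w, codes[w]] <- 1 - eps
  structure(list(width = W, pwm = pwm,
                 background = stats::setNames(rep(0.25, 4), c("A", "C", "G", "U")),
                 lambda = 0.5, loglik = NA_real_, llr = NA_real_,
                 obj_trace = numeric(0), site_posteriors = NULL,
                 consensus = word, e_value = NA_real_,
                 n_widths_scanned = 1L, converged = TRUE),
            class = "motif_model")
}

random_sequences <- function(n, len, seed = 1, freqs = rep(0.25, 4)) {
  withr::with_seed(seed, {
    tibble::tibble(
      mirna_id = sprintf("rnd-%03d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "U"), len, TRUE, prob = freqs),
              collapse = "")
      }, character(1))
    )
  })
}

# Maximum number of positions (over all offsets) at which the allowed base
# sets of two degenerate IUPAC strings intersect.
consensus_overlap <- function(consensus, target) {
  allowed <- function(s) lapply(strsplit(s, "")[[1]], mirexport:::iupac_allowed)
  a <- allowed(consensus); b <- allowed(target)
  best <- 0L
  for (shift in seq(-(length(a) - 1L), length(b) - 1L)) {
    hits <- 0L
    for (i in seq_along(a)) {
      j <- i + shift
      if (j >= 1L && j <= length(b) &&
          length(intersect(a[[i]], b[[j]])) > 0L) {
        hits <- hits + 1L
      }
    }
    best <- max(best, hits)
  }
  best
}
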