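# Fixed positive-class preference profile used at signal_strength = 1:
# the ten flank positions immediately around the central adenosine
# (offsets -5..-1 and +1..+5) draw from this composition, emulating a strong
# G-enrichment adjacent to the edited site. The constant is deliberately
# frozen so generated datasets are stable across package versions.
SIGNAL_PROFILE <- c(A = 0.05, C = 0.05, G = 0.85, U = 0.05)
SIGNAL_OFFSETS <- c(-5:-1, 1:5)

#' Generate a labeled synthetic window dataset
#'
#' Produces balanced sets of adenosine-centered windows for exercising the
#' full pipeline without external data. Negative windows draw every
#' non-center position i.i.d. from `background`. Positive windows use, at the
#' ten flank offsets -5..-1 and +1..+5, a position-specific composition
#' interpolated between `background` (at `signal_strength = 0`) and a fixed
#' G-enriched preference profile (at `signal_strength = 1`); all other
#' positions stay at `background`. The center is always `A` in both classes.
#' At zero signal the two classes are therefore statistically
#' indistinguishable; at full signal they are separable with high
#' probability.
#'
#' @param n_pos,n_neg Number of positive / negative windows (default 200
#'   each).
#' @param xi Flank size (default 25; windows are 2*xi + 1 = 51 nt).
#' @param signal_strength Real in `[0, 1]` scaling the positional
#'   composition bias of the positive class (default 1).
#' @param background Length-4 probability vector over (A, C, G, U) for
#'   unbiased positions (default uniform).
#' @param seed Integer seed; output is reproducible from it.
#' @return A labeled window tibble; `source_id` encodes class and index
#'   (`sim_pos_1`, ...), `center_pos` is `xi + 1`.
#' @export
#' @examples
#' d <- simulate_editing_windows(n_pos = 5, n_neg = 5, xi = 3, seed = 1)
#' d$residues
simulate_editing_windows <- function(n_pos = 200, n_neg = 200, xi = 25,
                                     signal_strength = 1,
                                     background = c(0.25, 0.25, 0.25, 0.25),
                                     seed = 1) {
  if (!is.numeric(background) || length(background) != 4 ||
      any(background < 0) || abs(sum(background) - 1) > 1e-8) {
    abort("`background` must be 4 probabilities summing to 1",
          class = "inosine_invalid_input")
  }
  if (!is.numeric(signal_strength) || signal_strength < 0 ||
      signal_strength > 1) {
    abort("`signal_strength` must lie in [0, 1]",
          class = "inosine_invalid_input")
  }
  stopifnot(xi >= 1, n_pos >= 0, n_neg >= 0)
  xi <- as.integer(xi)
  L <- 2L * xi + 1L
  background <- stats::setNames(background, names(SIGNAL_PROFILE))
  # per-position composition matrix for each class (positions x ACGU)
  neg_comp <- matrix(background, nrow = L, ncol = 4, byrow = TRUE)
  pos_comp <- neg_comp
  biased <- xi + 1L + SIGNAL_OFFSETS
  biased <- biased[biased >= 1 & biased <= L]
  for (p in biased) {
    pos_comp[p, ] <- (1 - signal_strength) * background +
      signal_strength * SIGNAL_PROFILE
  }
  draw_class <- function(n, comp) {
    if (n == 0) return(character(0))
    vapply(seq_len(n), function(i) {
      chars <- vapply(seq_len(L), function(p) {
        sample(RNA_ALPHABET, 1, prob = comp[p, ])
      }, character(1))
      chars[xi + 1L] <- "A"
      paste(chars, collapse = "")
    }, character(1))
  }
  withr::with_seed(seed, {
    pos <- draw_class(n_pos, pos_comp)
    neg <- draw_class(n_neg, neg_comp)
  })
  tibble(
    source_id = c(sprintf("sim_pos_%d", seq_len(n_pos)),
                  sprintf("sim_neg_%d", seq_len(n_neg))),
    center_pos = xi + 1L,
    xi = xi,
    residues = c(pos, neg),
    label = rep(c("pos", "neg"), c(n_pos, n_neg))
  )
}

#' Write a generator manifest
#'
#' Records the generator parameters alongside a simulated FASTA so a run can
#' be reproduced.
#'
#' @param params Named list of generator arguments.
#' @param path Output path for the plain-text manifest.
#' @return The path, invisibly.
#' @export
write_sim_manifest <- function(params, path) {
  lines <- paste0(names(params), "\t",
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         character(1)))
  writeLines(c("# synthetic window generator parameters", lines), path)
  invisible(path)
}
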