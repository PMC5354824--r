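# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (character loops, all-pairs scans) and written against
# the definitions, not against the package internals.

write_fasta_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Build a window tibble directly (bypassing extraction) for unit tests.
make_windows <- function(residues, label = "unknown",
                         source_id = NULL) {
  xi <- (nchar(residues[1]) - 1L) %/% 2L
  if (is.null(source_id)) source_id <- sprintf("w%d", seq_along(residues))
  tibble::tibble(
    source_id = source_id,
    center_pos = xi + 1L,
    xi = xi,
    residues = residues,
    label = rep_len(label, length(residues))
  )
}

# Random valid window string of half-width xi (center forced to A).
random_window <- function(xi) {
  chars <- sample(c("A", "C", "G", "U"), 2 * xi + 1, replace = TRUE)
  chars[xi + 1] <- "A"
  paste(chars, collapse = "")
}

# Oracle: occurrence density by an explicit prefix-counting loop.
oracle_density <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  vapply(seq_along(chars), function(i) {
    sum(chars[1:i] == chars[i]) / i
  }, numeric(1))
}

# Oracle: column identity between two equal-length strings.
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca == cb) / length(ca)
}

# Oracle: conventional TP/TN/FP/FN metric formulas.
oracle_metrics <- function(n_pos, n_neg, fn, fp) {
  tp <- n_pos - fn
  tn <- n_neg - fp
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / (n_pos + n_neg),
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  )
}

# A tiny linearly separable window dataset: positives are G-rich upstream,
# negatives U-rich upstream, so classes are trivially separable.
toy_separable_windows <- function(n_per_class = 3, xi = 2) {
  pos <- replicate(n_per_class, {
    chars <- rep("G", 2 * xi + 1)
    chars[xi + 1] <- "A"
    chars[sample(setdiff(seq_len(2 * xi + 1), xi + 1), 1)] <- "C"
    paste(chars, collapse = "")
  })
  neg <- replicate(n_per_class, {
    chars <- rep("U", 2 * xi + 1)
    chars[xi + 1] <- "A"
    chars[sample(setdiff(seq_len(2 * xi + 1), xi + 1), 1)] <- "C"
    paste(chars, collapse = "")
  })
  make_windows(c(pos, neg), label = rep(c("pos", "neg"), each = n_per_class),
               source_id = sprintf("toy%d", seq_len(2 * n_per_class)))
}
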