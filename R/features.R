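# Chemical-property triplets (ring structure, functional group, hydrogen
# bonding): purines A,G carry two rings; A,C carry an amino group; A,U pair
# with two hydrogen bonds (weaker) while C,G pair with three (stronger).
CHEM_TRIPLETS <- matrix(
  c(1, 1, 1,   # A
    0, 1, 0,   # C
    1, 0, 0,   # G
    0, 0, 1),  # U
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), c("x", "y", "z"))
)

#' Chemical-property triplet of a nucleotide
#'
#' Maps a nucleotide to its binary (ring structure, functional group,
#' hydrogen bonding) indicators: `A` is `(1,1,1)`, `C` is `(0,1,0)`,
#' `G` is `(1,0,0)`, and `U` is `(0,0,1)`. The mapping is injective, so the
#' residue is recoverable from the triplet.
#'
#' @param nucleotide A single character, one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return A named numeric vector `c(x=, y=, z=)` of 0/1 indicators.
#' @export
#' @examples
#' encode_chemical("A")
#' encode_chemical("G")
encode_chemical <- function(nucleotide) {
  if (!is.character(nucleotide) || length(nucleotide) != 1L ||
      !nucleotide %in% rownames(CHEM_TRIPLETS)) {
    abort("`nucleotide` must be one of \"A\", \"C\", \"G\", \"U\"",
          class = "inosine_invalid_input")
  }
  CHEM_TRIPLETS[nucleotide, ]
}

#' Sliding occurrence density profile
#'
#' For each position i of a sequence, the density is the number of occurrences
#' of the nucleotide occupying position i within the prefix of length i,
#' divided by i. For `"ACGUA"` this gives `1, 0.5, 1/3, 0.25, 0.4`: the final
#' `A` is the second `A` among the first five residues, hence `2/5`.
#' Densities are exact rationals evaluated in double precision; no rounding
#' is applied.
#'
#' @param residues A single string over `A`, `C`, `G`, `U`.
#' @return A numeric vector of length `nchar(residues)` with values in
#'   `(0, 1]`; the first element is always 1.
#' @export
#' @examples
#' density_profile("ACGUA")
density_profile <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    abort("`residues` must be one non-empty string",
          class = "inosine_invalid_input")
  }
  if (!is_acgu(residues)) {
    abort("`residues` contains characters outside {A,C,G,U}",
          class = "inosine_invalid_input")
  }
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  # running per-nucleotide prefix counts
  counts <- c(A = 0L, C = 0L, G = 0L, U = 0L)
  d <- numeric(L)
  for (i in seq_len(L)) {
    nt <- chars[[i]]
    counts[[nt]] <- counts[[nt]] + 1L
    d[[i]] <- counts[[nt]] / i
  }
  d
}

#' Encode one window as a PseKNC feature vector
#'
#' Concatenates, position by position, the chemical-property triplet and the
#' sliding occurrence density: position i contributes `(x_i, y_i, z_i, D_i)`.
#' A window of length L therefore encodes to a 4L-dimensional vector (a 51-nt
#' window gives 204 features).
#'
#' @param residues A window string over `A`, `C`, `G`, `U` (a single row of a
#'   window tibble may be passed via its `residues` column).
#' @return A named numeric vector of length `4 * nchar(residues)`; names are
#'   `p{i}_{x|y|z|d}`.
#' @export
#' @examples
#' vectorize("ACGUA")
vectorize <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L) {
    abort("`residues` must be one string; use encode_windows() for many",
          class = "inosine_invalid_input")
  }
  if (!is_acgu(residues) || !nzchar(residues)) {
    abort("`residues` must be non-empty over {A,C,G,U}",
          class = "inosine_invalid_input")
  }
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  trip <- CHEM_TRIPLETS[chars, , drop = FALSE]
  d <- density_profile(residues)
  out <- as.numeric(t(cbind(trip, d)))
  names(out) <- paste0("p", rep(seq_len(L), each = 4L),
                       "_", rep(c("x", "y", "z", "d"), L))
  out
}

#' Encode a set of windows into a feature matrix
#'
#' Applies [vectorize()] to every row of a window tibble and stacks the
#' results; row k of the matrix encodes window k, in input order.
#'
#' @param windows A window tibble (see [extract_windows()]); all rows must
#'   share one `xi`.
#' @return A numeric matrix with `nrow(windows)` rows and `4 * (2*xi + 1)`
#'   columns named `p{i}_{x|y|z|d}`. A zero-row input gives a zero-row matrix.
#' @export
encode_windows <- function(windows) {
  check_window_tibble(windows)
  if (nrow(windows) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  mat <- t(vapply(windows$residues, vectorize,
                  numeric(4L * (2L * windows$xi[[1]] + 1L))))
  rownames(mat) <- NULL
  mat
}

#' Recover the residue string from a feature vector
#'
#' Inverts [vectorize()] using the injective chemical-property channels;
#' the density channel is ignored.
#'
#' @param values A numeric feature vector of length divisible by 4.
#' @return The residue string.
#' @export
devectorize <- function(values) {
  if (length(values) %% 4L != 0L || length(values) == 0L) {
    abort("Feature vector length must be a positive multiple of 4",
          class = "inosine_invalid_input")
  }
  trip <- matrix(values, ncol = 4L, byrow = TRUE)[, 1:3, drop = FALSE]
  key <- apply(CHEM_TRIPLETS, 1, paste, collapse = "")
  got <- apply(trip, 1, paste, collapse = "")
  idx <- match(got, key)
  if (anyNA(idx)) {
    abort("Feature vector contains an invalid chemical-property triplet",
          class = "inosine_invalid_input")
  }
  paste(names(key)[idx], collapse = "")
}

#' Write a feature matrix as headered CSV
#'
#' One row per sample with the window's provenance and label followed by the
#' `p{i}_{x|y|z|d}` feature columns.
#'
#' @param windows A labeled window tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(windows, path) {
  mat <- encode_windows(windows)
  df <- cbind(windows[, c("source_id", "center_pos", "label")],
              as.data.frame(mat))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write features in sparse SVM-tool format
#'
#' Emits one line per sample: `label index:value ...` with 1-based feature
#' indices in channel order, the plain-text format consumed by libsvm-style
#' tools. Labels map to `+1` (pos) / `-1` (neg); zero-valued features are
#' omitted.
#'
#' @param windows A labeled window tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_feature_svmlight <- function(windows, path) {
  check_window_tibble(windows, need_label = TRUE)
  mat <- encode_windows(windows)
  lab <- ifelse(windows$label == "pos", "+1", "-1")
  lines <- vapply(seq_len(nrow(mat)), function(k) {
    v <- mat[k, ]
    nz <- which(v != 0)
    vals <- vapply(v[nz], function(x) format(x, trim = TRUE, digits = 15),
                   character(1))
    paste(lab[[k]], paste0(nz, ":", vals, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
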