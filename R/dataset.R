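#' Label candidate windows from a site annotation table
#'
#' Joins extracted windows to an annotation table on (sequence id, center
#' position). Windows whose center is annotated as an editing site become
#' positive, annotated non-sites become negative, and windows with no
#' annotation are excluded. By default nothing is inferred about unannotated
#' adenosines; set `unannotated_negative = TRUE` only if every unannotated
#' center should be treated as a non-site.
#'
#' @param windows A window tibble from [extract_windows()].
#' @param annotations A tibble from [read_annotations()] (columns `seq_id`,
#'   `position`, `label`).
#' @param sequences Optional sequence tibble; when supplied, every annotation
#'   is checked to reference an `A` residue, and violations raise an error
#'   naming the record.
#' @param unannotated_negative If `TRUE`, windows without an annotation are
#'   kept as negatives instead of excluded. Default `FALSE`.
#' @return A labeled window tibble (`label` in `"pos"`/`"neg"`).
#' @export
label_windows <- function(windows, annotations, sequences = NULL,
                          unannotated_negative = FALSE) {
  check_window_tibble(windows)
  stopifnot(all(c("seq_id", "position", "label") %in% names(annotations)))
  if (!is.null(sequences)) {
    for (k in seq_len(nrow(annotations))) {
      sid <- annotations$seq_id[[k]]
      pos <- annotations$position[[k]]
      res <- sequences$residues[match(sid, sequences$id)]
      if (!is.na(res) &&
          (pos < 1 || pos > nchar(res) || substr(res, pos, pos) != "A")) {
        abort(paste0("Annotation for ", sid, " position ", pos,
                     " does not reference an adenosine"),
              class = "inosine_invalid_input")
      }
    }
  }
  ann <- dplyr::distinct(annotations, .data$seq_id, .data$position,
                         .keep_all = TRUE)
  out <- dplyr::left_join(
    dplyr::select(windows, -"label"),
    dplyr::rename(ann, source_id = "seq_id", center_pos = "position"),
    by = c("source_id", "center_pos")
  )
  if (unannotated_negative) {
    out$label[is.na(out$label)] <- "neg"
  } else {
    out <- out[!is.na(out$label), , drop = FALSE]
  }
  as_tibble(out)
}

#' Pairwise identity of equal-length ungapped windows
#'
#' Fraction of identical columns between two equal-length strings.
#' @param a,b Equal-length residue strings.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Remove redundant windows by greedy identity clustering
#'
#' Within each label group independently, samples are scanned in input order;
#' a sample is removed when its ungapped column identity (matching positions
#' divided by window length) with an already-retained same-label sample is
#' strictly greater than `threshold`. This plays the role CD-HIT plays for
#' variable-length sequences; because all windows here are equal-length and
#' ungapped, exact column identity is the natural criterion and greedy
#' first-come clustering suffices.
#'
#' @param windows A labeled window tibble; all residue strings equal length.
#' @param threshold Identity threshold in `(0, 1]`; default 0.60. Removal uses
#'   strict inequality (`identity > threshold`).
#' @return The retained windows, in input order.
#' @export
reduce_redundancy <- function(windows, threshold = 0.60) {
  check_window_tibble(windows, need_label = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1]", class = "inosine_invalid_input")
  }
  if (nrow(windows) == 0) return(windows)
  keep <- logical(nrow(windows))
  for (grp in unique(windows$label)) {
    idx <- which(windows$label == grp)
    # character matrix of the group's windows, one row per sample
    chars <- do.call(rbind, strsplit(windows$residues[idx], ""))
    L <- ncol(chars)
    retained <- integer(0)
    for (j in seq_along(idx)) {
      if (length(retained) == 0) {
        retained <- j
        keep[idx[[j]]] <- TRUE
        next
      }
      prev <- chars[retained, , drop = FALSE]
      ident <- rowMeans(prev == matrix(chars[j, ], nrow = nrow(prev),
                                       ncol = L, byrow = TRUE))
      if (all(ident <= threshold)) {
        retained <- c(retained, j)
        keep[idx[[j]]] <- TRUE
      }
    }
  }
  windows[keep, , drop = FALSE]
}

#' Balance classes by random subsampling
#'
#' Draws `n_per_class` samples uniformly without replacement from each class.
#' Unselected positives are returned separately so they can seed a disjoint
#' independent set, mirroring the usual benchmark-construction practice of
#' holding leftover confirmed sites out for an independent test.
#'
#' @param windows A labeled window tibble with both classes present.
#' @param n_per_class Number of samples to keep per class.
#' @param seed Integer seed; the draw is reproducible from it.
#' @return A list with elements `balanced` (the 2*`n_per_class`-row tibble,
#'   positives first) and `leftover_pos` (unsampled positives).
#' @export
balance_dataset <- function(windows, n_per_class, seed) {
  check_window_tibble(windows, need_label = TRUE)
  pos <- windows[windows$label == "pos", , drop = FALSE]
  neg <- windows[windows$label == "neg", , drop = FALSE]
  if (nrow(pos) < n_per_class || nrow(neg) < n_per_class) {
    abort(paste0("Each class needs at least ", n_per_class, " samples; got ",
                 nrow(pos), " positive and ", nrow(neg), " negative"),
          class = "inosine_invalid_input")
  }
  withr::with_seed(seed, {
    pi <- sample(nrow(pos), n_per_class)
    ni <- sample(nrow(neg), n_per_class)
  })
  list(
    balanced = dplyr::bind_rows(pos[sort(pi), , drop = FALSE],
                                neg[sort(ni), , drop = FALSE]),
    leftover_pos = pos[setdiff(seq_len(nrow(pos)), pi), , drop = FALSE]
  )
}

#' Check that two window sets share no sample
#'
#' Two sets are disjoint when no residue string of one occurs in the other;
#' an independent test set must be disjoint from the training benchmark.
#'
#' @param a,b Window tibbles with equal `xi`.
#' @return `TRUE` if no residue string is shared, else `FALSE`.
#' @export
assert_disjoint <- function(a, b) {
  check_window_tibble(a)
  check_window_tibble(b)
  if (nrow(a) > 0 && nrow(b) > 0 && a$xi[[1]] != b$xi[[1]]) {
    abort("Window sets have different xi", class = "inosine_invalid_input")
  }
  length(intersect(a$residues, b$residues)) == 0
}

#' Build benchmark and independent datasets from annotated sequences
#'
#' Runs the full construction: extract adenosine-centered windows, label them
#' from the annotation table, reduce redundancy within each label group at the
#' identity threshold, subsample a balanced benchmark, and (when enough
#' material remains) assemble a disjoint independent set from leftover
#' positives and unused negatives.
#'
#' @param sequences Sequence tibble from [read_rna_fasta()].
#' @param annotations Annotation tibble from [read_annotations()].
#' @param xi Flank size (default 25, i.e. 51-nt windows).
#' @param threshold Identity threshold for redundancy reduction (default 0.60).
#' @param n_per_class Benchmark samples per class; defaults to the largest
#'   balanced size available after redundancy reduction.
#' @param seed Integer seed for the balancing draw.
#' @return A list with `benchmark`, `independent` (possibly zero rows), and a
#'   `manifest` tibble of per-stage counts and parameters.
#' @export
build_benchmark <- function(sequences, annotations, xi = 25,
                            threshold = 0.60, n_per_class = NULL, seed = 1) {
  windows <- extract_windows(sequences, xi)
  labeled <- label_windows(windows, annotations, sequences)
  nr <- reduce_redundancy(labeled, threshold)
  n_pos <- sum(nr$label == "pos")
  n_neg <- sum(nr$label == "neg")
  if (is.null(n_per_class)) n_per_class <- min(n_pos, n_neg)
  bal <- balance_dataset(nr, n_per_class, seed)
  leftover_pos <- bal$leftover_pos
  used_neg <- paste(bal$balanced$source_id, bal$balanced$center_pos)
  spare_neg <- nr[nr$label == "neg" &
                    !paste(nr$source_id, nr$center_pos) %in% used_neg, ,
                  drop = FALSE]
  n_ind <- min(nrow(leftover_pos), nrow(spare_neg))
  independent <- if (n_ind > 0) {
    dplyr::bind_rows(utils::head(leftover_pos, n_ind),
                     utils::head(spare_neg, n_ind))
  } else {
    nr[0, , drop = FALSE]
  }
  manifest <- tibble(
    stage = c("windows", "labeled", "nonredundant_pos", "nonredundant_neg",
              "benchmark_per_class", "independent_per_class"),
    count = c(nrow(windows), nrow(labeled), n_pos, n_neg, n_per_class, n_ind)
  )
  attr(manifest, "params") <- list(xi = xi, threshold = threshold, seed = seed)
  list(benchmark = bal$balanced, independent = independent,
       manifest = manifest)
}
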