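#' Read RNA (or DNA) sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a tibble of RNA sequences. DNA input is
#' accepted: `T`/`t` is mapped to `U` and lowercase letters are uppercased.
#' Records containing characters outside the IUPAC nucleotide codes after
#' normalization are rejected with a warning; ambiguity codes such as `N` are
#' kept at this stage and handled during window extraction (see
#' [extract_windows()]).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `residues` (character,
#'   uppercase RNA with `U`), one row per record, in file order.
#' @seealso [extract_windows()], [read_labeled_fasta()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), fa)
#' read_rna_fasta(fa)
read_rna_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "inosine_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  # header tokens after whitespace are description, not id
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate sequence id(s) in ", path, ": ",
                 paste(dups, collapse = ", ")),
          class = "inosine_invalid_input")
  }
  residues <- normalize_residues(as.character(set))
  ok <- vapply(residues, is_iupac, logical(1)) & nzchar(residues)
  if (any(!ok)) {
    warn(paste0("Rejected ", sum(!ok), " record(s) with non-IUPAC characters: ",
                paste(ids[!ok], collapse = ", ")))
  }
  tibble(id = ids[ok], residues = unname(residues[ok]))
}

# Uppercase and map T -> U.
normalize_residues <- function(x) {
  chartr("T", "U", toupper(x))
}

is_iupac <- function(s) {
  !grepl(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), s)
}

is_acgu <- function(s) {
  !grepl("[^ACGU]", s)
}

#' Read a labeled sample FASTA file
#'
#' Loads a file in which every record is one fixed-length window sample of
#' length 2*xi + 1 with adenosine at the center, and the header carries the
#' class label using the convention `>{id}|label={pos|neg}` (the tokens `1`/`0`
#' and `+`/`-` are also accepted). This is the format written by
#' [write_labeled_fasta()] and matches published supplementary benchmark sets
#' of editing-site windows.
#'
#' @param path Path to the labeled FASTA file.
#' @return A window tibble (see [extract_windows()]) with columns `source_id`,
#'   `center_pos`, `xi`, `residues`, and `label` (`"pos"`/`"neg"`), one row per
#'   record. `center_pos` is the center within the record itself (xi + 1).
#' @export
read_labeled_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "inosine_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  residues <- normalize_residues(as.character(set))
  n <- length(residues)
  if (n == 0) {
    return(tibble(source_id = character(), center_pos = integer(),
                  xi = integer(), residues = character(), label = character()))
  }
  lens <- nchar(residues)
  if (length(unique(lens)) != 1L) {
    abort(paste0("Mixed record lengths in ", path, ": ",
                 paste(sort(unique(lens)), collapse = ", ")),
          class = "inosine_invalid_input")
  }
  len <- lens[[1]]
  if (len %% 2L == 0L) {
    abort(paste0("Record length ", len, " is even; window samples must have ",
                 "odd length 2*xi + 1"), class = "inosine_invalid_input")
  }
  xi <- (len - 1L) %/% 2L
  ids <- sub("\\|label=.*$", "", headers)
  ids <- sub("\\s.*$", "", ids)
  label_tok <- ifelse(grepl("\\|label=", headers),
                      sub("^.*\\|label=([^| \t]+).*$", "\\1", headers), NA)
  label <- dplyr::case_when(
    label_tok %in% c("pos", "1", "+") ~ "pos",
    label_tok %in% c("neg", "0", "-") ~ "neg",
    TRUE ~ NA_character_
  )
  if (anyNA(label)) {
    abort(paste0("Missing or unrecognized label token in header(s): ",
                 paste(utils::head(headers[is.na(label)], 5), collapse = ", ")),
          class = "inosine_invalid_input")
  }
  center <- substr(residues, xi + 1L, xi + 1L)
  if (any(center != "A")) {
    bad <- ids[center != "A"]
    abort(paste0("Record(s) without adenosine at center position ", xi + 1L,
                 ": ", paste(utils::head(bad, 5), collapse = ", ")),
          class = "inosine_invalid_input")
  }
  bad_alpha <- !vapply(residues, is_acgu, logical(1))
  if (any(bad_alpha)) {
    abort(paste0("Record(s) with characters outside {A,C,G,U}: ",
                 paste(utils::head(ids[bad_alpha], 5), collapse = ", ")),
          class = "inosine_invalid_input")
  }
  tibble(source_id = ids, center_pos = rep(xi + 1L, n), xi = rep(xi, n),
         residues = unname(residues), label = label)
}

#' Write window samples to a labeled FASTA file
#'
#' Emits one record per window with header `>{source_id}_{center_pos}|label={pos|neg}`,
#' the convention read back by [read_labeled_fasta()].
#'
#' @param windows A window tibble with columns `source_id`, `center_pos`,
#'   `residues`, and `label`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_labeled_fasta <- function(windows, path) {
  check_window_tibble(windows, need_label = TRUE)
  headers <- paste0(windows$source_id, "_", windows$center_pos,
                    "|label=", windows$label)
  set <- Biostrings::BStringSet(windows$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a site annotation table
#'
#' Reads a tab-separated annotation file with three columns and no header:
#' sequence id, 1-based position of the annotated adenosine, and label
#' (`1` = editing site, `0` = confirmed non-site).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `seq_id` (character), `position` (integer),
#'   and `label` (`"pos"`/`"neg"`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path),
          class = "inosine_io_error")
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq_id", "position", "label"),
                          colClasses = c("character", "integer", "character"))
  if (!all(df$label %in% c("0", "1"))) {
    abort("Annotation labels must be 1 (editing site) or 0 (non-site)",
          class = "inosine_invalid_input")
  }
  tibble(seq_id = df$seq_id, position = as.integer(df$position),
         label = ifelse(df$label == "1", "pos", "neg"))
}

#' Extract adenosine-centered windows from sequences
#'
#' Slides a window of half-width `xi` (full length 2*xi + 1) along each
#' sequence and keeps every position whose central residue is `A` and whose
#' flanks fit entirely inside the sequence. Windows truncated by a sequence
#' end are skipped, not padded; windows containing ambiguity codes (anything
#' outside `A`, `C`, `G`, `U`) are dropped with a warning.
#'
#' @param sequences A tibble as returned by [read_rna_fasta()], or any data
#'   frame with `id` and `residues` columns.
#' @param xi Positive integer flank size; the window spans the closed interval
#'   `[center - xi, center + xi]` in 1-based coordinates.
#' @return A window tibble with columns `source_id`, `center_pos` (1-based
#'   position of the central `A` in its source), `xi`, `residues`
#'   (the 2*xi + 1 window string), and `label` (all `"unknown"`).
#' @export
#' @examples
#' seqs <- tibble::tibble(id = "s1", residues = "CAGUACGUA")
#' extract_windows(seqs, xi = 1)
extract_windows <- function(sequences, xi) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "residues") %in% names(sequences)))
  if (!is.numeric(xi) || length(xi) != 1L || xi < 1 || xi != as.integer(xi)) {
    abort("`xi` must be a positive integer", class = "inosine_invalid_input")
  }
  xi <- as.integer(xi)
  out <- purrr::map2_dfr(sequences$id, sequences$residues, function(id, res) {
    L <- nchar(res)
    chars <- strsplit(res, "")[[1]]
    centers <- which(chars == "A")
    centers <- centers[centers > xi & centers <= L - xi]
    if (length(centers) == 0L) {
      return(tibble(source_id = character(), center_pos = integer(),
                    xi = integer(), residues = character(),
                    label = character()))
    }
    win <- substring(res, centers - xi, centers + xi)
    tibble(source_id = id, center_pos = as.integer(centers),
           xi = xi, residues = win, label = "unknown")
  })
  valid <- vapply(out$residues, is_acgu, logical(1))
  if (any(!valid)) {
    warn(paste0("Dropped ", sum(!valid),
                " window(s) containing ambiguity codes"))
    out <- out[valid, , drop = FALSE]
  }
  out
}

# Shared validation for window tibbles.
check_window_tibble <- function(windows, need_label = FALSE) {
  stopifnot(is.data.frame(windows))
  need <- c("source_id", "center_pos", "xi", "residues")
  if (need_label) need <- c(need, "label")
  missing <- setdiff(need, names(windows))
  if (length(missing) > 0) {
    abort(paste0("Window tibble is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "inosine_invalid_input")
  }
  if (nrow(windows) == 0) return(invisible(windows))
  if (length(unique(windows$xi)) != 1L) {
    abort("All windows must share one xi value",
          class = "inosine_invalid_input")
  }
  xi <- windows$xi[[1]]
  if (any(nchar(windows$residues) != 2L * xi + 1L)) {
    abort("Window residue strings must have length 2*xi + 1",
          class = "inosine_invalid_input")
  }
  if (any(substr(windows$residues, xi + 1L, xi + 1L) != "A")) {
    abort("Every window must have adenosine at its center",
          class = "inosine_invalid_input")
  }
  invisible(windows)
}
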