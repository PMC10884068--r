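#' Symbolic sequences over a finite alphabet
#'
#' A `symbolic_sequence` is the universal input of the package: an ordered
#' vector of categorical states drawn from a small finite alphabet, such as an
#' EEG microstate label sequence (typically 4 or 5 classes) or the time course
#' of a single Potts lattice node. States are stored as 0-based integer codes;
#' display labels live alongside them so that all numerical modules share one
#' integer code path regardless of how the states are written.
#'
#' @param states Integer vector of 0-based state codes, or a character vector
#'   of labels (resolved against `labels`).
#' @param labels Character vector of unique display labels, one per state, in
#'   code order. Defaults to `LETTERS[1:4]` for character input inferred from
#'   the data, and is required for integer input.
#' @param meta Named list of free-form provenance (source file, seed,
#'   temperature, condition label, ...). Carried along and emitted into result
#'   tables by the experiment drivers.
#'
#' @return An object of class `symbolic_sequence`: a list with elements
#'   `states` (integer, 0-based), `labels` (character) and `meta` (list).
#' @examples
#' s <- symbolic_sequence(c("A", "C", "C", "A"), labels = LETTERS[1:4])
#' s$states  # 0 2 2 0
#' @export
symbolic_sequence <- function(states, labels = NULL, meta = list()) {
  if (is.character(states)) {
    if (is.null(labels)) {
      labels <- sort(unique(states))
    }
    idx <- match(states, labels)
    if (anyNA(idx)) {
      bad <- states[which(is.na(idx))[1]]
      abort(sprintf("unknown symbol '%s' (alphabet: %s)",
                    bad, paste(labels, collapse = ", ")))
    }
    states <- idx - 1L
  } else {
    states <- as.integer(states)
    if (is.null(labels)) {
      labels <- LETTERS[seq_len(max(states) + 1L)]
    }
  }
  validate_symbolic_sequence(states, labels)
  structure(list(states = states, labels = labels, meta = meta),
            class = "symbolic_sequence")
}

validate_symbolic_sequence <- function(states, labels) {
  if (length(states) < 1L) abort("a symbolic sequence must have length >= 1")
  if (anyNA(states)) abort("sequence states must not contain NA")
  if (anyDuplicated(labels)) abort("alphabet labels must be unique")
  if (length(labels) < 2L) abort("alphabet must have at least 2 states")
  if (any(states < 0L) || any(states >= length(labels))) {
    abort("state codes must lie in [0, alphabet size)")
  }
  invisible(TRUE)
}

#' @export
length.symbolic_sequence <- function(x) length(x$states)

#' @export
print.symbolic_sequence <- function(x, ...) {
  n <- length(x$states)
  head_lab <- x$labels[x$states[seq_len(min(n, 30L))] + 1L]
  cat(sprintf("<symbolic_sequence> n = %d, alphabet = {%s}\n",
              n, paste(x$labels, collapse = ", ")))
  cat("  ", paste(head_lab, collapse = ""), if (n > 30L) "..." else "", "\n",
      sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coerce to a symbolic sequence
#'
#' @param x A `symbolic_sequence`, factor, character vector of labels, or
#'   integer vector of 0-based codes.
#' @param labels Optional alphabet labels (required for integer input if the
#'   alphabet is larger than the observed codes).
#' @param ... Unused.
#' @return A `symbolic_sequence`.
#' @export
as_symbolic_sequence <- function(x, labels = NULL, ...) {
  if (inherits(x, "symbolic_sequence")) return(x)
  if (is.factor(x)) {
    return(symbolic_sequence(as.character(x),
                             labels = labels %||% levels(x)))
  }
  symbolic_sequence(x, labels = labels)
}

#' @export
as.character.symbolic_sequence <- function(x, ...) x$labels[x$states + 1L]

n_states <- function(seq) length(seq$labels)

#' Read a symbolic sequence from a text file
#'
#' Three plain-text dialects are supported, matching common microstate-export
#' practice: one label per line (`"lines"`), a single comma-separated line
#' (`"single-line"`), and a single-column CSV with a header row (`"csv"`).
#' Files are read as UTF-8 and surrounding whitespace on tokens is ignored.
#'
#' @param path Path to the file.
#' @param format One of `"lines"`, `"single-line"`, `"csv"`.
#' @param labels Alphabet labels. If `NULL` the alphabet is inferred as the
#'   sorted set of distinct tokens (numeric tokens sort numerically, so the
#'   file `"0,1,2,3"` maps to codes 0..3).
#' @return A `symbolic_sequence` with `meta$source = path`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A", "C", "C", "A"), f)
#' read_sequence(f, labels = LETTERS[1:4])$states  # 0 2 2 0
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, format = c("lines", "single-line", "csv"),
                          labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty sequence file: %s", path))
  tokens <- switch(format,
    "lines" = trimws(lines),
    "single-line" = trimws(strsplit(paste(lines, collapse = ","), ",")[[1]]),
    "csv" = {
      if (length(lines) < 2L) abort(sprintf("CSV file has no data rows: %s", path))
      trimws(vapply(strsplit(lines[-1], ","), `[[`, character(1), 1L))
    }
  )
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) abort(sprintf("empty sequence file: %s", path))
  if (is.null(labels)) {
    labels <- unique(tokens)
    nums <- suppressWarnings(as.numeric(labels))
    labels <- if (!anyNA(nums)) labels[order(nums)] else sort(labels)
  }
  idx <- match(tokens, labels)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf(
      "unknown symbol '%s' at token %d of %s (alphabet: %s)",
      tokens[bad], bad, path, paste(labels, collapse = ", ")))
  }
  symbolic_sequence(idx - 1L, labels = labels, meta = list(source = path))
}

#' Write a symbolic sequence to a text file
#'
#' Inverse of [read_sequence()]: `read_sequence(write_sequence(s, f), ...)`
#' round-trips bit-exactly for every dialect.
#'
#' @param seq A `symbolic_sequence`.
#' @param path Destination path; the directory must exist.
#' @param format One of `"lines"` (default), `"single-line"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("lines", "single-line", "csv")) {
  format <- match.arg(format)
  seq <- as_symbolic_sequence(seq)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("directory does not exist: %s", dirname(path)))
  }
  lab <- seq$labels[seq$states + 1L]
  out <- switch(format,
    "lines" = lab,
    "single-line" = paste(lab, collapse = ","),
    "csv" = c("state", lab)
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Collapse consecutive duplicate states (jump sequence)
#'
#' Removes all repeated labels, keeping one representative per run, e.g.
#' `ACCCAADBBA` becomes `ACADBA`. This is the jump-chain representation from
#' Markov process theory: state durations are discarded and only transitions
#' between non-identical states remain. Jump sequences look substantially more
#' random than the full sequences they derive from and carry no long-range
#' correlation structure.
#'
#' @param seq A `symbolic_sequence` (or something coercible to one).
#' @return A `symbolic_sequence` with no two consecutive equal states;
#'   `meta$jump = TRUE` is added.
#' @examples
#' s <- symbolic_sequence(strsplit("ACCCAADBBA", "")[[1]])
#' paste(as.character(jump_sequence(s)), collapse = "")  # "ACADBA"
#' @export
jump_sequence <- function(seq) {
  seq <- as_symbolic_sequence(seq)
  x <- seq$states
  keep <- c(TRUE, x[-1] != x[-length(x)])
  meta <- seq$meta
  meta$jump <- TRUE
  symbolic_sequence(x[keep], labels = seq$labels, meta = meta)
}

#' Embed a categorical sequence as a signed unit series
#'
#' Substitutes every state in `plus` with +1 and every state in `minus` with
#' -1, producing the random-walk embedding used by the DFA/Hurst analysis.
#' The two subsets must partition the alphabet exactly.
#'
#' @param seq A `symbolic_sequence`.
#' @param plus,minus Disjoint sets of states covering the alphabet, given as
#'   label characters or 0-based integer codes.
#' @return A numeric vector of +1/-1 with the same length as the sequence.
#' @examples
#' s <- symbolic_sequence(c("A", "C", "A", "C"), labels = LETTERS[1:4])
#' apply_partition(s, c("A", "B"), c("C", "D"))  # +1 -1 +1 -1
#' @export
apply_partition <- function(seq, plus, minus) {
  seq <- as_symbolic_sequence(seq)
  to_code <- function(v) {
    if (is.character(v)) {
      idx <- match(v, seq$labels)
      if (anyNA(idx)) abort("partition contains labels not in the alphabet")
      idx - 1L
    } else as.integer(v)
  }
  plus <- to_code(plus); minus <- to_code(minus)
  all_states <- sort(c(plus, minus))
  if (anyDuplicated(all_states) ||
      !identical(all_states, seq(0L, n_states(seq) - 1L))) {
    abort("partition subsets must be disjoint and cover the alphabet exactly")
  }
  ifelse(seq$states %in% plus, 1, -1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
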