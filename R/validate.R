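#' Validate a FASTA stream
#'
#' Grammar stage of the validator. The token stream produced by the lexer
#' must satisfy
#'
#' \preformatted{file   := record+ EOF
#' record := HEADER COMMENT* SEQLINE+}
#'
#' i.e. the input starts with a `>` header, `;` comments are legal only
#' directly after a header, and every record carries at least one sequence
#' line. A file whose tokens are all correct and correctly ordered is valid.
#' Sequence lines are checked against the mode's alphabet (residue letters
#' case-insensitively, plus the alignment characters space, `-`, `.`, `*`);
#' the first invalid character of a record is reported as an
#' `ILLEGAL_CHARACTER` issue with its line and column, after which the
#' validator resynchronizes at the next header so one corrupt record yields
#' one issue. Blank lines are issues by default;
#' `allow_blank_between_records` tolerates them between a record's last
#' sequence line and the next header (or the end of file).
#'
#' The issue codes are `NO_HEADER_AT_START`, `EMPTY_SEQUENCE`,
#' `ILLEGAL_CHARACTER`, `MISPLACED_COMMENT`, `BLANK_LINE` and `EMPTY_FILE`.
#' Lines and columns are 1-based; whole-line issues carry column 0.
#'
#' @inheritParams fasta_tokenize
#' @param fail_fast Stop at the first issue.
#' @param max_issues Stop scanning once this many issues were collected.
#' @param allow_blank_between_records Tolerate blank lines between records.
#' @param count_letters Also tally valid letters (see
#'   [fasta_count_letters()]); the tallies are attached to the report as
#'   `letter_counts` only when the input is valid.
#' @param handler Optional [fasta_handler()] whose hooks fire, in token
#'   order, once for every accepted token.
#' @return An object of class `"fasta_report"`: a list with elements `valid`
#'   (logical; `TRUE` iff `issues` is empty), `mode`, `issues` (data frame
#'   with columns `code`, `message`, `line`, `column`, `offending`),
#'   `record_count` (accepted headers), `line_count`, `accepted_tokens` and
#'   `letter_counts` (a `"fasta_letter_counts"` object or `NULL`).
#' @seealso [fasta_records()], [fasta_count_letters()],
#'   [fasta_detect_alphabet()]
#' @export
#' @examples
#' fasta_validate(text = ">a\nACGT\n", mode = "dna")
#' fasta_validate(text = ">a\nACGU\n", mode = "dna")$issues
fasta_validate <- function(file = NULL, text = NULL, mode = "universal",
                           fail_fast = FALSE, max_issues = Inf,
                           allow_blank_between_records = FALSE,
                           count_letters = FALSE, handler = NULL,
                           chunk_size = 1048576L) {
  res <- fasta_scan(
    file = file, text = text, mode = mode, chunk_size = chunk_size,
    fail_fast = isTRUE(fail_fast), max_issues = max_issues,
    allow_blank = isTRUE(allow_blank_between_records),
    count_letters = isTRUE(count_letters), handler = handler
  )
  valid <- nrow(res$issues) == 0L
  lc <- NULL
  if (isTRUE(count_letters) && valid) {
    lc <- .letter_counts_from_tallies(res$tallies, res$mode)
  }
  structure(
    list(
      valid = valid,
      mode = res$mode,
      issues = res$issues,
      record_count = res$record_count,
      line_count = res$line_count,
      accepted_tokens = res$accepted,
      letter_counts = lc
    ),
    class = "fasta_report"
  )
}

#' @export
print.fasta_report <- function(x, max = 10L, ...) {
  cat(
    "FASTA validation (", x$mode, " mode): ",
    if (x$valid) "VALID" else "INVALID", "\n",
    sep = ""
  )
  cat(
    "  ", x$record_count, " record(s), ", x$line_count, " line(s), ",
    x$accepted_tokens, " accepted token(s)\n",
    sep = ""
  )
  n <- nrow(x$issues)
  if (n > 0L) {
    cat("  ", n, " issue(s):\n", sep = "")
    shown <- utils::head(x$issues, max)
    for (i in seq_len(nrow(shown))) {
      cat("   - [", shown$code[i], "] ", shown$message[i], "\n", sep = "")
    }
    if (n > max) cat("   ... and ", n - max, " more\n", sep = "")
  }
  if (!is.null(x$letter_counts)) print(x$letter_counts)
  invisible(x)
}

#' Event handler for the validator
#'
#' Bundles up to four callbacks that [fasta_validate()] fires once per
#' accepted token, in token order, so lines can be transformed into
#' user-defined data structures while streaming. Each hook receives a token:
#' a list with elements `kind`, `text`, `line`, `byte_offset`, `terminator`.
#'
#' @param on_header,on_comment,on_sequence_line,on_eof Functions of one
#'   argument (the token), or `NULL` to ignore that token kind.
#' @return An object of class `"fasta_handler"`.
#' @export
#' @examples
#' ids <- character(0)
#' h <- fasta_handler(on_header = function(tok) ids <<- c(ids, tok$text))
#' fasta_validate(text = ">a\nAC\n>b\nGT\n", handler = h)
#' ids
fasta_handler <- function(on_header = NULL, on_comment = NULL,
                          on_sequence_line = NULL, on_eof = NULL) {
  for (f in list(on_header, on_comment, on_sequence_line, on_eof)) {
    if (!is.null(f) && !is.function(f)) {
      stop("handler hooks must be functions (or NULL)", call. = FALSE)
    }
  }
  structure(
    list(
      on_header = on_header, on_comment = on_comment,
      on_sequence_line = on_sequence_line, on_eof = on_eof
    ),
    class = "fasta_handler"
  )
}

# condition constructor shared by the strict readers
.fasta_invalid_error <- function(issue) {
  structure(
    class = c("fasta_validation_error", "error", "condition"),
    list(
      message = paste0("invalid FASTA input: ", issue$message),
      call = NULL,
      issue = issue
    )
  )
}

#' Read all records from a FASTA stream (strict)
#'
#' Materialized convenience layer over the event API: validates the input
#' and returns one row per record. Any validation issue aborts with an error
#' of class `"fasta_validation_error"` carrying the first issue. Sequence
#' lines of a record are concatenated verbatim, so alignment characters
#' (gaps, stops) are preserved.
#'
#' @inheritParams fasta_tokenize
#' @return A data frame with columns `header` (header text without the
#'   leading `>`), `comments` (list column of comment texts without the
#'   leading `;`) and `sequence` (concatenated sequence lines).
#' @export
#' @examples
#' fasta_records(text = ">a\nAC\nGT\n>b\nGG\n")
fasta_records <- function(file = NULL, text = NULL, mode = "universal",
                          chunk_size = 1048576L) {
  env <- new.env(parent = emptyenv())
  env$header <- character(0)
  env$comments <- list()
  env$seq_parts <- list()
  env$cur <- 0L
  h <- fasta_handler(
    on_header = function(tok) {
      env$cur <- env$cur + 1L
      env$header[env$cur] <- sub("^>", "", tok$text)
      env$comments[[env$cur]] <- character(0)
      env$seq_parts[[env$cur]] <- character(0)
    },
    on_comment = function(tok) {
      env$comments[[env$cur]] <- c(env$comments[[env$cur]], sub("^;", "", tok$text))
    },
    on_sequence_line = function(tok) {
      env$seq_parts[[env$cur]] <- c(env$seq_parts[[env$cur]], tok$text)
    }
  )
  rep <- fasta_validate(
    file = file, text = text, mode = mode, fail_fast = TRUE,
    handler = h, chunk_size = chunk_size
  )
  if (!rep$valid) stop(.fasta_invalid_error(rep$issues[1L, , drop = FALSE]))
  out <- data.frame(
    header = env$header,
    sequence = vapply(env$seq_parts, paste0, character(1), collapse = ""),
    stringsAsFactors = FALSE
  )
  out$comments <- env$comments
  out[, c("header", "comments", "sequence")]
}
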