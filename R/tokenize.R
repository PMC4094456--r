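#' Tokenize a FASTA stream
#'
#' First stage of the validator: converts the raw character stream into an
#' ordered token sequence. Lines are classified by their first character
#' (`>` header, `;` comment, empty/whitespace-only blank, anything else a
#' sequence line) and a final `EOF` token closes the stream. Unix (`LF`),
#' Windows (`CRLF`) and classic Mac (`CR`) line terminators are recognised,
#' also mixed within one file; each token records its own terminator style.
#' A sequence line containing a character outside the mode's alphabet is
#' still emitted, annotated with the column of the first invalid character
#' (`bad_col`); rejecting it is the grammar stage's job.
#'
#' Concatenating `text` plus the terminator characters of all non-EOF tokens
#' reconstructs the input byte-for-byte.
#'
#' @param file Path to a FASTA file, or a connection.
#' @param text A single string holding FASTA content (alternative to `file`).
#' @param mode Parsing mode; see [fasta_modes()]. Affects only the `bad_col`
#'   annotation.
#' @param chunk_size Bytes read per chunk; memory use is bounded by the chunk
#'   size plus the longest line.
#' @return A data frame of class `"fasta_tokens"` with columns `kind`
#'   (`HEADER`, `COMMENT`, `SEQLINE`, `BLANK`, `EOF`), `text` (line content
#'   without its terminator), `line` (1-based), `byte_offset` (0-based offset
#'   of the line start), `terminator` (`LF`, `CRLF`, `CR`, `NONE`) and
#'   `bad_col` (1-based column of the first invalid sequence character, `NA`
#'   if none).
#' @export
#' @examples
#' fasta_tokenize(text = ">id desc\nACGT\n", mode = "dna")
fasta_tokenize <- function(file = NULL, text = NULL, mode = "universal",
                           chunk_size = 1048576L) {
  res <- fasta_scan(
    file = file, text = text, mode = mode, chunk_size = chunk_size,
    collect_tokens = TRUE, max_issues = Inf
  )
  toks <- if (length(res$tokens)) {
    do.call(rbind, res$tokens)
  } else {
    data.frame(
      kind = character(0), text = character(0), line = integer(0),
      byte_offset = numeric(0), terminator = character(0),
      bad_col = integer(0), stringsAsFactors = FALSE
    )
  }
  eof <- data.frame(
    kind = "EOF", text = "", line = res$line_count + 1L,
    byte_offset = res$total_bytes, terminator = "NONE",
    bad_col = NA_integer_, stringsAsFactors = FALSE
  )
  out <- rbind(toks, eof)
  rownames(out) <- NULL
  class(out) <- c("fasta_tokens", "data.frame")
  out
}

#' Reassemble the input text from a token table
#'
#' Inverse of [fasta_tokenize()]: pastes token texts and their terminators
#' back together.
#'
#' @param tokens A `"fasta_tokens"` data frame.
#' @return A single string identical to the tokenized input.
#' @export
fasta_untokenize <- function(tokens) {
  term <- c(LF = "\n", CRLF = "\r\n", CR = "\r", NONE = "")
  body <- tokens[tokens$kind != "EOF", , drop = FALSE]
  paste0(paste0(body$text, term[body$terminator]), collapse = "")
}
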