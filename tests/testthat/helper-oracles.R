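# Independent oracles used across the suite. Everything here is written
# against the FASTA format directly, not against the package's lexer, so
# the checks stay two-route.

ORC_ALN <- c(" ", "-", ".", "*")

ORC_RES <- local({
  dna <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  rna <- strsplit("ACGURYSWKMBDHVN", "")[[1]]
  protein <- strsplit("ACDEFGHIKLMNPQRSTVWYBZXJUO", "")[[1]]
  list(
    dna = dna, rna = rna, protein = protein,
    universal = unique(c(dna, rna, protein))
  )
})

# split into lines across any terminator style; a trailing terminator does
# not open a new line
orc_lines <- function(text) {
  if (identical(text, "")) return(character(0))
  strsplit(text, "\r\n|\r|\n")[[1]]
}

orc_kind <- function(line) {
  if (grepl("^>", line)) "HEADER"
  else if (grepl("^;", line)) "COMMENT"
  else if (grepl("^[ \t]*$", line)) "BLANK"
  else "SEQLINE"
}

# single-pass character-scan letter counter (assumes input valid for mode)
orc_count <- function(text, mode) {
  lines <- orc_lines(text)
  kinds <- vapply(lines, orc_kind, character(1), USE.NAMES = FALSE)
  chars <- unlist(strsplit(lines[kinds == "SEQLINE"], ""), use.names = FALSE)
  if (is.null(chars)) chars <- character(0)
  aln <- chars %in% ORC_ALN
  res <- toupper(chars[!aln])
  res_tab <- table(factor(res, levels = sort(ORC_RES[[mode]])))
  aln_tab <- table(factor(chars[aln], levels = ORC_ALN))
  res_v <- as.integer(res_tab)
  names(res_v) <- names(res_tab)
  aln_v <- as.integer(aln_tab)
  names(aln_v) <- names(aln_tab)
  list(
    residue = res_v[res_v > 0L],
    alignment = aln_v[aln_v > 0L],
    total_residues = sum(res_v),
    total_alignment = sum(aln_v)
  )
}

# brute-force recognizer of  file := (HEADER COMMENT* SEQLINE+)+ EOF
orc_grammar_valid <- function(kinds) {
  if (length(kinds) == 0L) return(FALSE)
  if (any(kinds == "BLANK")) return(FALSE)
  s <- paste(substr(kinds, 1L, 1L), collapse = "")
  grepl("^(HC*S+)+$", s)
}

# render a token-kind string as FASTA text
orc_render <- function(kinds, style = "LF") {
  texts <- vapply(kinds, function(k) {
    switch(k, HEADER = ">id x", COMMENT = "; note", SEQLINE = "ACGT", BLANK = "")
  }, character(1))
  terms <- switch(style,
    LF = "\n", CRLF = "\r\n", CR = "\r",
    MIXED = rep_len(c("\n", "\r\n", "\r"), length(kinds))
  )
  paste0(paste0(texts, terms), collapse = "")
}

# rewrite every line terminator of a text to the given style
orc_rewrite_terminators <- function(text, style) {
  canon <- gsub("\r\n", "\n", text, fixed = TRUE)
  canon <- gsub("\r", "\n", canon, fixed = TRUE)
  if (style == "LF") return(canon)
  parts <- strsplit(canon, "\n", fixed = TRUE)[[1]]
  trailing <- grepl("\n$", canon)
  n_terms <- length(parts) - !trailing
  if (length(parts) == 0L) parts <- ""
  terms <- switch(style,
    CRLF = rep("\r\n", length(parts)),
    CR = rep("\r", length(parts)),
    MIXED = rep_len(c("\r\n", "\n", "\r"), length(parts))
  )
  if (!trailing) terms[length(terms)] <- ""
  paste0(paste0(parts, terms), collapse = "")
}

# random small FASTA document; returns list(kinds, text). `valid_only`
# constrains the kind string to the grammar.
fuzz_doc <- function(valid_only = FALSE, style = "LF", mode = "universal") {
  kinds <- if (valid_only) {
    nrec <- sample(1:3, 1)
    unlist(lapply(seq_len(nrec), function(i) {
      c("HEADER", rep("COMMENT", sample(0:2, 1)), rep("SEQLINE", sample(1:3, 1)))
    }))
  } else {
    n <- sample(0:8, 1)
    sample(c("HEADER", "COMMENT", "SEQLINE", "BLANK"), n, replace = TRUE)
  }
  letters_for <- list(
    dna = "ACGTacgtN", rna = "ACGUacguN",
    protein = "ACDEFGHIKLMNPQRSTVWYacdefg", universal = "ACGTUacgtuEFILPQefilpqN"
  )[[mode]]
  pool <- c(strsplit(letters_for, "")[[1]], "-", ".", "*")
  texts <- vapply(seq_along(kinds), function(i) {
    switch(kinds[i],
      HEADER = paste0(">seq", i, " desc ", i),
      COMMENT = paste0("; comment ", i),
      BLANK = paste0(rep(" ", sample(0:2, 1)), collapse = ""),
      SEQLINE = {
        x <- paste0(sample(pool, sample(1:30, 1), replace = TRUE), collapse = "")
        # keep the lexical class stable
        if (grepl("^[ \t]*$", x)) x <- paste0("A", x)
        x
      }
    )
  }, character(1))
  term <- switch(style,
    LF = "\n", CRLF = "\r\n", CR = "\r",
    MIXED = rep_len(c("\n", "\r\n", "\r"), length(kinds))
  )
  list(kinds = kinds, text = paste0(paste0(texts, term), collapse = ""))
}

first_issue <- function(report) {
  if (report$valid) NULL else report$issues[1L, c("code", "line", "column")]
}
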