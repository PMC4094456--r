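test_that("minimal well-formed and malformed records get the right verdicts", {
  r <- fasta_validate(text = ">a\nACGT\n", mode = "dna")
  expect_true(r$valid)
  expect_identical(r$record_count, 1L)
  expect_identical(nrow(r$issues), 0L)

  r <- fasta_validate(text = ">a\n>b\nAC\n", mode = "dna")
  expect_false(r$valid)
  expect_identical(r$issues$code[1], "EMPTY_SEQUENCE")
  expect_identical(r$issues$line[1], 2L)

  r <- fasta_validate(text = "ACGT\n", mode = "dna")
  expect_identical(r$issues$code[1], "NO_HEADER_AT_START")
  expect_identical(r$issues$line[1], 1L)

  r <- fasta_validate(text = ">a\nACGU\n", mode = "dna")
  expect_identical(r$issues$code[1], "ILLEGAL_CHARACTER")
  expect_identical(r$issues$line[1], 2L)
  expect_identical(r$issues$column[1], 4L)
  expect_identical(r$issues$offending[1], "U")

  r <- fasta_validate(text = ">a\n;note\nAC..G-*\n", mode = "universal")
  expect_true(r$valid)

  # header with no text after '>' is syntactically fine
  expect_true(fasta_validate(text = ">\nAC\n", mode = "dna")$valid)

  # record ending at EOF without sequence
  r <- fasta_validate(text = ">a\nAC\n>b\n", mode = "dna")
  expect_identical(r$issues$code[1], "EMPTY_SEQUENCE")
  expect_identical(r$issues$line[1], 3L)

  r <- fasta_validate(text = "")
  expect_identical(r$issues$code[1], "EMPTY_FILE")
})

test_that("verdicts equal the brute-force grammar recognizer (short strings)", {
  kinds_pool <- c("HEADER", "COMMENT", "SEQLINE", "BLANK")
  for (n in 0:4) {
    grid <- if (n == 0) list(character(0)) else {
      g <- do.call(expand.grid, c(rep(list(kinds_pool), n), stringsAsFactors = FALSE))
      lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
    }
    for (kinds in grid) {
      txt <- orc_render(kinds)
      got <- fasta_validate(text = txt)$valid
      want <- orc_grammar_valid(kinds)
      if (!identical(got, want)) {
        fail(sprintf(
          "verdict mismatch for [%s]: got %s, oracle %s",
          paste(kinds, collapse = " "), got, want
        ))
      }
    }
  }
  succeed()
})

test_that("comments are legal only immediately after a header", {
  expect_true(fasta_validate(text = ">a\n;c1\n;c2\nAC\n")$valid)
  r <- fasta_validate(text = ">a\nAC\n;late\n")
  expect_identical(r$issues$code[1], "MISPLACED_COMMENT")
  expect_identical(r$issues$line[1], 3L)
  r <- fasta_validate(text = ";lead\n>a\nAC\n")
  expect_identical(r$issues$code[1], "NO_HEADER_AT_START")
})

test_that("blank lines are issues unless allowed between records", {
  between <- ">a\nAC\n\n>b\nGG\n"
  r <- fasta_validate(text = between)
  expect_identical(r$issues$code, "BLANK_LINE")
  expect_identical(r$issues$line, 3L)
  expect_true(fasta_validate(text = between, allow_blank_between_records = TRUE)$valid)
  # trailing blanks after the last record are tolerated too
  expect_true(fasta_validate(
    text = ">a\nAC\n\n\n",
    allow_blank_between_records = TRUE
  )$valid)
  # ... but blanks inside a record are not
  inside <- ">a\nAC\n\nGG\n"
  r <- fasta_validate(text = inside, allow_blank_between_records = TRUE)
  expect_identical(r$issues$code[1], "BLANK_LINE")
  expect_identical(r$issues$line[1], 3L)
  # ... nor between header and first sequence line
  r <- fasta_validate(text = ">a\n\nAC\n", allow_blank_between_records = TRUE)
  expect_identical(r$issues$code[1], "BLANK_LINE")
})

test_that("one corrupt record yields one issue, then resynchronization", {
  txt <- ">a\nAC!T\nG!G\n>b\nACGT\n"
  r <- fasta_validate(text = txt, mode = "dna")
  expect_identical(r$issues$code, "ILLEGAL_CHARACTER")
  expect_identical(nrow(r$issues), 1L)
  expect_identical(r$record_count, 2L)
  # a second corrupt record gets its own issue
  txt2 <- ">a\nA!C\n>b\nG!G\n"
  r2 <- fasta_validate(text = txt2, mode = "dna")
  expect_identical(r2$issues$line, c(2L, 4L))
})

test_that("fail_fast agrees with the full scan on the first issue", {
  set.seed(404)
  codes <- c(
    "NO_HEADER_AT_START", "EMPTY_SEQUENCE", "ILLEGAL_CHARACTER",
    "MISPLACED_COMMENT", "BLANK_LINE"
  )
  for (i in 1:40) {
    fx <- generate_fasta(fixture_spec(
      mode = "dna", n_records = sample(2:4, 1), length_min = 10,
      length_max = 40, line_width = 12, comment_prob = 0.5, seed = i
    ), manifest = FALSE)
    bad <- corrupt_fasta(fx$text, corruption_recipe(sample(codes, 1), seed = i))
    full <- fasta_validate(text = bad$text, mode = "dna")
    fast <- fasta_validate(text = bad$text, mode = "dna", fail_fast = TRUE)
    expect_identical(nrow(fast$issues), 1L)
    expect_identical(first_issue(fast), first_issue(full))
  }
})

test_that("max_issues caps the scan", {
  txt <- paste0(rep("\n", 50), collapse = "")
  r <- fasta_validate(text = txt, max_issues = 5)
  expect_identical(nrow(r$issues), 5L)
  expect_false(r$valid)
})

test_that("handler hooks fire once per accepted token, in order", {
  log <- new.env()
  log$events <- character(0)
  h <- fasta_handler(
    on_header = function(tok) log$events <- c(log$events, paste0("H", tok$line)),
    on_comment = function(tok) log$events <- c(log$events, paste0("C", tok$line)),
    on_sequence_line = function(tok) log$events <- c(log$events, paste0("S", tok$line)),
    on_eof = function(tok) log$events <- c(log$events, paste0("E", tok$line))
  )
  r <- fasta_validate(text = ">a\n;c\nAC\nGT\n>b\nGG\n", handler = h)
  expect_identical(log$events, c("H1", "C2", "S3", "S4", "H5", "S6", "E7"))
  expect_identical(length(log$events), r$accepted_tokens)

  # rejected tokens (illegal char, misplaced comment) fire no event
  log$events <- character(0)
  r2 <- fasta_validate(text = ">a\nA!C\n;x\nGG\n", mode = "dna", handler = h)
  expect_identical(log$events, c("H1", "S4", "E5"))
  expect_identical(length(log$events), r2$accepted_tokens)
})

test_that("validation verdicts are invariant under terminator rewrites", {
  set.seed(505)
  for (i in 1:30) {
    doc <- fuzz_doc()
    base <- fasta_validate(text = doc$text)
    for (style in c("CRLF", "CR", "MIXED")) {
      alt <- fasta_validate(text = orc_rewrite_terminators(doc$text, style))
      expect_identical(base$valid, alt$valid)
      expect_identical(first_issue(base), first_issue(alt))
    }
  }
})

test_that("any file valid under a specific mode is valid under universal", {
  set.seed(606)
  for (m in c("dna", "rna", "protein")) {
    for (i in 1:10) {
      fx <- generate_fasta(fixture_spec(
        mode = m, n_records = 2, length_min = 10, length_max = 50,
        gap_prob = 0.1, seed = i
      ), manifest = FALSE)
      expect_true(fasta_validate(text = fx$text, mode = m)$valid)
      expect_true(fasta_validate(text = fx$text, mode = "universal")$valid)
    }
  }
})

test_that("records are materialized in order with verbatim sequences", {
  out <- fasta_records(text = ">a\nAC\nGT\n")
  expect_identical(out$header, "a")
  expect_identical(out$sequence, "ACGT")
  expect_identical(out$comments[[1]], character(0))

  out <- fasta_records(text = ">a\nAC\n>b\nGG\n")
  expect_identical(out$header, c("a", "b"))
  expect_identical(out$sequence, c("AC", "GG"))

  out <- fasta_records(text = ">a\n;note\nAC..G-*\n")
  expect_identical(out$comments[[1]], "note")
  expect_identical(out$sequence, "AC..G-*")

  err <- tryCatch(
    fasta_records(text = ">a\nAC!T\n"),
    fasta_validation_error = function(e) e
  )
  expect_s3_class(err, "fasta_validation_error")
  expect_identical(err$issue$code, "ILLEGAL_CHARACTER")
  expect_identical(err$issue$line, 2L)
  expect_identical(err$issue$column, 3L)
})

test_that("I/O failures are errors, not invalid-content verdicts", {
  expect_error(fasta_validate(file = tempfile("missing-")), "no such file")
  expect_error(fasta_validate(text = ">a\nAC\n", file = "x"), "not both")
  expect_error(fasta_validate(), "supply one of")
})
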