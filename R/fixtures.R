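# Deterministic generator of valid and deliberately corrupted FASTA files.
# All randomness flows through R's RNG seeded from the spec/recipe, so the
# same spec yields byte-identical output on every platform.

.terminator_styles <- c("LF", "CRLF", "CR", "MIXED")
.terminator_chars <- c(LF = "\n", CRLF = "\r\n", CR = "\r")

# base letters drawn uniformly; ambiguity codes mixed in at 5%
.base_codes <- list(
  dna = utf8ToInt("ACGT"),
  rna = utf8ToInt("ACGU"),
  protein = utf8ToInt("ACDEFGHIKLMNPQRSTVWY"),
  universal = utf8ToInt("ACDEFGHIKLMNPQRSTVWY")
)
.amb_codes <- list(
  dna = utf8ToInt(paste(.nt_ambiguity, collapse = "")),
  rna = utf8ToInt(paste(.nt_ambiguity, collapse = "")),
  protein = utf8ToInt("BZXJUO"),
  universal = utf8ToInt("BZXJUO")
)
# gap characters weighted so dashes dominate, as in real alignments; spaces
# kept rare to avoid whole lines of whitespace
.gap_codes <- utf8ToInt("-.* ")
.gap_weights <- c(0.55, 0.25, 0.12, 0.08)

run_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic FASTA fixture
#'
#' Parameters for deterministic generation of a valid (multi)FASTA file.
#' Record lengths are drawn uniformly from `[length_min, length_max]`;
#' residues are drawn uniformly from the mode's base letters (4 bases for
#' DNA/RNA, the 20 canonical amino acids otherwise) with a 5% chance of an
#' ambiguity code; `gap_prob` is the per-position chance of an alignment
#' character, emulating aligned reference sets. Shape, not biological
#' realism, is the goal.
#'
#' @param mode Parsing mode the fixture must validate under.
#' @param n_records Number of records.
#' @param length_min,length_max Residue positions per record (inclusive).
#' @param line_width Characters per wrapped sequence line.
#' @param terminator `"LF"`, `"CRLF"`, `"CR"` or `"MIXED"` (per-line random).
#' @param comment_prob Per-record probability of a `;` comment line after
#'   the header.
#' @param gap_prob Per-position probability of an alignment character.
#' @param seed Integer seed; same spec + same seed gives byte-identical
#'   output.
#' @return An object of class `"fixture_spec"`.
#' @export
#' @examples
#' fixture_spec(mode = "dna", n_records = 3, seed = 42)
fixture_spec <- function(mode = "universal", n_records = 10L,
                         length_min = 80L, length_max = 300L,
                         line_width = 70L,
                         terminator = c("LF", "CRLF", "CR", "MIXED"),
                         comment_prob = 0, gap_prob = 0, seed = 1L) {
  mode <- match_mode(mode)
  terminator <- match.arg(toupper(terminator[1L]), .terminator_styles)
  n_records <- as.integer(n_records)
  length_min <- as.integer(length_min)
  length_max <- as.integer(length_max)
  line_width <- as.integer(line_width)
  seed <- as.integer(seed)
  if (is.na(n_records) || n_records < 1L) stop("`n_records` must be a positive integer")
  if (is.na(length_min) || length_min < 1L) stop("`length_min` must be a positive integer")
  if (is.na(length_max) || length_max < length_min) {
    stop("`length_max` must be >= `length_min`")
  }
  if (is.na(line_width) || line_width < 1L) stop("`line_width` must be a positive integer")
  for (p in c(comment_prob, gap_prob)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("probabilities must be single numbers in [0, 1]")
    }
  }
  if (is.na(seed)) stop("`seed` must be an integer")
  structure(
    list(
      mode = mode, n_records = n_records,
      length_min = length_min, length_max = length_max,
      line_width = line_width, terminator = terminator,
      comment_prob = comment_prob, gap_prob = gap_prob, seed = seed
    ),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(
    "FASTA fixture spec: ", x$n_records, " ", x$mode, " record(s), lengths ",
    x$length_min, "-", x$length_max, ", width ", x$line_width,
    ", terminator ", x$terminator, ", comment_prob ", x$comment_prob,
    ", gap_prob ", x$gap_prob, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Generate one batch of records using the *current* RNG stream. Returns the
# text (single string) plus manifest ingredients.
.gen_batch <- function(spec, ids, want_manifest) {
  n <- length(ids)
  span <- spec$length_max - spec$length_min + 1L
  len <- spec$length_min + sample.int(span, n, replace = TRUE) - 1L
  total <- sum(len)
  bases <- .base_codes[[spec$mode]]
  ambs <- .amb_codes[[spec$mode]]
  codes <- bases[sample.int(length(bases), total, replace = TRUE)]
  amb <- stats::runif(total) < 0.05
  if (any(amb)) {
    codes[amb] <- ambs[sample.int(length(ambs), sum(amb), replace = TRUE)]
  }
  gap <- logical(total)
  if (spec$gap_prob > 0) {
    gap <- stats::runif(total) < spec$gap_prob
    if (any(gap)) {
      codes[gap] <- .gap_codes[sample.int(4L, sum(gap),
        replace = TRUE, prob = .gap_weights
      )]
    }
  }
  big <- intToUtf8(codes)
  cend <- cumsum(len)
  cstart <- cend - len + 1L
  w <- spec$line_width
  nlines <- (len + w - 1L) %/% w
  ls_rel <- sequence(nlines)
  rec_of <- rep.int(seq_len(n), nlines)
  gstart <- cstart[rec_of] + (ls_rel - 1L) * w
  gend <- pmin(gstart + w - 1L, cend[rec_of])
  slines <- substring(big, gstart, gend)
  # a wrapped line that came out all-spaces would lex as BLANK; anchor it
  allsp <- grepl("^ +$", slines)
  if (any(allsp)) {
    slines[allsp] <- paste0("-", substring(slines[allsp], 2L))
  }
  hdrs <- paste0(">", sprintf("rec%06d", ids), " synthetic ", spec$mode)
  has_cmt <- if (spec$comment_prob > 0) {
    stats::runif(n) < spec$comment_prob
  } else {
    logical(n)
  }
  cmts <- paste0("; synthetic record ", ids[has_cmt], recycle0 = TRUE)
  lines <- c(hdrs, cmts, slines)
  key_rec <- c(seq_len(n), which(has_cmt), rec_of)
  key_rank <- c(rep.int(0L, n), rep.int(1L, sum(has_cmt)), ls_rel + 1L)
  o <- order(key_rec, key_rank)
  lines <- lines[o]
  if (spec$terminator == "MIXED") {
    tchar <- unname(.terminator_chars[sample.int(3L, length(lines), replace = TRUE)])
  } else {
    tchar <- .terminator_chars[[spec$terminator]]
  }
  out <- list(text = paste0(paste0(lines, tchar), collapse = ""))
  if (want_manifest) {
    rec_of_pos <- rep.int(seq_len(n), len)
    out$lengths <- len
    out$gaps <- if (any(gap)) tabulate(rec_of_pos[gap], n) else integer(n)
    # tallies computed from the final lines (after the all-space fix-up)
    seq_only <- lines[!startsWith(lines, ">") & !startsWith(lines, ";")]
    out$tallies <- tabulate(
      utf8ToInt(paste0(seq_only, collapse = "")) + 1L, 256L
    )
  }
  out
}

#' Generate a valid FASTA fixture
#'
#' Deterministically produces a FASTA text that validates as valid under the
#' spec's mode, together with a manifest of per-record lengths and expected
#' letter counts. The manifest counts are tallied directly from the
#' generated characters, independently of the validator, so they double as
#' an oracle for [fasta_count_letters()].
#'
#' @param spec A [fixture_spec()].
#' @param manifest Compute the manifest (set `FALSE` to save time on very
#'   large fixtures).
#' @return An object of class `"fasta_fixture"`: list with `text` (single
#'   string) and `manifest` (list with `mode`, `n_records`,
#'   `record_lengths`, `record_gaps` and `letter_counts`, the latter a
#'   `"fasta_letter_counts"` object), or `NULL` manifest.
#' @export
#' @examples
#' fx <- generate_fasta(fixture_spec(mode = "dna", n_records = 2, seed = 7))
#' cat(fx$text)
generate_fasta <- function(spec, manifest = TRUE) {
  if (!inherits(spec, "fixture_spec")) stop("`spec` must be a fixture_spec()")
  run_with_seed(spec$seed, {
    batch <- 5000L
    starts <- seq(1L, spec$n_records, by = batch)
    texts <- vector("list", length(starts))
    lens <- integer(0)
    gaps <- integer(0)
    tallies <- integer(256)
    for (k in seq_along(starts)) {
      ids <- starts[k]:min(starts[k] + batch - 1L, spec$n_records)
      b <- .gen_batch(spec, ids, want_manifest = manifest)
      texts[[k]] <- b$text
      if (manifest) {
        lens <- c(lens, b$lengths)
        gaps <- c(gaps, b$gaps)
        tallies <- tallies + b$tallies
      }
    }
    man <- NULL
    if (manifest) {
      man <- list(
        mode = spec$mode,
        n_records = spec$n_records,
        record_lengths = lens,
        record_gaps = gaps,
        letter_counts = .letter_counts_from_tallies(tallies, spec$mode)
      )
    }
    structure(
      list(text = paste0(unlist(texts), collapse = ""), manifest = man),
      class = "fasta_fixture"
    )
  })
}

#' Write a FASTA fixture to disk, streaming
#'
#' Same generator as [generate_fasta()] (identical bytes for the same spec)
#' but records are written to `path` batch by batch, so fixtures far larger
#' than memory can be produced. Optionally writes the manifest as JSON.
#'
#' @param spec A [fixture_spec()].
#' @param path Output FASTA path.
#' @param manifest_path Optional path for a JSON manifest side-file.
#' @return Invisibly, the manifest list (or `NULL` when `manifest_path` is
#'   `NULL` and the fixture is large).
#' @export
write_fasta_fixture <- function(spec, path, manifest_path = NULL) {
  if (!inherits(spec, "fixture_spec")) stop("`spec` must be a fixture_spec()")
  want_manifest <- !is.null(manifest_path)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  man <- run_with_seed(spec$seed, {
    batch <- 5000L
    starts <- seq(1L, spec$n_records, by = batch)
    lens <- integer(0)
    gaps <- integer(0)
    tallies <- integer(256)
    for (k in seq_along(starts)) {
      ids <- starts[k]:min(starts[k] + batch - 1L, spec$n_records)
      b <- .gen_batch(spec, ids, want_manifest = want_manifest)
      writeBin(charToRaw(b$text), con)
      if (want_manifest) {
        lens <- c(lens, b$lengths)
        gaps <- c(gaps, b$gaps)
        tallies <- tallies + b$tallies
      }
    }
    if (!want_manifest) {
      NULL
    } else {
      lc <- .letter_counts_from_tallies(tallies, spec$mode)
      list(
        mode = spec$mode,
        n_records = spec$n_records,
        record_lengths = lens,
        record_gaps = gaps,
        letter_counts = list(
          residue = as.list(lc$residue),
          alignment = as.list(lc$alignment),
          total_residues = lc$total_residues,
          total_alignment = lc$total_alignment
        )
      )
    }
  })
  if (want_manifest) {
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(man)
}

#' Recipe for corrupting a valid FASTA text
#'
#' @param issue Target issue code, one of `NO_HEADER_AT_START`,
#'   `EMPTY_SEQUENCE`, `ILLEGAL_CHARACTER`, `MISPLACED_COMMENT`,
#'   `BLANK_LINE`, `EMPTY_FILE`.
#' @param policy `"random-record"` picks the corruption site with the
#'   recipe's seed; `"fixed-line"` targets the existing line given in
#'   `line`.
#' @param line Target line for the `"fixed-line"` policy (the header or
#'   sequence line the corruption acts on).
#' @param seed Integer seed for the `"random-record"` policy.
#' @return An object of class `"corruption_recipe"`.
#' @export
corruption_recipe <- function(issue, policy = c("random-record", "fixed-line"),
                              line = NULL, seed = 1L) {
  issue <- match.arg(issue, .issue_codes)
  policy <- match.arg(policy)
  if (policy == "fixed-line" && issue != "EMPTY_FILE" &&
    (is.null(line) || is.na(as.integer(line)) || as.integer(line) < 1L)) {
    stop("`line` must be a positive integer under the fixed-line policy")
  }
  structure(
    list(
      issue = issue, policy = policy,
      line = if (!is.null(line)) as.integer(line), seed = as.integer(seed)
    ),
    class = "corruption_recipe"
  )
}

.unrealizable <- function(msg) {
  structure(
    class = c("fasta_unrealizable_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Corrupt a valid FASTA text so it fails validation at a known position
#'
#' Applies a single, targeted corruption to a valid FASTA text and returns
#' the corrupted text together with the exact first issue (code, line,
#' column) the validator must report for it — a round-trip contract used to
#' exercise the validator. The input must itself be valid.
#'
#' @param text A valid FASTA text (single string).
#' @param recipe A [corruption_recipe()].
#' @return A list with `text` (corrupted FASTA) and `expected` (list with
#'   `code`, `line`, `column`, `offending`).
#' @export
#' @examples
#' fx <- generate_fasta(fixture_spec(mode = "dna", n_records = 2, seed = 3))
#' bad <- corrupt_fasta(fx$text, corruption_recipe("ILLEGAL_CHARACTER", seed = 9))
#' fasta_validate(text = bad$text, mode = "dna")$issues[1, ]
corrupt_fasta <- function(text, recipe) {
  if (!inherits(recipe, "corruption_recipe")) {
    stop("`recipe` must be a corruption_recipe()")
  }
  if (recipe$issue == "EMPTY_FILE") {
    return(list(
      text = "",
      expected = list(code = "EMPTY_FILE", line = 1L, column = 0L, offending = "")
    ))
  }
  toks <- fasta_tokenize(text = text, mode = "universal")
  body <- toks[toks$kind != "EOF", , drop = FALSE]
  term <- c(LF = "\n", CRLF = "\r\n", CR = "\r", NONE = "")

  pick <- function(cands, what) {
    if (recipe$policy == "fixed-line") {
      if (!(recipe$line %in% cands)) {
        stop(.unrealizable(paste0(
          "line ", recipe$line, " is not ", what,
          "; cannot realize ", recipe$issue
        )))
      }
      recipe$line
    } else {
      if (!length(cands)) {
        stop(.unrealizable(paste0("no ", what, " available for ", recipe$issue)))
      }
      run_with_seed(recipe$seed, cands[sample.int(length(cands), 1L)])
    }
  }
  insert_after <- function(i, newtext) {
    tc <- term[body$terminator[i]]
    if (tc == "") tc <- "\n" # unterminated final line: give both a newline
    before <- paste0(body$text[seq_len(i)], term[body$terminator[seq_len(i)]])
    before[i] <- paste0(body$text[i], tc)
    after <- if (i < nrow(body)) {
      j <- (i + 1L):nrow(body)
      paste0(body$text[j], term[body$terminator[j]])
    } else {
      character(0)
    }
    paste0(paste0(c(before, paste0(newtext, tc), after), collapse = ""))
  }

  switch(recipe$issue,
    NO_HEADER_AT_START = {
      if (body$kind[1L] != "HEADER") {
        stop(.unrealizable("text does not start with a header"))
      }
      rest <- body[-1L, , drop = FALSE]
      list(
        text = paste0(paste0(rest$text, term[rest$terminator]), collapse = ""),
        expected = list(
          code = "NO_HEADER_AT_START", line = 1L, column = 0L, offending = ""
        )
      )
    },
    EMPTY_SEQUENCE = {
      h <- pick(which(body$kind == "HEADER"), "a header line")
      list(
        text = insert_after(h, body$text[h]),
        expected = list(
          code = "EMPTY_SEQUENCE", line = h + 1L, column = 0L, offending = ""
        )
      )
    },
    ILLEGAL_CHARACTER = {
      cands <- which(body$kind == "SEQLINE" & nchar(body$text) > 0L)
      s <- pick(cands, "a non-empty sequence line")
      col <- run_with_seed(recipe$seed + 1L, sample.int(nchar(body$text[s]), 1L))
      body$text[s] <- paste0(
        substring(body$text[s], 1L, col - 1L), "!",
        substring(body$text[s], col + 1L)
      )
      list(
        text = paste0(paste0(body$text, term[body$terminator]), collapse = ""),
        expected = list(
          code = "ILLEGAL_CHARACTER", line = s, column = col, offending = "!"
        )
      )
    },
    MISPLACED_COMMENT = {
      s <- pick(which(body$kind == "SEQLINE"), "a sequence line")
      list(
        text = insert_after(s, "; misplaced comment"),
        expected = list(
          code = "MISPLACED_COMMENT", line = s + 1L, column = 0L, offending = ""
        )
      )
    },
    BLANK_LINE = {
      h <- pick(which(body$kind == "HEADER"), "a header line")
      list(
        text = insert_after(h, ""),
        expected = list(
          code = "BLANK_LINE", line = h + 1L, column = 0L, offending = ""
        )
      )
    }
  )
}
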