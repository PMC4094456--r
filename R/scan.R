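# Single-pass streaming engine shared by tokenize/validate/count/detect.
#
# The input is consumed as raw byte chunks. Each chunk is lexed with
# vectorised byte operations (line splitting across LF / CRLF / CR,
# classification by first character, first-invalid-character annotation,
# letter tallies); the grammar stage then walks runs of like-kinded lines,
# so its interpreted loop is proportional to the number of token runs, not
# bytes. Memory is bounded by the chunk size plus the longest line (a line
# longer than a chunk accumulates in the carry buffer until its terminator
# arrives).

.issue_codes <- c(
  "NO_HEADER_AT_START", "EMPTY_SEQUENCE", "ILLEGAL_CHARACTER",
  "MISPLACED_COMMENT", "BLANK_LINE", "EMPTY_FILE"
)

.kind_names <- c("HEADER", "COMMENT", "SEQLINE", "BLANK")

# printable rendering of a byte for issue messages
.off_char <- function(code) {
  if (is.na(code)) return("")
  if (code >= 32L && code <= 126L) rawToChar(as.raw(code)) else sprintf("\\x%02x", code)
}

.issue_message <- function(code, line, column, offending, mode) {
  switch(code,
    NO_HEADER_AT_START = sprintf("line %d: file content before the first '>' header", line),
    EMPTY_SEQUENCE = sprintf("line %d: header without any sequence line", line),
    ILLEGAL_CHARACTER = sprintf(
      "line %d, column %d: character '%s' not allowed in %s mode",
      line, column, offending, mode
    ),
    MISPLACED_COMMENT = sprintf("line %d: ';' comment allowed only directly after a header", line),
    BLANK_LINE = sprintf("line %d: blank line inside a record", line),
    EMPTY_FILE = "empty input: a FASTA file needs at least one record"
  )
}

# reader factory: returns function() -> raw chunk (length 0 at end of stream)
.make_reader <- function(file, text, chunk_size) {
  if (!is.null(text)) {
    if (!is.null(file)) stop("supply `file` or `text`, not both", call. = FALSE)
    if (!is.character(text) || length(text) != 1L || is.na(text)) {
      stop("`text` must be a single character string", call. = FALSE)
    }
    payload <- charToRaw(text)
    done <- FALSE
    return(list(
      read = function() {
        if (done) return(raw(0))
        done <<- TRUE
        payload
      },
      close = function() invisible()
    ))
  }
  if (is.null(file)) stop("supply one of `file` or `text`", call. = FALSE)
  if (inherits(file, "connection")) {
    con <- file
    owned <- FALSE
    if (!isOpen(con)) {
      open(con, "rb")
      owned <- TRUE
    }
  } else {
    if (!is.character(file) || length(file) != 1L || is.na(file)) {
      stop("`file` must be a path or a connection", call. = FALSE)
    }
    if (!file.exists(file)) {
      stop("cannot open file '", file, "': no such file", call. = FALSE)
    }
    con <- base::file(file, "rb")
    owned <- TRUE
  }
  list(
    read = function() readBin(con, what = "raw", n = chunk_size),
    close = function() if (owned) close(con) else invisible()
  )
}

fasta_scan <- function(file = NULL, text = NULL, mode = "universal",
                       chunk_size = 1048576L,
                       collect_tokens = FALSE,
                       fail_fast = FALSE,
                       max_issues = Inf,
                       allow_blank = FALSE,
                       count_letters = FALSE,
                       handler = NULL,
                       track_modes = NULL) {
  mode <- match_mode(mode)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) stop("`chunk_size` must be >= 1")
  if (!is.null(handler) && !inherits(handler, "fasta_handler")) {
    stop("`handler` must be built with fasta_handler()", call. = FALSE)
  }
  valid_tab <- .valid_tables[[mode]]
  need_text <- collect_tokens || !is.null(handler)

  track_tabs <- NULL
  rejections <- list()
  if (!is.null(track_modes)) {
    track_modes <- vapply(track_modes, match_mode, character(1), USE.NAMES = FALSE)
    track_tabs <- lapply(track_modes, function(m) .valid_tables[[m]])
    names(track_tabs) <- track_modes
    rejections <- stats::setNames(vector("list", length(track_modes)), track_modes)
  }

  rd <- .make_reader(file, text, chunk_size)
  on.exit(rd$close(), add = TRUE)

  # grammar state: 0 expect first header, 1 after header (need sequence),
  # 2 inside sequence, 3 blank run after a completed record (allow_blank)
  st <- 0L
  resync <- FALSE # skipping until next header after NO_HEADER_AT_START
  suppress <- FALSE # one ILLEGAL_CHARACTER per record
  pending_blank <- NA_integer_
  last_header_line <- NA_integer_
  line_no <- 0L
  byte_base <- 0
  nrec <- 0L
  naccept <- 0L
  stop_scan <- FALSE
  issues_code <- character(0)
  issues_line <- integer(0)
  issues_col <- integer(0)
  issues_off <- character(0)
  tallies <- if (count_letters) integer(256) else NULL
  token_chunks <- list()

  push_issue <- function(code, line, column, offending) {
    issues_code[length(issues_code) + 1L] <<- code
    issues_line[length(issues_line) + 1L] <<- line
    issues_col[length(issues_col) + 1L] <<- column
    issues_off[length(issues_off) + 1L] <<- offending
    if (fail_fast || length(issues_code) >= max_issues) stop_scan <<- TRUE
  }

  call_hook <- function(fn, kind, texts, i, starts, terms) {
    if (is.null(fn)) return(invisible())
    fn(structure(
      list(
        kind = kind, text = texts[i], line = line_no + i,
        byte_offset = byte_base + starts[i] - 1, terminator = terms[i]
      ),
      class = "fasta_token"
    ))
  }

  do_lines <- function(b, starts, cends, terms) {
    nl <- length(starts)
    lens <- cends - starts + 1L
    ib <- as.integer(b)
    first <- integer(nl)
    hascontent <- lens > 0L
    first[hascontent] <- ib[starts[hascontent]]
    kind <- rep.int(3L, nl)
    kind[first == 62L] <- 1L # '>'
    kind[first == 59L] <- 2L # ';'
    nonws <- !(ib == 32L | ib == 9L)
    cs <- c(0L, cumsum(nonws))
    kind[kind == 3L & (cs[cends + 1L] - cs[starts]) == 0L] <- 4L # BLANK

    bad_col <- rep(NA_integer_, nl)
    sel <- which(kind == 3L)
    if (length(sel)) {
      slens <- lens[sel]
      idx <- sequence(slens) + rep(starts[sel] - 1L, slens)
      lof <- rep.int(seq_along(sel), slens)
      codes <- ib[idx]
      badv <- !valid_tab[codes + 1L]
      if (any(badv)) {
        bp <- which(badv)
        fb <- bp[!duplicated(lof[bp])]
        bl <- lof[fb]
        bad_col[sel[bl]] <- idx[fb] - starts[sel[bl]] + 1L
      }
      if (count_letters) tallies <<- tallies + tabulate(codes + 1L, 256L)
      if (!is.null(track_tabs)) {
        for (m in names(track_tabs)) {
          if (!is.null(rejections[[m]])) next
          bm <- which(!track_tabs[[m]][codes + 1L])
          if (length(bm)) {
            j <- bm[1L]
            li <- sel[lof[j]]
            rejections[[m]] <<- list(
              line = line_no + li,
              column = idx[j] - starts[li] + 1L,
              offending = .off_char(codes[j])
            )
          }
        }
      }
    }

    texts <- NULL
    if (need_text) {
      if (any(b == as.raw(0L))) {
        stop("embedded NUL byte in input; not a text FASTA file", call. = FALSE)
      }
      s <- rawToChar(b)
      Encoding(s) <- "bytes"
      texts <- substring(s, starts, cends)
      Encoding(texts) <- "unknown"
    }

    if (collect_tokens) {
      token_chunks[[length(token_chunks) + 1L]] <<- data.frame(
        kind = .kind_names[kind],
        text = texts,
        line = line_no + seq_len(nl),
        byte_offset = byte_base + starts - 1,
        terminator = terms,
        bad_col = bad_col,
        stringsAsFactors = FALSE
      )
    }

    # grammar over runs of identical kinds
    r <- rle(kind)
    run_start <- cumsum(c(1L, r$lengths))
    for (ri in seq_along(r$values)) {
      if (stop_scan) break
      kv <- r$values[ri]
      cnt <- r$lengths[ri]
      i0 <- run_start[ri]
      if (kv == 3L) { # SEQLINE run
        if (st == 0L) {
          if (!resync) {
            push_issue("NO_HEADER_AT_START", line_no + i0, 0L, "")
            resync <<- TRUE
          }
          next
        }
        if (st == 3L) {
          push_issue("BLANK_LINE", pending_blank, 0L, "")
          if (stop_scan) break
        }
        st <<- 2L
        ii <- i0:(i0 + cnt - 1L)
        bc <- bad_col[ii]
        nb <- which(!is.na(bc))
        if (length(nb) && !suppress) {
          j <- nb[1L]
          li <- ii[j]
          off <- .off_char(ib[starts[li] + bc[j] - 1L])
          push_issue("ILLEGAL_CHARACTER", line_no + li, bc[j], off)
          suppress <<- TRUE
        }
        ok <- if (length(nb)) ii[-nb] else ii
        if (stop_scan) ok <- ok[ok < ii[nb[1L]]]
        naccept <<- naccept + length(ok)
        if (!is.null(handler)) {
          for (i in ok) call_hook(handler$on_sequence_line, "SEQLINE", texts, i, starts, terms)
        }
      } else if (kv == 1L) { # HEADER run
        for (j in seq_len(cnt)) {
          li <- i0 + j - 1L
          if (st == 1L) {
            push_issue("EMPTY_SEQUENCE", line_no + li, 0L, "")
            if (stop_scan) break
          }
          st <<- 1L
          resync <<- FALSE
          suppress <<- FALSE
          last_header_line <<- line_no + li
          nrec <<- nrec + 1L
          naccept <<- naccept + 1L
          if (!is.null(handler)) call_hook(handler$on_header, "HEADER", texts, li, starts, terms)
          if (stop_scan) break
        }
      } else if (kv == 2L) { # COMMENT run
        if (st == 0L) {
          if (!resync) {
            push_issue("NO_HEADER_AT_START", line_no + i0, 0L, "")
            resync <<- TRUE
          }
        } else if (st == 1L) {
          naccept <<- naccept + cnt
          if (!is.null(handler)) {
            for (i in i0:(i0 + cnt - 1L)) call_hook(handler$on_comment, "COMMENT", texts, i, starts, terms)
          }
        } else {
          if (st == 3L) {
            push_issue("BLANK_LINE", pending_blank, 0L, "")
            st <<- 2L
          }
          for (j in seq_len(cnt)) {
            if (stop_scan) break
            push_issue("MISPLACED_COMMENT", line_no + i0 + j - 1L, 0L, "")
          }
        }
      } else { # BLANK run
        if (st == 0L && resync) {
          next
        } else if (st == 2L && allow_blank) {
          st <<- 3L
          pending_blank <<- line_no + i0
        } else if (st == 3L) {
          # extend a tolerated inter-record blank run
        } else {
          for (j in seq_len(cnt)) {
            if (stop_scan) break
            push_issue("BLANK_LINE", line_no + i0 + j - 1L, 0L, "")
          }
        }
      }
    }
    nl
  }

  carry <- raw(0)
  repeat {
    if (stop_scan) break
    chunk <- rd$read()
    final <- length(chunk) == 0L
    buf <- if (length(carry)) c(carry, chunk) else chunk
    n <- length(buf)
    if (n == 0L && final) break
    lf <- buf == as.raw(10L)
    cr <- buf == as.raw(13L)
    is_end <- lf | (cr & !c(lf[-1L], FALSE))
    ends <- which(is_end)
    if (!final && length(ends) && ends[length(ends)] == n && buf[n] == as.raw(13L)) {
      ends <- ends[-length(ends)] # trailing CR might be half a CRLF
    }
    last_end <- if (length(ends)) ends[length(ends)] else 0L
    if (final) {
      proc_n <- n
    } else {
      proc_n <- last_end
    }
    if (proc_n > 0L || final) {
      b <- buf[seq_len(proc_n)]
      carry <- if (proc_n < n) buf[(proc_n + 1L):n] else raw(0)
      if (length(ends) || (final && proc_n > 0L)) {
        at_lf <- buf[ends] == as.raw(10L)
        crlf <- at_lf & ends > 1L & buf[pmax(ends - 1L, 1L)] == as.raw(13L)
        tlen <- ifelse(at_lf, ifelse(crlf, 2L, 1L), 1L)
        terms <- ifelse(at_lf, ifelse(crlf, "CRLF", "LF"), "CR")
        starts <- c(1L, ends[-length(ends)] + 1L)
        if (!length(ends)) starts <- integer(0)
        cends <- ends - tlen
        if (final && last_end < proc_n) {
          starts <- c(starts, if (length(ends)) last_end + 1L else 1L)
          cends <- c(cends, proc_n)
          terms <- c(terms, "NONE")
        }
        if (length(starts)) {
          line_no <- line_no + do_lines(b, starts, cends, terms)
        }
      }
      byte_base <- byte_base + proc_n
    } else {
      carry <- buf
    }
    if (final) break
  }

  # EOF stage: runs only if the scan was not cut short by fail_fast/max_issues
  eof_accepted <- FALSE
  if (!stop_scan) {
    if (line_no == 0L) {
      push_issue("EMPTY_FILE", 1L, 0L, "")
    } else if (st == 1L) {
      push_issue("EMPTY_SEQUENCE", last_header_line, 0L, "")
    }
    if (!stop_scan) {
      eof_accepted <- TRUE
      naccept <- naccept + 1L
      if (!is.null(handler) && !is.null(handler$on_eof)) {
        handler$on_eof(structure(
          list(
            kind = "EOF", text = "", line = line_no + 1L,
            byte_offset = byte_base, terminator = "NONE"
          ),
          class = "fasta_token"
        ))
      }
    }
  }

  list(
    mode = mode,
    issues = data.frame(
      code = issues_code,
      message = vapply(seq_along(issues_code), function(i) {
        .issue_message(issues_code[i], issues_line[i], issues_col[i], issues_off[i], mode)
      }, character(1)),
      line = issues_line,
      column = issues_col,
      offending = issues_off,
      stringsAsFactors = FALSE
    ),
    record_count = nrec,
    line_count = line_no,
    accepted = naccept,
    total_bytes = byte_base,
    tallies = tallies,
    rejections = rejections,
    tokens = token_chunks,
    eof_accepted = eof_accepted
  )
}
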