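# Letter-counting benchmark statistic and candidate-alphabet detection.

# Fold a 256-slot byte tally into a letter-counts object. Residue counts are
# case-folded to uppercase; alignment characters are tallied separately so
# both "with gaps" and "without gaps" totals stay available.
.letter_counts_from_tallies <- function(tallies, mode) {
  residues <- .residue_sets[[mode]]
  up <- utf8ToInt(paste(residues, collapse = ""))
  lo <- utf8ToInt(tolower(paste(residues, collapse = "")))
  res_counts <- tallies[up + 1L] + tallies[lo + 1L]
  names(res_counts) <- residues
  res_counts <- res_counts[res_counts > 0L]
  aln_codes <- utf8ToInt(paste(.alignment_chars, collapse = ""))
  aln_counts <- tallies[aln_codes + 1L]
  names(aln_counts) <- .alignment_chars
  aln_counts <- aln_counts[aln_counts > 0L]
  structure(
    list(
      mode = mode,
      residue = res_counts,
      alignment = aln_counts,
      total_residues = sum(res_counts),
      total_alignment = sum(aln_counts)
    ),
    class = "fasta_letter_counts"
  )
}

#' Count valid letters in a FASTA stream
#'
#' Counts every residue letter (case-folded to uppercase) across all
#' sequence lines; alignment characters (space, `-`, `.`, `*`) are tallied
#' separately and excluded from the residue total. Header and comment
#' characters are never counted. Counting includes validation: any
#' validation issue under `mode` aborts with an error of class
#' `"fasta_validation_error"` carrying the issue.
#'
#' @inheritParams fasta_tokenize
#' @return An object of class `"fasta_letter_counts"`: a list with named
#'   integer vectors `residue` and `alignment` (letters observed at least
#'   once) and totals `total_residues` and `total_alignment`.
#' @export
#' @examples
#' fasta_count_letters(text = ">a\nAC-GT\n..\n", mode = "dna")
fasta_count_letters <- function(file = NULL, text = NULL, mode = "universal",
                                chunk_size = 1048576L) {
  res <- fasta_scan(
    file = file, text = text, mode = mode, chunk_size = chunk_size,
    fail_fast = TRUE, count_letters = TRUE
  )
  if (nrow(res$issues) > 0L) {
    stop(.fasta_invalid_error(res$issues[1L, , drop = FALSE]))
  }
  .letter_counts_from_tallies(res$tallies, res$mode)
}

#' @export
print.fasta_letter_counts <- function(x, ...) {
  cat("Letter counts (", x$mode, " mode)\n", sep = "")
  if (length(x$residue)) {
    cat("  residues: ")
    cat(paste0(names(x$residue), "=", x$residue), sep = " ")
    cat("\n")
  }
  if (length(x$alignment)) {
    cat("  alignment: ")
    cat(paste0(gsub(" ", "<space>", names(x$alignment)), "=", x$alignment), sep = " ")
    cat("\n")
  }
  cat(
    "  total residues: ", x$total_residues,
    " | total alignment: ", x$total_alignment, "\n",
    sep = ""
  )
  invisible(x)
}

#' Convert letter counts to a two-column data frame
#'
#' @param x A `"fasta_letter_counts"` object.
#' @param ... Unused.
#' @return Data frame with columns `letter`, `class` (`residue`/`alignment`)
#'   and `count`, the form written as TSV by the command-line interface.
#' @export
as.data.frame.fasta_letter_counts <- function(x, ...) {
  data.frame(
    letter = c(names(x$residue), names(x$alignment)),
    class = c(
      rep("residue", length(x$residue)),
      rep("alignment", length(x$alignment))
    ),
    count = c(unname(x$residue), unname(x$alignment)),
    stringsAsFactors = FALSE
  )
}

#' Detect candidate alphabets of a FASTA stream
#'
#' Returns every specific mode (`dna`, `rna`, `protein`) under which all
#' sequence characters are legal. Because the amino-acid and nucleotide
#' alphabets overlap (especially with ambiguity codes included), forcing a
#' single answer is not robust; the result is deliberately the honest
#' candidate *set*, with the first offending position reported for each
#' rejected mode. The input must be valid under the universal mode,
#' otherwise an error of class `"fasta_validation_error"` is raised.
#'
#' @inheritParams fasta_tokenize
#' @return An object of class `"fasta_alphabet_detection"`: a list with
#'   `candidates` (character vector of accepted modes) and `rejections`
#'   (data frame with columns `mode`, `line`, `column`, `offending` for the
#'   first rejecting character of each non-candidate mode).
#' @export
#' @examples
#' fasta_detect_alphabet(text = ">a\nACGT\n") # DNA or protein, not RNA
fasta_detect_alphabet <- function(file = NULL, text = NULL,
                                  chunk_size = 1048576L) {
  specific <- c("dna", "rna", "protein")
  res <- fasta_scan(
    file = file, text = text, mode = "universal", chunk_size = chunk_size,
    fail_fast = TRUE, track_modes = specific
  )
  if (nrow(res$issues) > 0L) {
    stop(.fasta_invalid_error(res$issues[1L, , drop = FALSE]))
  }
  rej <- res$rejections
  rejected <- specific[!vapply(rej, is.null, logical(1))]
  rejections <- data.frame(
    mode = rejected,
    line = vapply(rej[rejected], function(x) as.integer(x$line), integer(1)),
    column = vapply(rej[rejected], function(x) as.integer(x$column), integer(1)),
    offending = vapply(rej[rejected], function(x) x$offending, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(rejections) <- NULL
  structure(
    list(
      candidates = setdiff(specific, rejected),
      rejections = rejections
    ),
    class = "fasta_alphabet_detection"
  )
}

#' @export
print.fasta_alphabet_detection <- function(x, ...) {
  if (length(x$candidates)) {
    cat("Candidate alphabets:", paste(x$candidates, collapse = ", "), "\n")
  } else {
    cat("Candidate alphabets: none (only the universal mode accepts this input)\n")
  }
  if (nrow(x$rejections)) {
    for (i in seq_len(nrow(x$rejections))) {
      cat(
        "  ", x$rejections$mode[i], ": rejected at line ",
        x$rejections$line[i], ", column ", x$rejections$column[i],
        " ('", x$rejections$offending[i], "')\n",
        sep = ""
      )
    }
  }
  invisible(x)
}
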