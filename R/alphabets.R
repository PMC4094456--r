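# IUPAC residue alphabets for the four parsing modes, all extended by the
# alignment characters (space, dash, dot, asterisk). Residue membership is
# case-insensitive; counts and reports are case-folded to uppercase.

.fasta_modes <- c("universal", "dna", "rna", "protein")

.nt_ambiguity <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.residue_sets <- local({
  dna <- c("A", "C", "G", "T", .nt_ambiguity)
  rna <- c("A", "C", "G", "U", .nt_ambiguity)
  # 20 canonical amino acids + IUPAC ambiguity/unknown (B, Z, X) + the later
  # additions J (Leu/Ile), U (selenocysteine), O (pyrrolysine)
  protein <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
    "B", "Z", "X", "J", "U", "O"
  )
  list(
    dna = sort(dna),
    rna = sort(rna),
    protein = sort(protein),
    universal = sort(unique(c(dna, rna, protein)))
  )
})

.alignment_chars <- c(" ", "-", ".", "*")

# 256-entry logical lookup tables indexed by byte value + 1; the workhorse of
# the lexer's character validation.
.byte_table <- function(chars) {
  tab <- logical(256)
  tab[utf8ToInt(paste(chars, collapse = "")) + 1L] <- TRUE
  tab
}

.residue_tables <- lapply(.residue_sets, function(set) {
  .byte_table(c(set, tolower(set)))
})

.alignment_table <- .byte_table(.alignment_chars)

.valid_tables <- lapply(.residue_tables, function(tab) tab | .alignment_table)

match_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L || is.na(mode)) {
    stop("`mode` must be one of: ", paste(.fasta_modes, collapse = ", "),
      call. = FALSE
    )
  }
  m <- .fasta_modes[match(tolower(mode), .fasta_modes)]
  if (is.na(m)) {
    stop(
      "unknown mode '", mode, "'; must be one of: ",
      paste(.fasta_modes, collapse = ", "),
      call. = FALSE
    )
  }
  m
}

#' Names of the four FASTA parsing modes
#'
#' @return Character vector `c("universal", "dna", "rna", "protein")`.
#' @export
#' @examples
#' fasta_modes()
fasta_modes <- function() .fasta_modes

#' IUPAC alphabet backing a parsing mode
#'
#' Each parsing mode validates sequence lines against a fixed residue
#' alphabet plus the four alignment characters (space, dash, dot, asterisk)
#' needed for aligned sequence sets. The DNA and RNA alphabets hold the four
#' bases and the eleven IUPAC ambiguity codes and differ only in T versus U;
#' the protein alphabet holds the twenty canonical amino acids plus the
#' ambiguity/unknown codes B, Z, X and the extensions J, U, O; the universal
#' alphabet is the union of all three. Residue membership is
#' case-insensitive in every mode.
#'
#' @param mode One of `"universal"`, `"dna"`, `"rna"`, `"protein"`
#'   (case-insensitive).
#' @return An object of class `"fasta_alphabet"`: a list with elements
#'   `name`, `residues` (uppercase character vector), `alignment` and
#'   `case_insensitive` (always `TRUE`).
#' @export
#' @examples
#' fasta_alphabet("dna")
#' setdiff(fasta_alphabet("rna")$residues, fasta_alphabet("dna")$residues)
fasta_alphabet <- function(mode) {
  mode <- match_mode(mode)
  structure(
    list(
      name = mode,
      residues = .residue_sets[[mode]],
      alignment = .alignment_chars,
      case_insensitive = TRUE
    ),
    class = "fasta_alphabet"
  )
}

#' @export
print.fasta_alphabet <- function(x, ...) {
  cat("FASTA alphabet:", x$name, "\n")
  cat(
    "  residues  (", length(x$residues), "): ",
    paste(x$residues, collapse = ""), "\n",
    sep = ""
  )
  cat(
    "  alignment ( ", length(x$alignment), "): ",
    paste(gsub(" ", "<space>", x$alignment), collapse = " "), "\n",
    sep = ""
  )
  cat("  case-insensitive:", x$case_insensitive, "\n")
  invisible(x)
}

#' Classify characters under a parsing mode
#'
#' Total membership test underlying the lexer: each single character is a
#' residue letter (case-insensitive), an alignment character, or invalid for
#' the given mode.
#'
#' @param chars Character vector of single characters.
#' @param mode Parsing mode (see [fasta_modes()]).
#' @return Character vector the same length as `chars` with values
#'   `"residue"`, `"alignment"` or `"invalid"`.
#' @export
#' @examples
#' fasta_char_class(c("a", "T", ".", "!"), "dna")
fasta_char_class <- function(chars, mode) {
  mode <- match_mode(mode)
  if (!is.character(chars)) stop("`chars` must be a character vector")
  if (length(chars) && any(nchar(chars, type = "chars") != 1L, na.rm = TRUE)) {
    stop("every element of `chars` must be a single character")
  }
  res_tab <- .residue_tables[[mode]]
  out <- rep("invalid", length(chars))
  codes <- vapply(chars, function(ch) {
    if (is.na(ch)) return(NA_integer_)
    utf8ToInt(ch)
  }, integer(1), USE.NAMES = FALSE)
  ascii <- !is.na(codes) & codes < 256L
  out[ascii & res_tab[pmin(codes, 255L) + 1L]] <- "residue"
  out[ascii & .alignment_table[pmin(codes, 255L) + 1L]] <- "alignment"
  out[is.na(codes)] <- NA_character_
  out
}
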