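---
title: "Validating FASTA files with a lexer and a grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating FASTA files with a lexer and a grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastacheck)
```

## The problem

FASTA is the de-facto exchange format for biological sequences: a record is
a `>` header line followed by one or more sequence lines, and a file may
hold millions of records. Because the format looks trivial, tools often
parse it with ad-hoc code that silently mishandles the three line-ending
dialects (Unix `LF`, Windows `CRLF`, classic Mac `CR`), accepts characters
that are not legal residues, or ignores structural damage such as a header
with no sequence. Aligned reference sets add a further wrinkle: their
sequence lines legitimately contain gap and stop characters (space, dash,
dot, asterisk) that many parsers reject. Invalid sequences that slip
through propagate into downstream analyses as wrong results, so a
validator's job is to give a precise, reproducible verdict with exact
line/column positions — fast enough for high-volume data.

`fastacheck` treats validation as a small compiler front end, in two
stages:

1. **Lexer.** The byte stream is split into lines and each line becomes a
   token, classified by its first character: `>` → `HEADER`, `;` →
   `COMMENT`, empty or whitespace-only → `BLANK`, anything else →
   `SEQLINE`; a synthetic `EOF` token closes the stream. All three
   terminator styles are recognised, mixed freely within one file, and a
   final unterminated line is a complete token. Sequence lines are checked
   against the active alphabet; an offending line is still emitted as a
   token, annotated with the column of its first invalid character.
2. **Grammar.** Token order must satisfy

   ```
   file   := record+ EOF
   record := HEADER COMMENT* SEQLINE+
   ```

   A file whose tokens are all individually correct and correctly ordered
   is valid. Everything else becomes a `ValidationIssue` from a closed
   catalogue: `NO_HEADER_AT_START`, `EMPTY_SEQUENCE`, `ILLEGAL_CHARACTER`,
   `MISPLACED_COMMENT`, `BLANK_LINE`, `EMPTY_FILE`. Lines and columns are
   1-based (column 0 marks whole-line issues); byte offsets are 0-based.

Each accepted token can additionally fire a user callback
(`fasta_handler()`), so streaming consumers can build their own data
structures without a second pass; `fasta_records()` is exactly such a
consumer.

## Alphabets and modes

Four parsing modes define the legal sequence characters, following the
IUPAC one-letter codes:

* `dna` — the bases `ACGT` plus the eleven ambiguity codes
  `RYSWKMBDHVN`;
* `rna` — the same set with `U` in place of `T`;
* `protein` — the twenty canonical amino acids plus the ambiguity/unknown
  codes `B`, `Z`, `X` and the later additions `J` (Leu/Ile ambiguity),
  `U` (selenocysteine) and `O` (pyrrolysine);
* `universal` — the union of the three, accepting any (multi)FASTA file.

Residue matching is case-insensitive everywhere; reported counts are
case-folded to uppercase. Every mode is extended by the four **alignment
characters** — space, `-`, `.`, `*` — so aligned sequence sets (for
example rRNA reference alignments, which use dots heavily) validate
without preprocessing. `*` is treated as an alignment character in every
mode rather than as a protein-only stop, keeping the extension set
identical across modes.

Two consequences of this composition are worth stating explicitly. With
`J`, `U` and `O` included, the protein alphabet covers all 26 letters, so
the universal residue set is `A–Z`; and because the nucleotide sets are
subsets of it, any file valid under a specific mode is valid under
`universal`. The inclusion of `J/U/O` is a deliberate design choice — the
IUPAC extensions are needed for modern protein databases, which annotate
selenocysteine and pyrrolysine — and it is what makes the subset
structure, and hence mode monotonicity, hold exactly.

## Grammar decisions on points the format leaves open

The classic FASTA dialect is informal, so a validator has to fix several
semantics. The choices here, all surfaced in the issue catalogue:

* **Comments** (`;` lines, from the original FASTA dialect) are legal only
  immediately after a header, in any number. A comment anywhere else is
  `MISPLACED_COMMENT`.
* **Empty records are invalid**: a header followed by another header or by
  EOF yields `EMPTY_SEQUENCE`. When EOF triggers it, the issue is reported
  at the offending header's line so positions always point inside the
  input.
* **Empty header text** (`>` alone) is valid — the grammar constrains
  order, not header content.
* **Blank lines are issues by default.** The option
  `allow_blank_between_records` tolerates them between a record's last
  sequence line and the next header, and equally between the last record
  and EOF (trailing empty lines are ubiquitous in real files); blanks
  before the first header, after a header, or between sequence lines of
  one record remain issues either way.
* **Error recovery**: without `fail_fast` the validator resynchronizes at
  the next header after an issue, and at most one `ILLEGAL_CHARACTER` is
  reported per record, so one corrupt record yields one issue rather than
  a cascade. `fail_fast` stops at the first issue, and is guaranteed to
  agree with the full scan on that issue's code, line and column.
* **Encoding**: input is treated as ASCII-compatible bytes. Non-ASCII
  bytes are legal in header and comment text only; in a sequence line they
  are illegal characters like any other byte outside the alphabet.

## Streaming implementation and its numerical edges

The engine reads raw chunks (default 1 MiB) and lexes each chunk with
vectorised byte operations; the grammar walks *runs* of same-kinded lines,
so interpreted work scales with the number of token runs rather than with
bytes. Memory is bounded by the chunk size plus the longest line: a line
longer than a chunk simply accumulates in a carry buffer until its
terminator arrives. Two boundary cases are handled explicitly: a chunk
ending in `CR` is held back because the terminator could be a split
`CRLF`, and token streams are therefore invariant to chunk size (checked
down to 1-byte chunks). Counting uses a 256-slot byte tally per chunk,
folded to letters once at the end, so letter counts are exact integers at
any file size.

## The fixture generator

Real evaluation corpora (genomes, protein databases, aligned rRNA sets)
are large and external, so the package carries its own synthetic test
surface. `generate_fasta()` emulates the *shapes* that matter to a
parser, not biological realism:

* record lengths uniform on `[length_min, length_max]`; residues uniform
  over the mode's base letters (4 bases, or the 20 canonical amino acids)
  with a 5% chance of an ambiguity code;
* `gap_prob` converts positions into alignment characters (dash-weighted,
  with rare spaces), emulating aligned reference sets; a wrapped line that
  would come out entirely spaces is anchored with a dash, since it would
  otherwise lex as `BLANK`;
* optional `;` comments per record, any terminator style including
  per-line `MIXED`, configurable wrap width.

All randomness flows through R's RNG seeded from the spec, so the same
spec gives byte-identical output, and the caller's RNG state is restored
afterwards. The manifest (per-record lengths and letter tallies) is
computed directly from the drawn characters, independently of the
validator — which is what lets the test suite compare
`fasta_count_letters()` against generation-time truth. The defaults
(10 records of 80–300 residues, 70-character lines) are the shape of a
small protein FASTA; tests vary them per case.

`corrupt_fasta()` applies exactly one targeted corruption (delete the
first header, duplicate a header, plant a `!`, insert a misplaced comment
or blank line, or truncate to an empty file) and returns the precise first
issue the validator must report; unrealizable requests (for example
targeting a header line with an illegal-character recipe) raise a
dedicated error rather than producing an unpredictable fixture.

Because the generator draws from letters legal in its mode and the
corruptions are single and local, passing the round-trip checks shows the
validator's positional accuracy, not its behaviour on pathological real
data (deep non-ASCII damage, interleaved partial records); those cases
are covered separately by fuzzed token-string tests, which explore the
grammar space exhaustively at short lengths.

## Letter counting and alphabet detection

`fasta_count_letters()` implements the validate-and-count scenario used to
exercise the parser end to end: validation is included, so invalid input
aborts with the first issue rather than returning counts of dubious
meaning. Alignment characters are tallied separately from residues and
excluded from `total_residues`; whether gaps should count as "valid
letters" is a convention that differs between tools, so both totals are
reported and either reading can be compared.

`fasta_detect_alphabet()` returns the *set* of specific modes whose
alphabet accepts every sequence character, with the first rejecting
position for each excluded mode. The set is deliberately never collapsed
to a single guess: nucleotide and amino-acid alphabets overlap
substantially (every DNA letter is also a protein letter once ambiguity
codes are included), so `ACGT` honestly yields `{dna, protein}` and a
heuristic tie-break would be guesswork. The invariant tying the API
together: `m` is a candidate exactly when `fasta_validate(..., mode = m)`
passes.

## Verification scale

The package verifies itself with property checks at fixed sizes chosen to
exercise each contract thoroughly while staying quick on one CPU: the
grammar verdict is compared against a brute-force regular-grammar
recognizer on all 1,365 token-kind strings up to length 5; line-ending
invariance on 500 fuzzed documents across four terminator rewrites;
letter counts against an independent character scan on 1,000 generated
files over all four modes; 500 generate→corrupt→validate round trips;
detection/validation consistency on 300 files (900 mode checks); and a
~100 MB, 100,000-record file validated from disk, asserting that peak
heap does not grow with input size. `scripts/acceptance.R` reruns all of
these from scratch against the installed package and writes the measured
agreement percentages and throughput as JSON.

## Limitations

* FASTQ, gzip transparency and multi-byte encodings in sequence lines are
  out of scope (compressed input can be piped in via a shell).
* Lint-style checks beyond validity — duplicate IDs, inconsistent aligned
  lengths, wrap-width uniformity — are deliberately not validity rules
  here.
* Validation throughput in R (roughly 8 MB/s on commodity hardware) is
  ample for QC of assemblies and reference sets but well below what a
  compiled lexer achieves; the architecture keeps the hot path vectorised
  so the constant factor, not the memory profile, is the cost.
* The candidate-set detector reports letter-compatibility, not biological
  likelihood; it will happily report that a protein file of only
  `ACGTN`-composition letters "could be" DNA, because it could.
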