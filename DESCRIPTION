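Package: fastacheck
Title: Streaming Validation and Parsing of FASTA Sequence Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming lexer-plus-grammar validator for (multi)FASTA files.
    Four IUPAC-based parsing modes (universal, DNA, RNA, protein) extended with
    the alignment characters (space, dash, dot, asterisk) accept plain-text
    sequence data with Unix, Windows or classic Mac line endings. The lexer
    turns the character stream into header, comment, sequence-line, blank and
    end-of-file tokens in constant memory; a grammar stage checks their order,
    reports precise line/column issues, and fires user-defined callbacks per
    accepted token. Utilities count valid residue and alignment letters,
    detect candidate alphabets (returning the honest candidate set rather than
    a forced guess), generate deterministic valid or deliberately corrupted
    fixture files, and expose the whole pipeline through a shell-friendly
    command-line interface with stable exit codes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
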