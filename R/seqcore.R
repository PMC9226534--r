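#' @useDynLib lahr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats rbinom rmultinom runif setNames
#' @importFrom utils modifyList write.table
"_PACKAGE"

# IUPAC nucleotide codes and their expansions; patterns may use any of these,
# loci are restricted to the concrete four bases.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_dna <- function(seq, what = "sequence", iupac = FALSE, allow_empty = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(seq)) {
    if (allow_empty) return(invisible(seq))
    stop(what, " must be non-empty", call. = FALSE)
  }
  pat <- if (iupac) "^[ACGTRYSWKMBDHVN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq))
    stop(what, " contains characters outside the ",
         if (iupac) "IUPAC" else "{A,C,G,T}", " alphabet", call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement, 5'->3'. IUPAC ambiguity codes are
#' complemented to their mirror codes (R<->Y, K<->M, B<->V, D<->H; S, W, N are
#' self-complementary), so the function is an involution on any valid input.
#'
#' @param seq a single DNA string over the IUPAC alphabet (upper case).
#' @return the reverse complement as a single string; `""` for `""`.
#' @examples
#' revcomp("TTTC")  # "GAAA"
#' @export
revcomp <- function(seq) {
  if (identical(seq, "")) return("")
  check_dna(seq, "seq", iupac = TRUE)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Find all matches of an IUPAC pattern on one strand
#'
#' Locates every (possibly overlapping) occurrence of an IUPAC pattern such as
#' the AsCas12a PAM `"TTTV"` or the SpCas9 PAM `"NGG"` in a concrete DNA
#' sequence. Matching is delegated to [Biostrings::matchPattern()] with the
#' subject held fixed, so ambiguity codes are active in the pattern only.
#'
#' @param pattern non-empty IUPAC pattern string.
#' @param seq concrete DNA string to search (only A/C/G/T).
#' @return integer vector of 1-based match start positions, ascending; may be
#'   empty.
#' @examples
#' iupac_find("TTTV", "AATTTCGG")  # 3
#' @export
iupac_find <- function(pattern, seq) {
  check_dna(pattern, "pattern", iupac = TRUE)
  check_dna(seq, "seq", allow_empty = TRUE)
  if (!nzchar(seq) || nchar(seq) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = "subject")
  sort(Biostrings::start(m))
}

#' Single-base synonymous substitutions of a codon
#'
#' Enumerates every single-nucleotide change of a codon that leaves the encoded
#' amino acid unchanged under the standard genetic code (stop codons included:
#' stop-to-stop changes count as synonymous). This is the primitive behind
#' codon-aware silent PAM/seed disruption.
#'
#' @param codon a 3-letter DNA string over A/C/G/T.
#' @return data.frame with columns `offset` (1-based position within the codon),
#'   `alt` (replacement base) and `codon` (the resulting codon); zero rows when
#'   no single-base synonym exists (e.g. ATG, TGG).
#' @examples
#' synonymous_substitutions("CTG")  # CTA/CTC/CTT and TTG all encode Leu
#' @export
synonymous_substitutions <- function(codon) {
  check_dna(codon, "codon")
  if (nchar(codon) != 3L) stop("codon must be exactly 3 bases", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[[codon]])
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (off in 1:3) {
    for (b in setdiff(bases, substr(codon, off, off))) {
      alt_codon <- codon
      substr(alt_codon, off, off) <- b
      if (identical(unname(code[[alt_codon]]), aa))
        out[[length(out) + 1L]] <- data.frame(offset = off, alt = b,
                                              codon = alt_codon,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(offset = integer(0), alt = character(0),
                      codon = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' CDS annotation for a locus
#'
#' @param start,end 1-based inclusive interval of the coding region on the
#'   locus top strand.
#' @param strand `"+"` or `"-"`: strand on which the CDS is read.
#' @param frame 0, 1 or 2: number of bases at the CDS 5' end (on `strand`)
#'   before the first complete codon.
#' @return an object of class `cds_annotation`.
#' @export
cds_annotation <- function(start, end, strand = "+", frame = 0L) {
  start <- as.integer(start); end <- as.integer(end); frame <- as.integer(frame)
  stopifnot(length(start) == 1L, length(end) == 1L, start >= 1L, end >= start)
  strand <- match.arg(strand, c("+", "-"))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  if ((end - start + 1L - frame) %% 3L != 0L)
    stop("CDS length minus frame offset must be a multiple of 3", call. = FALSE)
  structure(list(start = start, end = end, strand = strand, frame = frame),
            class = "cds_annotation")
}

#' Construct a locus
#'
#' A locus is the coordinate frame for all designs: a named, upper-case DNA
#' sequence over A/C/G/T (ambiguity codes rejected — designs must be concrete
#' sequences) with an optional CDS annotation used for codon-aware silent
#' mutagenesis. All coordinates in this package are 1-based inclusive on the
#' locus top strand.
#'
#' @param seq DNA string; lower case is normalised to upper case.
#' @param name identifier for reports and FASTA output.
#' @param cds optional [cds_annotation()].
#' @return an object of class `locus`.
#' @export
locus <- function(seq, name = "locus", cds = NULL) {
  seq <- toupper(seq)
  check_dna(seq, "locus seq")
  if (!is.null(cds)) {
    if (!inherits(cds, "cds_annotation"))
      stop("cds must be a cds_annotation()", call. = FALSE)
    if (cds$end > nchar(seq))
      stop("CDS interval extends beyond the locus", call. = FALSE)
  }
  structure(list(name = as.character(name), seq = seq, cds = cds),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus> ", x$name, ": ", nchar(x$seq), " bp", sep = "")
  if (!is.null(x$cds))
    cat(sprintf("; CDS [%d,%d] %s frame %d", x$cds$start, x$cds$end,
                x$cds$strand, x$cds$frame))
  cat("\n")
  show <- if (nchar(x$seq) > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat("  ", show, "\n", sep = "")
  invisible(x)
}

as_locus <- function(x, name = "locus") {
  if (inherits(x, "locus")) x else locus(x, name = name)
}

#' Specify a substitution edit
#'
#' An edit replaces `ref` by `alt` (equal length, substitutions only) starting
#' at a 1-based position on the locus top strand. `ref` is checked against the
#' locus before any design is attempted.
#'
#' @param position 1-based top-strand coordinate of the first affected base.
#' @param ref expected base(s) at `position`.
#' @param alt replacement base(s); same length as `ref`, different from it.
#' @return an object of class `edit_spec`.
#' @export
edit_spec <- function(position, ref, alt) {
  position <- as.integer(position)
  stopifnot(length(position) == 1L, position >= 1L)
  ref <- toupper(ref); alt <- toupper(alt)
  check_dna(ref, "ref"); check_dna(alt, "alt")
  if (nchar(ref) != nchar(alt))
    stop("ref and alt must have equal length (substitutions only)", call. = FALSE)
  if (identical(ref, alt)) stop("ref and alt are identical", call. = FALSE)
  structure(list(position = position, ref = ref, alt = alt),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit> %d:%s>%s\n", x$position, x$ref, x$alt))
  invisible(x)
}

#' Parse a paper-style edit label
#'
#' Accepts `"POS:REF>ALT"` with POS 1-based, e.g. `"200:A>C"` for the reporter
#' A200C correction.
#'
#' @param text edit label string.
#' @return an [edit_spec()].
#' @export
parse_edit <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+):([ACGTacgt]+)>([ACGTacgt]+)$", text))[[1L]]
  if (length(m) != 4L)
    stop("edit must look like POS:REF>ALT, e.g. 200:A>C", call. = FALSE)
  edit_spec(as.integer(m[2L]), m[3L], m[4L])
}

as_edit_list <- function(edits) {
  if (is.null(edits)) return(list())
  if (inherits(edits, "edit_spec")) return(list(edits))
  stopifnot(is.list(edits), all(vapply(edits, inherits, TRUE, "edit_spec")))
  edits
}

#' Apply substitution edits to a locus
#'
#' Checks every edit's `ref` against the sequence (a mismatch is an error
#' naming the offending position), rejects overlapping edits, and returns the
#' edited top-strand sequence. The locus itself is never modified.
#'
#' @param x a [locus()] or plain DNA string.
#' @param edits an [edit_spec()] or list of them; an empty list is the identity.
#' @return the edited sequence as a single string.
#' @export
apply_edits <- function(x, edits) {
  seq <- if (inherits(x, "locus")) x$seq else check_dna(toupper(x), "seq")
  edits <- as_edit_list(edits)
  if (!length(edits)) return(seq)
  covered <- integer(0)
  for (e in edits) {
    span <- e$position:(e$position + nchar(e$ref) - 1L)
    if (max(span) > nchar(seq))
      stop("edit at position ", e$position, " extends beyond the sequence",
           call. = FALSE)
    if (any(span %in% covered))
      stop("overlapping edits at position ", e$position, call. = FALSE)
    covered <- c(covered, span)
    have <- substr(seq, e$position, e$position + nchar(e$ref) - 1L)
    if (!identical(have, e$ref))
      stop("reference mismatch at position ", e$position, ": expected ",
           e$ref, ", locus has ", have, call. = FALSE)
    substr(seq, e$position, e$position + nchar(e$ref) - 1L) <- e$alt
  }
  seq
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped lines, multi-record).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector or list of DNA strings.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}
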