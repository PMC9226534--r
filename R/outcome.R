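# Amplicon-read classification and the editing-efficiency statistic:
# reads are globally aligned to the WT and expected-edit references and
# labelled edited / wt / indel / discarded inside a window around the nick, so
# sequencing errors far from the cut do not miscall classes. Efficiency is the
# percentage of edited reads over total retained reads.

#' Optimal global alignment of two DNA strings
#'
#' Needleman-Wunsch alignment under a linear gap scheme (defaults: match +1,
#' mismatch -1, gap -2) with a deterministic traceback that prefers a
#' diagonal move, then a gap in `b`, then a gap in `a` when scores tie.
#'
#' @param a,b non-empty DNA strings.
#' @param match,mismatch,gap alignment scores.
#' @return list of class `global_alignment` with aligned strings `a`, `b`
#'   (gaps as `-`) and the `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  check_dna(a, "a"); check_dna(b, "b")
  res <- nw_align_cpp(a, b, match, mismatch, gap)
  structure(list(a = res$a, b = res$b, score = res$score),
            class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat("<global_alignment> score ", x$score, "\n  ", x$a, "\n  ", x$b, "\n",
      sep = "")
  invisible(x)
}

#' Classification references for amplicon reads
#'
#' Holds the WT amplicon, the expected edited amplicon (same length;
#' substitution designs only), and the classification window around the nick.
#'
#' @param wt,edited equal-length DNA strings, `wt != edited`.
#' @param nick boundary coordinate of the non-target-strand nick on the
#'   amplicon (bases 5' of the nick); used to centre the default window.
#' @param window explicit `c(start, end)` 1-based window; overrides `nick`.
#' @param flank half-width of the default window around the nick (bp).
#' @return an object of class `amplicon_refs`.
#' @export
amplicon_refs <- function(wt, edited, nick = NULL, window = NULL,
                          flank = 20L) {
  check_dna(wt, "wt"); check_dna(edited, "edited")
  if (identical(wt, edited)) stop("wt and edited references are identical",
                                  call. = FALSE)
  if (nchar(wt) != nchar(edited))
    stop("wt and edited references must have equal length ",
         "(substitution designs only)", call. = FALSE)
  if (is.null(window)) {
    if (is.null(nick))
      stop("provide either a nick coordinate or an explicit window",
           call. = FALSE)
    window <- c(max(1L, as.integer(nick) - as.integer(flank) + 1L),
                min(nchar(wt), as.integer(nick) + as.integer(flank)))
  }
  window <- as.integer(window)
  if (window[1L] < 1L || window[2L] > nchar(wt) || window[2L] < window[1L])
    stop("window outside the references", call. = FALSE)
  structure(list(wt = wt, edited = edited, window = window),
            class = "amplicon_refs")
}

# Per-alignment window diagnostics for a (reference, read) alignment.
# Reference-gap columns are assigned the coordinate of the preceding
# reference base so insertions at the window edge still count as in-window.
aln_stats <- function(ref_aln, read_aln, window) {
  rc <- strsplit(ref_aln, "", fixed = TRUE)[[1L]]
  qc <- strsplit(read_aln, "", fixed = TRUE)[[1L]]
  refpos <- cumsum(rc != "-")  # ref-gap columns inherit the previous base
  inw <- refpos >= window[1L] & refpos <= window[2L]
  gaps <- rc == "-" | qc == "-"
  mm <- !gaps & rc != qc
  out <- !inw
  out_cols <- sum(out)
  out_ident <- if (out_cols == 0L) 1 else sum(out & !gaps & rc == qc) / out_cols
  list(gap_in_window = any(gaps & inw),
       mismatch_in_window = any(mm & inw),
       outside_identity = out_ident)
}

#' Classify one amplicon read
#'
#' A read is `"edited"` when its global alignment to the edited reference has
#' no gap and no mismatch inside the window and passes the outside-window
#' identity floor; `"wt"` analogously against the WT reference; `"indel"` when
#' its best-scoring alignment carries a gap inside the window; otherwise
#' `"discarded"` (too short, below the identity floor, or matching neither
#' reference cleanly).
#'
#' @param read DNA string.
#' @param refs an [amplicon_refs()].
#' @param min_len minimum read length retained.
#' @param identity_floor minimum outside-window identity.
#' @param match,mismatch,gap alignment scores passed to [align_global()].
#' @return one of `"edited"`, `"wt"`, `"indel"`, `"discarded"`.
#' @export
classify_read <- function(read, refs, min_len = 50L, identity_floor = 0.8,
                          match = 1, mismatch = -1, gap = -2) {
  stopifnot(inherits(refs, "amplicon_refs"))
  if (!is.character(read) || length(read) != 1L || nchar(read) < min_len ||
      !grepl("^[ACGTN]*$", read))
    return("discarded")
  aln_e <- align_global(refs$edited, read, match, mismatch, gap)
  aln_w <- align_global(refs$wt, read, match, mismatch, gap)
  st_e <- aln_stats(aln_e$a, aln_e$b, refs$window)
  st_w <- aln_stats(aln_w$a, aln_w$b, refs$window)
  if (!st_e$gap_in_window && !st_e$mismatch_in_window &&
      st_e$outside_identity >= identity_floor) return("edited")
  if (!st_w$gap_in_window && !st_w$mismatch_in_window &&
      st_w$outside_identity >= identity_floor) return("wt")
  best <- if (aln_w$score >= aln_e$score) st_w else st_e
  if (best$outside_identity < identity_floor) return("discarded")
  if (best$gap_in_window) return("indel")
  "discarded"
}

#' Editing efficiency from class counts
#'
#' The efficiency statistic: the percentage of edited reads over total
#' retained reads, `100 * edited / (total - discarded)`.
#'
#' @param counts named numeric vector with entries `edited`, `wt`, `indel`,
#'   `discarded` (missing entries count as 0).
#' @return efficiency in percent, within \[0, 100].
#' @export
editing_efficiency <- function(counts) {
  full <- c(edited = 0, wt = 0, indel = 0, discarded = 0)
  full[names(counts)] <- counts
  if (any(full < 0)) stop("negative class count", call. = FALSE)
  denom <- sum(full) - full[["discarded"]]
  if (denom <= 0)
    stop("no retained reads: total minus discarded is zero", call. = FALSE)
  100 * full[["edited"]] / denom
}

#' Quantify editing outcomes in a set of amplicon reads
#'
#' Classifies every read with [classify_read()] and reports per-class counts
#' together with the editing efficiency (percentage of edited reads over
#' retained reads).
#'
#' @param reads character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTQ file (plain or gzip).
#' @param refs an [amplicon_refs()].
#' @param ... passed to [classify_read()].
#' @return an object of class `amplicon_report` with `counts`, `total`,
#'   `efficiency_percent`, and the per-read `classes`.
#' @export
quantify_amplicons <- function(reads, refs, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads), length(reads) > 0L)
  cls <- vapply(toupper(reads), classify_read, "", refs = refs, ...,
                USE.NAMES = FALSE)
  counts <- vapply(c("edited", "wt", "indel", "discarded"),
                   function(k) sum(cls == k), 0L)
  structure(list(counts = counts, total = length(cls),
                 efficiency_percent = editing_efficiency(counts),
                 classes = cls, window = refs$window),
            class = "amplicon_report")
}

#' @export
print.amplicon_report <- function(x, ...) {
  cat("<amplicon_report> ", x$total, " reads; window [",
      x$window[1L], ", ", x$window[2L], "]\n", sep = "")
  cat(sprintf("  edited %d  wt %d  indel %d  discarded %d\n",
              x$counts[["edited"]], x$counts[["wt"]], x$counts[["indel"]],
              x$counts[["discarded"]]))
  cat(sprintf("  editing efficiency: %.2f%% of retained reads\n",
              x$efficiency_percent))
  invisible(x)
}
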