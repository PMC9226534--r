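# Deterministic generators for test loci (with planted TTTV PAMs and marked
# mutations) and simulated amplicon read sets, so every module is exercisable
# without external data. Fully reproducible under a fixed seed; sequencing
# error is substitution-only so the indel class stays identifiable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, weights = c(A = 1, C = 1, G = 1, T = 1) / 4) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}

#' Specification of a synthetic locus
#'
#' Describes a reproducible locus with planted AsCas12a PAM + protospacer
#' features and optionally a marked point mutation at a chosen protospacer
#' base (emulating a pathogenic SNV a known distance from the cut).
#'
#' @param length locus length in nt.
#' @param pams list of `list(pos, strand)` entries: plant a `TTTC` PAM whose
#'   first base sits at top-strand position `pos` (site-frame position for
#'   `-` strand plants is mirrored automatically).
#' @param snv optional `list(pam = 1, proto_base = 14)`: mark the protospacer
#'   base at that index (of the given planted PAM) as a mutant position; the
#'   manifest then records the corrective edit.
#' @param seed RNG seed; identical specs give bit-identical loci.
#' @param background base-composition weights for the random background.
#' @param name locus name.
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(length = 60L, pams = list(list(pos = 11L, strand = "+")),
                       snv = NULL, seed = 1L,
                       background = c(A = 1, C = 1, G = 1, T = 1) / 4,
                       name = "synthetic_locus") {
  length <- as.integer(length)
  stopifnot(length > 0L, is.list(pams), length(pams) >= 1L)
  pams <- lapply(pams, function(p) {
    p$pos <- as.integer(p$pos)
    p$strand <- if (is.null(p$strand)) "+" else match.arg(p$strand, c("+", "-"))
    p
  })
  if (!is.null(snv)) {
    snv$pam <- if (is.null(snv$pam)) 1L else as.integer(snv$pam)
    snv$proto_base <- as.integer(snv$proto_base)
    stopifnot(snv$pam %in% seq_along(pams), snv$proto_base >= 1L)
  }
  structure(list(length = length, pams = pams, snv = snv,
                 seed = as.integer(seed), background = background,
                 name = name),
            class = "locus_spec")
}

#' Generate a synthetic locus with planted features
#'
#' Draws a random background, plants each requested `TTTC` PAM (with a random
#' 23-nt protospacer after it in the site frame), then deterministically
#' breaks any unintended TTTV match on either strand so [find_sites()] returns
#' exactly the planted sites. The returned manifest records every planted
#' coordinate as ground truth; when an SNV is specified the manifest also
#' carries the corrective [edit_spec()].
#'
#' @param spec a [locus_spec()].
#' @return list of class `synthetic_locus` with elements `locus`, `manifest`
#'   (data.frame of planted features, top-strand coordinates) and `edit`
#'   (corrective edit or `NULL`).
#' @export
make_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  profile <- cas12a_profile()
  plen <- profile$protospacer_len
  with_seed(spec$seed, {
    chars <- strsplit(random_dna(spec$length, spec$background), "",
                      fixed = TRUE)[[1L]]
    protected <- integer(0)
    manifest <- list()
    for (i in seq_along(spec$pams)) {
      p <- spec$pams[[i]]
      pam_iv <- c(p$pos, p$pos + 3L)
      proto_iv <- if (p$strand == "+") c(p$pos + 4L, p$pos + 3L + plen)
                  else c(p$pos - plen, p$pos - 1L)
      if (pam_iv[1L] < 1L || pam_iv[2L] > spec$length ||
          proto_iv[1L] < 1L || proto_iv[2L] > spec$length)
        stop("planted PAM ", i, " leaves no room for its protospacer",
             call. = FALSE)
      pam_chars <- strsplit(if (p$strand == "+") "TTTC" else revcomp("TTTC"),
                            "", fixed = TRUE)[[1L]]
      chars[pam_iv[1L]:pam_iv[2L]] <- pam_chars
      protected <- c(protected, pam_iv[1L]:pam_iv[2L])
      manifest[[length(manifest) + 1L]] <- data.frame(
        feature = sprintf("pam%d", i), start = pam_iv[1L], end = pam_iv[2L],
        strand = p$strand, note = "TTTC", stringsAsFactors = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        feature = sprintf("protospacer%d", i), start = proto_iv[1L],
        end = proto_iv[2L], strand = p$strand, note = "",
        stringsAsFactors = FALSE)
    }
    snv_pos <- NA_integer_; snv_alt <- NA_character_
    if (!is.null(spec$snv)) {
      p <- spec$pams[[spec$snv$pam]]
      if (spec$snv$proto_base > plen)
        stop("snv proto_base beyond the protospacer", call. = FALSE)
      snv_pos <- if (p$strand == "+") p$pos + 3L + spec$snv$proto_base
                 else p$pos - spec$snv$proto_base
      protected <- c(protected, snv_pos)
      snv_alt <- next_base(chars[snv_pos])  # the corrective base
      manifest[[length(manifest) + 1L]] <- data.frame(
        feature = "snv", start = snv_pos, end = snv_pos,
        strand = p$strand,
        note = sprintf("corrective edit %d:%s>%s", snv_pos, chars[snv_pos],
                       snv_alt),
        stringsAsFactors = FALSE)
    }
    planted_pams <- do.call(rbind, manifest)
    planted_pams <- planted_pams[grepl("^pam", planted_pams$feature), ,
                                 drop = FALSE]
    is_planted <- function(st, strand) {
      any(planted_pams$start == st & planted_pams$strand == strand)
    }
    for (try in 1:100) {
      seq_now <- paste(chars, collapse = "")
      stray <- list()
      for (strand in c("+", "-")) {
        sf <- if (strand == "+") seq_now else revcomp(seq_now)
        for (st_sf in iupac_find("TTTV", sf)) {
          st_top <- if (strand == "+") st_sf else spec$length - 2L - st_sf
          if (!is_planted(st_top, strand))
            stray[[length(stray) + 1L]] <- list(start = st_top, strand = strand)
        }
      }
      if (!length(stray)) break
      fixed_any <- FALSE
      for (s in stray) {
        # break the stray by turning one of its three T bases into a C (in
        # the stray's own frame): removes a T, so the loop must terminate
        t_top <- if (s$strand == "+") s$start + 0:2 else s$start + 1:3
        free <- setdiff(t_top, protected)
        if (!length(free)) next
        chars[free[1L]] <- if (s$strand == "+") "C" else "G"
        fixed_any <- TRUE
      }
      if (!fixed_any)
        stop("infeasible locus spec: an unintended PAM overlaps only ",
             "protected bases", call. = FALSE)
    }
    loc <- locus(paste(chars, collapse = ""), name = spec$name)
    found <- find_sites(loc, profile)
    want <- nrow(planted_pams)
    if (length(found) != want)
      stop("could not realise the spec: ", length(found),
           " site(s) found, ", want, " planted", call. = FALSE)
    structure(list(
      locus = loc, manifest = do.call(rbind, manifest),
      edit = if (!is.na(snv_pos))
        edit_spec(snv_pos, substr(loc$seq, snv_pos, snv_pos), snv_alt)
      else NULL,
      spec = spec
    ), class = "synthetic_locus")
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic_locus> seed ", x$spec$seed, "\n", sep = "")
  print(x$locus)
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Specification of a simulated amplicon read set
#'
#' @param refs an [amplicon_refs()] giving the WT and edited amplicons and the
#'   classification window.
#' @param fractions named non-negative class proportions over
#'   `edited` / `wt` / `indel`, summing to 1 (tolerance 1e-9).
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution-error probability, in \[0, 0.1].
#' @param read_len read length (5' prefix of the amplicon); default full
#'   amplicon length.
#' @param indel_len deletion length carried by `indel`-class reads, centred in
#'   the classification window.
#' @param seed RNG seed.
#' @return an object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(refs, fractions = c(edited = 0.25, wt = 0.75),
                          n_reads = 1000L, error_rate = 0.001,
                          read_len = NULL, indel_len = 3L, seed = 1L) {
  stopifnot(inherits(refs, "amplicon_refs"))
  full <- c(edited = 0, wt = 0, indel = 0)
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% names(full)))
    stop("fractions must be named over edited/wt/indel", call. = FALSE)
  full[names(fractions)] <- fractions
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  n_reads <- as.integer(n_reads)
  stopifnot(n_reads >= 1L)
  structure(list(refs = refs, fractions = full, n_reads = n_reads,
                 error_rate = error_rate,
                 read_len = if (is.null(read_len)) NULL else as.integer(read_len),
                 indel_len = as.integer(indel_len), seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate an amplicon read set
#'
#' Draws class counts from a multinomial over the specified mixture, emits
#' each read from its class template (WT amplicon, edited amplicon, or WT with
#' a deletion centred in the classification window), applies independent
#' per-base substitution errors, and shuffles read order. The class of origin
#' is recorded in each read name (`read00001|edited`) for truth-aware tests.
#' Output is bit-identical for identical specs.
#'
#' @param spec a [read_sim_spec()].
#' @return named character vector of reads (class `simulated_reads`) with a
#'   `truth` attribute (data.frame of read id and true class).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  refs <- spec$refs
  w <- refs$window
  center <- (w[1L] + w[2L]) %/% 2L
  del_start <- max(1L, center - spec$indel_len %/% 2L)
  indel_ref <- paste0(substr(refs$wt, 1L, del_start - 1L),
                      substr(refs$wt, del_start + spec$indel_len,
                             nchar(refs$wt)))
  templates <- c(edited = refs$edited, wt = refs$wt, indel = indel_ref)
  with_seed(spec$seed, {
    counts <- as.vector(rmultinom(1L, spec$n_reads, spec$fractions))
    names(counts) <- names(spec$fractions)
    classes <- rep(names(counts), counts)
    reads <- unname(templates[classes])
    if (!is.null(spec$read_len)) reads <- substr(reads, 1L, spec$read_len)
    if (spec$error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      for (i in seq_along(reads)) {
        n <- nchar(reads[i])
        nerr <- rbinom(1L, n, spec$error_rate)
        if (nerr > 0L) {
          pos <- sample.int(n, nerr)
          for (p in pos) {
            cur <- substr(reads[i], p, p)
            substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
          }
        }
      }
    }
    ord <- sample.int(length(reads))
    reads <- reads[ord]; classes <- classes[ord]
    ids <- sprintf("read%05d|%s", seq_along(reads), classes)
    names(reads) <- ids
    structure(reads,
              truth = data.frame(id = ids, class = classes,
                                 stringsAsFactors = FALSE),
              spec = spec, class = c("simulated_reads", "character"))
  })
}

#' Write simulated reads to a FASTQ file
#'
#' Constant Phred-40 qualities (`"I"`): the simulator's error model is
#' quality-independent by design.
#'
#' @param reads named character vector (e.g. from [simulate_reads()]).
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(unname(unclass(reads))),
    Biostrings::PhredQuality(strrep("I", nchar(reads))))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
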