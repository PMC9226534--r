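# LAHR template / CAPR insert / ssODN construction, silent PAM/seed
# disruption, heuristic scoring and ranking, and oligo output.
#
# A LAHR template pairs a single homology arm on the PAM-proximal side of the
# cut with a 5' sticky end complementary to the PAM-distal fragment's
# overhang. The arm is always PAM-proximal and the sticky end always targets
# the PAM-distal fragment; no mirrored variant is offered.

#' Design parameters
#'
#' Defaults encode the experimentally determined optima: an 80-bp homology arm
#' (arm-length series 20-200 bp), the 19th-base non-target nick whose 4-nt
#' overhang perfectly matches the PAM-distal sticky end, a favourable
#' mutation-to-nick distance window of 0-20 bp, and a 120-bp total-template
#' length warning threshold (templates over 120 bp showed decreased repair).
#'
#' @param arm_len homology-arm length in bp, within \[20, 200].
#' @param nick_choice non-target-strand nick option, 18 or 19.
#' @param end_type sticky-end variant: `"matched"` (5' overhang complementary
#'   to the genomic overhang; default), `"5nt"` / `"3nt"` (fixed-length 5'
#'   overhangs), `"mismatched"` (matched length with one substituted base),
#'   `"blunt"`, or `"3prime"` (overhang moved to the top strand's 3' end;
#'   approximate mirror construction).
#' @param distance_window allowed signed mutation-to-nick distance, bp.
#' @param total_len_warn total template length (longest strand) above which a
#'   warning is attached and the length score decays.
#' @param disruption_mode `"none"`, `"pam"` or `"seed"`: which re-cut-avoiding
#'   silent disruption to plant. Disrupting both at once is intentionally
#'   unrepresentable — the efficiency benefit is lost when PAM and seed are
#'   disrupted together.
#' @param extra_edit_positions optional list of [edit_spec()] silent mutations
#'   to carry in the arm in addition to the correction.
#' @param allow_overhang_edit permit edits inside the overhang interval
#'   (mismatched overhangs reduce efficiency; off by default).
#' @return an object of class `design_params`.
#' @export
design_params <- function(arm_len = 80L, nick_choice = 19L,
                          end_type = c("matched", "5nt", "3nt", "mismatched",
                                       "blunt", "3prime"),
                          distance_window = c(0L, 20L), total_len_warn = 120L,
                          disruption_mode = c("none", "pam", "seed"),
                          extra_edit_positions = NULL,
                          allow_overhang_edit = FALSE) {
  arm_len <- as.integer(arm_len)
  if (arm_len < 20L || arm_len > 200L)
    stop("arm_len must lie within [20, 200] bp", call. = FALSE)
  nick_choice <- as.integer(nick_choice)
  end_type <- match.arg(end_type)
  disruption_mode <- match.arg(disruption_mode)
  distance_window <- as.integer(distance_window)
  if (length(distance_window) != 2L || distance_window[1L] < 0L ||
      distance_window[2L] < distance_window[1L])
    stop("distance_window must be c(lower, upper) with 0 <= lower <= upper",
         call. = FALSE)
  structure(list(arm_len = arm_len, nick_choice = nick_choice,
                 end_type = end_type, distance_window = distance_window,
                 total_len_warn = as.integer(total_len_warn),
                 disruption_mode = disruption_mode,
                 extra_edit_positions = as_edit_list(extra_edit_positions),
                 allow_overhang_edit = isTRUE(allow_overhang_edit)),
            class = "design_params")
}

next_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

# site-frame sequence of a locus for a given site strand
sf_seq_of <- function(seq, strand) if (strand == "+") seq else revcomp(seq)

# map a site-frame interval (1-based inclusive) to top-strand coordinates
sf_interval_to_top <- function(iv, strand, L) {
  if (strand == "+") iv else c(L + 1L - iv[2L], L + 1L - iv[1L])
}

edit_span <- function(e) e$position:(e$position + nchar(e$ref) - 1L)

in_interval <- function(pos, iv) all(pos >= iv[1L] & pos <= iv[2L])

#' Build a LAHR repair template
#'
#' Constructs the double-stranded template: a top strand equal to the edited
#' locus over the PAM-proximal arm interval, and a bottom strand equal to the
#' reverse complement of the edited locus over arm-plus-overhang, which places
#' the 5' sticky end at the bottom strand's 5' terminus. That sticky end is the
#' reverse complement of the genomic overhang between the two nicks, hence
#' complementary to the PAM-distal fragment's 5' overhang.
#'
#' @param x a [locus()] or DNA string.
#' @param cut a [staggered_cut()] geometry (AsCas12a).
#' @param edit the correction [edit_spec()], a list of edits, or `NULL` for a
#'   no-edit template.
#' @param params a [design_params()]; `arm_len` and `end_type` are used here.
#' @return an object of class `lahr_template`.
#' @export
build_lahr_template <- function(x, cut, edit = NULL,
                                params = design_params()) {
  loc <- as_locus(x)
  stopifnot(inherits(cut, "cut_geometry"), inherits(params, "design_params"))
  if (cut$overhang_len <= 0L && params$end_type == "matched")
    stop("matched-end LAHR template requires a staggered (Cas12a) cut",
         call. = FALSE)
  edits <- as_edit_list(edit)
  L <- cut$site$locus_len
  strand <- cut$site$strand
  b_nt <- cut$nick_nontarget_sf
  b_t <- cut$nick_target_sf
  arm_sf <- c(b_nt - params$arm_len + 1L, b_nt)
  if (arm_sf[1L] < 1L)
    stop("arm (", params$arm_len, " bp) extends beyond the locus 5' end ",
         "in the site frame", call. = FALSE)
  arm_top <- sf_interval_to_top(arm_sf, strand, L)
  overhang_top <- if (b_t > b_nt) {
    sf_interval_to_top(c(b_nt + 1L, b_t), strand, L)
  } else NULL
  for (e in edits) {
    sp <- edit_span(e)
    if (!is.null(overhang_top) && any(sp >= overhang_top[1L] & sp <= overhang_top[2L])) {
      if (!params$allow_overhang_edit)
        stop("edit at position ", e$position, " falls inside the 5' overhang; ",
             "mismatched overhangs reduce repair efficiency ",
             "(set allow_overhang_edit = TRUE to override)", call. = FALSE)
    } else if (!in_interval(sp, arm_top)) {
      stop("edit at position ", e$position, " lies outside the homology arm [",
           arm_top[1L], ", ", arm_top[2L], "]", call. = FALSE)
    }
  }
  es <- sf_seq_of(apply_edits(loc, edits), strand)
  top <- substr(es, arm_sf[1L], arm_sf[2L])
  ov_end <- switch(params$end_type,
    matched = b_t, "5nt" = b_nt + 5L, "3nt" = b_nt + 3L,
    mismatched = b_t, blunt = b_nt, "3prime" = b_nt)
  if (ov_end > nchar(es))
    stop("overhang extends beyond the locus 3' end in the site frame",
         call. = FALSE)
  ov_region <- if (ov_end > b_nt) substr(es, b_nt + 1L, ov_end) else ""
  if (params$end_type == "mismatched" && nzchar(ov_region)) {
    p <- as.integer(ceiling(nchar(ov_region) / 2))
    substr(ov_region, p, p) <- next_base(substr(ov_region, p, p))
  }
  if (params$end_type == "3prime") {
    # overhang moved to the top strand's 3' end (mirror-image construction)
    top <- substr(es, arm_sf[1L], b_t)
    bottom <- revcomp(substr(es, arm_sf[1L], b_nt))
    overhang_seq <- ""
  } else {
    bottom <- revcomp(paste0(substr(es, arm_sf[1L], b_nt), ov_region))
    overhang_seq <- revcomp(ov_region)
  }
  structure(list(
    top_strand = top, bottom_strand = bottom, overhang_seq = overhang_seq,
    arm_len = params$arm_len, end_type = params$end_type,
    arm_interval = arm_top, arm_interval_sf = arm_sf,
    edits_carried = edits, source_cut = cut
  ), class = "lahr_template")
}

#' @export
print.lahr_template <- function(x, ...) {
  cat(sprintf("<lahr_template> arm %d bp, end type %s, %d edit(s) carried\n",
              x$arm_len, x$end_type, length(x$edits_carried)))
  cat("  top    5'-", x$top_strand, "-3'\n", sep = "")
  cat("  bottom 5'-", x$bottom_strand, "-3'", sep = "")
  if (nzchar(x$overhang_seq))
    cat("  (5' overhang ", x$overhang_seq, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate a perfect LAHR repair outcome
#'
#' The design-correctness oracle: ligates the template's sticky end to the
#' PAM-distal genomic fragment and resolves the homology arm against the
#' PAM-proximal fragment, returning the repaired top-strand sequence. For a
#' well-formed template this equals `apply_edits(locus, edits_carried)`.
#' In strict mode the template's 5' overhang must be exactly the reverse
#' complement of the genomic overhang between the nicks; blunt, truncated,
#' mismatched or 3'-overhang ends raise a ligation-incompatible error.
#'
#' @param x the [locus()] the template was designed against.
#' @param cut the [staggered_cut()] used for the design.
#' @param template a [build_lahr_template()] result.
#' @param strict enforce exact overhang complementarity (default `TRUE`).
#' @return the repaired top-strand sequence.
#' @export
simulate_perfect_lahr <- function(x, cut, template, strict = TRUE) {
  loc <- as_locus(x)
  stopifnot(inherits(cut, "cut_geometry"), inherits(template, "lahr_template"))
  L <- cut$site$locus_len
  strand <- cut$site$strand
  wt_sf <- sf_seq_of(loc$seq, strand)
  genomic_ov <- substr(wt_sf, cut$nick_nontarget_sf + 1L, cut$nick_target_sf)
  if (strict && !identical(template$overhang_seq, revcomp(genomic_ov)))
    stop("ligation-incompatible: template 5' overhang ",
         if (nzchar(template$overhang_seq)) template$overhang_seq else "(none)",
         " does not complement the genomic overhang ", genomic_ov,
         call. = FALSE)
  a <- template$arm_interval_sf
  repaired_sf <- paste0(substr(wt_sf, 1L, a[1L] - 1L), template$top_strand,
                        substr(wt_sf, cut$nick_nontarget_sf + 1L, nchar(wt_sf)))
  if (strand == "+") repaired_sf else revcomp(repaired_sf)
}

#' Design an ssODN repair template
#'
#' Single-stranded donor spanning `arms[1]` bases 5' of the non-target-strand
#' nick through `arms[2]` bases 3' of it (in the site frame), with the edit
#' applied, so total length is always `sum(arms)`: two 80-bp arms give the
#' 160-nt donor and two 50-bp arms the 100-nt donor. Emitted on the non-target
#' strand for AsCas12a sites and on the target strand for SpCas9 sites,
#' following the observed strand preferences.
#'
#' @param x a [locus()] or DNA string.
#' @param edit the correction [edit_spec()].
#' @param cut a [staggered_cut()] geometry.
#' @param arms `c(left, right)` arm lengths in bases, measured from the nick.
#' @return an object of class `ssodn_template`.
#' @export
design_ssodn <- function(x, edit, cut, arms = c(80L, 80L)) {
  loc <- as_locus(x)
  stopifnot(inherits(cut, "cut_geometry"))
  arms <- as.integer(arms)
  stopifnot(length(arms) == 2L, all(arms >= 1L))
  L <- cut$site$locus_len
  strand <- cut$site$strand
  b <- cut$nick_nontarget_sf
  span <- c(b - arms[1L] + 1L, b + arms[2L])
  if (span[1L] < 1L || span[2L] > L)
    stop("ssODN arms extend beyond the locus", call. = FALSE)
  edits <- as_edit_list(edit)
  span_top <- sf_interval_to_top(span, strand, L)
  for (e in edits)
    if (!in_interval(edit_span(e), span_top))
      stop("edit at position ", e$position,
           " lies outside the ssODN span", call. = FALSE)
  es <- sf_seq_of(apply_edits(loc, edits), strand)
  core <- substr(es, span[1L], span[2L])
  is_cas12a <- cut$site$profile$pam_side == "5prime"
  structure(list(
    seq = if (is_cas12a) core else revcomp(core),
    strand_used = if (is_cas12a) "non-target" else "target",
    arms = arms, nuclease = cut$site$profile$name,
    span_interval = span_top, edits_carried = edits
  ), class = "ssodn_template")
}

#' @export
print.ssodn_template <- function(x, ...) {
  cat(sprintf("<ssodn_template> %s, %s strand, arms %d+%d = %d nt\n",
              x$nuclease, x$strand_used, x$arms[1L], x$arms[2L], nchar(x$seq)))
  cat("  5'-", x$seq, "-3'\n", sep = "")
  invisible(x)
}

#' Codon-preserving PAM or seed disruption candidates
#'
#' Enumerates single-base synonymous substitutions that either break the TTTV
#' PAM match (`mode = "pam"`) or alter a seed-region base (`mode = "seed"`,
#' seed = PAM-proximal protospacer bases per the profile). Planting one such
#' change on the template prevents re-cutting of the repaired allele.
#' Requesting both modes at once is refused: disrupting PAM and seed together
#' loses the efficiency benefit. Without a CDS annotation covering the region
#' the operation refuses unless `allow_noncoding = TRUE`, in which case all
#' region-breaking single-base substitutions are returned without the
#' codon-preservation constraint.
#'
#' @param x a [locus()] (with CDS annotation unless `allow_noncoding`).
#' @param site a `target_site` from [find_sites()].
#' @param mode `"pam"` or `"seed"` (passing `"both"` is an error).
#' @param allow_noncoding lift the CDS requirement for non-coding targets.
#' @return list of single-base [edit_spec()] objects (top-strand coordinates),
#'   ordered by position then alternative base; possibly empty.
#' @export
silent_disruption_candidates <- function(x, site, mode = c("pam", "seed"),
                                         allow_noncoding = FALSE) {
  loc <- as_locus(x)
  stopifnot(inherits(site, "target_site"))
  if (length(mode) == 1L && mode %in% c("both", "pam+seed"))
    stop("disrupting both PAM and seed is refused: the efficiency benefit ",
         "is lost when both are disrupted together", call. = FALSE)
  mode <- match.arg(mode)
  L <- site$locus_len
  region <- if (mode == "pam") {
    site$pam_interval[1L]:site$pam_interval[2L]
  } else {
    seed_sf <- site$protospacer_interval_sf[1L] - 1L + site$profile$seed_region
    sort(vapply(seed_sf, sf_base_to_top, 1L, strand = site$strand, L = L))
  }
  if (!length(region)) return(list())
  cds <- loc$cds
  cand <- list()
  if (is.null(cds) || !all(region >= cds$start & region <= cds$end)) {
    if (!allow_noncoding)
      stop("the ", mode, " region is not covered by a CDS annotation; ",
           "silent disruption needs codon context ",
           "(set allow_noncoding = TRUE for non-coding targets)",
           call. = FALSE)
    for (p in region)
      for (b in setdiff(c("A", "C", "G", "T"), substr(loc$seq, p, p)))
        cand[[length(cand) + 1L]] <- edit_spec(p, substr(loc$seq, p, p), b)
  } else {
    for (p in region) {
      cc <- codon_context(loc, p)
      if (is.null(cc)) next
      syn <- synonymous_substitutions(cc$codon)
      if (!nrow(syn)) next
      hit <- syn[syn$offset == cc$offset, , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        alt_top <- if (cds$strand == "+") hit$alt[k] else revcomp(hit$alt[k])
        cand[[length(cand) + 1L]] <-
          edit_spec(p, substr(loc$seq, p, p), alt_top)
      }
    }
  }
  if (mode == "pam" && length(cand)) {
    keep <- vapply(cand, function(e) {
      new_sf <- sf_seq_of(apply_edits(loc, list(e)), site$strand)
      pam_now <- substr(new_sf, site$pam_interval_sf[1L],
                        site$pam_interval_sf[2L])
      !matches_iupac(pam_now, site$profile$pam)
    }, TRUE)
    cand <- cand[keep]
  }
  if (!length(cand)) return(list())
  key <- vapply(cand, function(e) sprintf("%09d%s", e$position, e$alt), "")
  cand[order(key)][!duplicated(sort(key))]
}

# codon containing top-strand position p under the locus CDS; NULL when p
# falls in a partial leading frame.
codon_context <- function(loc, p) {
  cds <- loc$cds
  if (cds$strand == "+") {
    idx <- p - (cds$start + cds$frame)
    if (idx < 0L) return(NULL)
    cs <- cds$start + cds$frame + 3L * (idx %/% 3L)
    if (cs + 2L > cds$end) return(NULL)
    list(codon = substr(loc$seq, cs, cs + 2L), offset = idx %% 3L + 1L)
  } else {
    idx <- (cds$end - cds$frame) - p
    if (idx < 0L) return(NULL)
    ce <- cds$end - cds$frame - 3L * (idx %/% 3L)
    if (ce - 2L < cds$start) return(NULL)
    list(codon = revcomp(substr(loc$seq, ce - 2L, ce)),
         offset = idx %% 3L + 1L)
  }
}

matches_iupac <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  all(mapply(function(b, code) b %in% IUPAC_CODES[[code]], s, p))
}

# Heuristic score: product of [0,1] components. Functional forms are the
# package's own; only their directions are empirically grounded (arm optimum
# at 80 bp; 0-20 bp favourable distance; decay beyond 120 bp total length;
# silent-mutation incorporation falls toward the blunt/arm end; a single
# PAM-or-seed disruption avoids re-cutting).
score_components <- function(distance, arm_len, total_len, extra_fracs,
                             n_disruptions, params) {
  w <- params$distance_window
  dist_comp <- if (distance >= w[1L] && distance <= w[2L]) 1 else {
    over <- if (distance > w[2L]) distance - w[2L] else w[1L] - distance
    max(0, 1 - over / max(w[2L], 1L))
  }
  arm_comp <- max(0, 1 - abs(arm_len - 80) / 180)
  warn_at <- params$total_len_warn
  len_comp <- if (total_len <= warn_at) 1 else
    max(0, 1 - (total_len - warn_at) / warn_at)
  mid_comp <- if (length(extra_fracs)) 1 - 0.5 * min(1, max(extra_fracs)) else 1
  recut_comp <- if (n_disruptions == 1L) 1 else 0.6
  c(distance = dist_comp, arm = arm_comp, total_length = len_comp,
    mid_arm = mid_comp, recut = recut_comp)
}

#' Score a design candidate
#'
#' Recomputes the candidate's component scores (each in \[0,1]) and their
#' product. Components: mutation-to-nick distance (flat inside the favourable
#' window, linear taper beyond), arm-length prior (peak at 80 bp), total
#' template length (decay beyond the 120-bp threshold), mid-arm placement of
#' extra silent edits (penalty grows with fractional distance from the nick),
#' and re-cut avoidance (maximal with exactly one PAM-or-seed disruption).
#'
#' @param candidate a `design_candidate` from [enumerate_designs()].
#' @param params a [design_params()].
#' @return the candidate with `score` and `components` refreshed.
#' @export
score_candidate <- function(candidate, params = design_params()) {
  stopifnot(inherits(candidate, "design_candidate"))
  comp <- score_components(candidate$distance, candidate$template$arm_len,
                           max(nchar(candidate$template$top_strand),
                               nchar(candidate$template$bottom_strand)),
                           candidate$extra_fracs, candidate$n_disruptions,
                           params)
  candidate$components <- comp
  candidate$score <- prod(comp)
  candidate
}

#' Enumerate and rank LAHR design candidates for an edit
#'
#' For every AsCas12a site on either strand whose geometry places the edit
#' inside the homology arm and within the favourable distance window, builds a
#' LAHR template (optionally carrying one silent PAM/seed disruption and any
#' requested extra silent edits), scores it, and returns candidates in a
#' deterministic total order: score descending, then top-strand PAM start
#' ascending, then + strand before -.
#'
#' @param x a [locus()] or DNA string.
#' @param edit the correction [edit_spec()].
#' @param params a [design_params()].
#' @param profile nuclease profile (AsCas12a by default; the profile's default
#'   nick is overridden by `params$nick_choice`).
#' @return an object of class `design_report` holding zero or more
#'   `design_candidate` objects plus per-site diagnostics.
#' @export
enumerate_designs <- function(x, edit, params = design_params(),
                              profile = NULL) {
  loc <- as_locus(x)
  stopifnot(inherits(edit, "edit_spec"), inherits(params, "design_params"))
  apply_edits(loc, edit)  # ref check up front
  if (is.null(profile)) profile <- cas12a_profile(nick_nontarget = params$nick_choice)
  sites <- find_sites(loc, profile)
  cands <- list(); diagnostics <- character(0)
  for (i in seq_along(sites)) {
    site <- sites[[i]]
    tag <- sprintf("site %d (%s, PAM at %d)", i, site$strand,
                   site$pam_interval[1L])
    cut <- staggered_cut(site, params$nick_choice)
    d <- mutation_cut_distance(cut, edit)
    w <- params$distance_window
    if (d < w[1L] || d > w[2L]) {
      diagnostics <- c(diagnostics, sprintf(
        "%s: mutation-to-nick distance %d bp outside window [%d, %d]",
        tag, d, w[1L], w[2L]))
      next
    }
    if (d > params$arm_len - 1L) {
      diagnostics <- c(diagnostics,
                       sprintf("%s: edit outside the %d-bp arm", tag,
                               params$arm_len))
      next
    }
    if (cut$nick_nontarget_sf - params$arm_len + 1L < 1L) {
      diagnostics <- c(diagnostics,
                       sprintf("%s: arm would run off the locus", tag))
      next
    }
    warnings <- character(0)
    arm_top <- sf_interval_to_top(c(cut$nick_nontarget_sf - params$arm_len + 1L,
                                    cut$nick_nontarget_sf),
                                  site$strand, site$locus_len)
    extras <- params$extra_edit_positions
    if (length(extras) &&
        !all(vapply(extras, function(e) in_interval(edit_span(e), arm_top), TRUE))) {
      diagnostics <- c(diagnostics,
                       sprintf("%s: extra silent edit outside the arm", tag))
      next
    }
    disruption <- list()
    if (params$disruption_mode != "none") {
      pool <- tryCatch(
        silent_disruption_candidates(loc, site, mode = params$disruption_mode),
        error = function(e) conditionMessage(e))
      if (is.character(pool)) {
        warnings <- c(warnings, paste0("disruption skipped: ", pool))
      } else {
        ov_top <- c(cut$cut_left + 1L, cut$cut_right)
        ok <- Filter(function(e) {
          in_interval(edit_span(e), arm_top) &&
            !any(edit_span(e) %in% edit_span(edit)) &&
            !any(edit_span(e) >= ov_top[1L] & edit_span(e) <= ov_top[2L])
        }, pool)
        if (length(ok)) disruption <- ok[1L]
        else warnings <- c(warnings,
          "disruption requested but no codon-preserving candidate fits the arm")
      }
    }
    all_edits <- c(list(edit), disruption, extras)
    tpl <- tryCatch(build_lahr_template(loc, cut, all_edits, params),
                    error = function(e) conditionMessage(e))
    if (is.character(tpl)) {
      diagnostics <- c(diagnostics, sprintf("%s: %s", tag, tpl))
      next
    }
    total_len <- max(nchar(tpl$top_strand), nchar(tpl$bottom_strand))
    if (total_len > params$total_len_warn)
      warnings <- c(warnings, sprintf(
        "total template length %d bp exceeds %d bp; repair efficiency drops for long templates",
        total_len, params$total_len_warn))
    if (site$pam_interval_sf[1L] <
        cut$nick_nontarget_sf - params$arm_len + 1L)
      warnings <- c(warnings, "arm does not reach the PAM; PAM lies outside the template")
    extra_fracs <- vapply(extras, function(e) {
      abs(mutation_cut_distance(cut, e)) / params$arm_len
    }, 1.0)
    cand <- structure(list(
      template = tpl, site = site, cut = cut, edit = edit,
      disruption = if (length(disruption)) disruption[[1L]] else NULL,
      n_disruptions = length(disruption), extra_fracs = extra_fracs,
      distance = d, warnings = warnings,
      components = NULL, score = NULL
    ), class = "design_candidate")
    cands[[length(cands) + 1L]] <- score_candidate(cand, params)
  }
  if (length(cands)) {
    ord <- order(-vapply(cands, function(c) c$score, 1.0),
                 vapply(cands, function(c) c$site$pam_interval[1L], 1L),
                 vapply(cands, function(c) c$site$strand, "") != "+")
    cands <- cands[ord]
  } else if (!length(diagnostics)) {
    diagnostics <- "no AsCas12a site found on either strand"
  }
  structure(list(locus_name = loc$name, edit = edit, params = params,
                 candidates = cands, diagnostics = diagnostics),
            class = "design_report")
}

#' @export
print.design_candidate <- function(x, ...) {
  cat(sprintf("<design_candidate> score %.3f  %s strand, PAM at %d, distance %d bp\n",
              x$score, x$site$strand, x$site$pam_interval[1L], x$distance))
  cat("  components:",
      paste(sprintf("%s=%.2f", names(x$components), x$components),
            collapse = " "), "\n")
  if (!is.null(x$disruption))
    cat(sprintf("  silent disruption: %d:%s>%s\n", x$disruption$position,
                x$disruption$ref, x$disruption$alt))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s, edit %d:%s>%s: %d candidate(s)\n",
              x$locus_name, x$edit$position, x$edit$ref, x$edit$alt,
              length(x$candidates)))
  for (c in x$candidates) print(c)
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

#' Design a CAPR replacement insert
#'
#' Cut-and-paste repair: two AsCas12a cuts excise the region around
#' `replace_interval`; the insert reproduces the genomic sequence between the
#' two top-strand nicks with the replacement applied, terminated by a 5'
#' overhang at each end complementary to the corresponding genomic fragment
#' overhang. The replacement may change length. The site pair chosen is the
#' closest pair flanking the interval whose double-stranded core still covers
#' it (so both overhangs remain genomic and ligatable).
#'
#' @param x a [locus()] or DNA string.
#' @param replace_interval `c(start, end)` 1-based inclusive top-strand
#'   interval to replace.
#' @param replacement DNA string (may be `""` for a pure deletion, or longer
#'   than the interval for an insertion).
#' @param params a [design_params()] (supplies the nick choice).
#' @param strict escalate the identical/palindromic-overhang orientation
#'   warning to an error.
#' @return an object of class `capr_design`.
#' @export
design_capr <- function(x, replace_interval, replacement,
                        params = design_params(), strict = FALSE) {
  loc <- as_locus(x)
  replace_interval <- as.integer(replace_interval)
  stopifnot(length(replace_interval) == 2L)
  rs <- replace_interval[1L]; re <- replace_interval[2L]
  L <- nchar(loc$seq)
  if (rs < 1L || re > L || re < rs)
    stop("replace_interval outside the locus", call. = FALSE)
  replacement <- toupper(replacement)
  check_dna(replacement, "replacement", allow_empty = TRUE)
  sites <- find_sites(loc, cas12a_profile(nick_nontarget = params$nick_choice))
  cuts <- lapply(sites, staggered_cut, nick_choice = params$nick_choice)
  lefts <- Filter(function(ct) ct$cut_right < rs, cuts)
  rights <- Filter(function(ct) ct$cut_left >= re, cuts)
  if (!length(lefts) || !length(rights))
    stop("no pair of AsCas12a sites flanks the replacement interval",
         call. = FALSE)
  # tightest excision: left cut with greatest bottom nick, right cut with
  # smallest top nick (ties: leftmost PAM, + strand first)
  pick <- function(cc, key, decreasing) {
    ord <- order(vapply(cc, key, 1L),
                 vapply(cc, function(ct) ct$site$pam_interval[1L], 1L),
                 vapply(cc, function(ct) ct$site$strand, "") != "+",
                 decreasing = c(decreasing, FALSE, FALSE), method = "radix")
    cc[[ord[1L]]]
  }
  cutA <- pick(lefts, function(ct) ct$cut_right, TRUE)
  cutB <- pick(rights, function(ct) ct$cut_left, FALSE)
  c_tA <- cutA$cut_left; c_bA <- cutA$cut_right
  c_tB <- cutB$cut_left; c_bB <- cutB$cut_right
  delta <- nchar(replacement) - (re - rs + 1L)
  new_top <- paste0(substr(loc$seq, 1L, rs - 1L), replacement,
                    substr(loc$seq, re + 1L, L))
  insert_top <- substr(new_top, c_tA + 1L, c_tB + delta)
  insert_bottom <- revcomp(substr(new_top, c_bA + 1L, c_bB + delta))
  if (nchar(insert_top) < (c_bA - c_tA) + (c_bB - c_tB))
    stop("replacement leaves no double-stranded insert core", call. = FALSE)
  lp <- substr(loc$seq, c_tA + 1L, c_bA)            # left 5' protrusion (top)
  rp <- revcomp(substr(loc$seq, c_tB + 1L, c_bB))   # right 5' protrusion (bottom)
  warnings <- character(0)
  if (identical(lp, rp) || identical(lp, revcomp(rp))) {
    msg <- sprintf(
      "insert overhangs %s/%s are identical or mutually reverse-complementary; insert orientation is not enforced",
      lp, rp)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    warnings <- msg
  }
  structure(list(
    left_cut = cutA, right_cut = cutB,
    excised_interval = c(c_tA + 1L, c_tB),
    insert_top = insert_top, insert_bottom = insert_bottom,
    left_overhang = lp, right_overhang = rp,
    replace_interval = c(rs, re), replacement = replacement,
    warnings = warnings
  ), class = "capr_design")
}

#' @export
print.capr_design <- function(x, ...) {
  cat(sprintf("<capr_design> excising top-strand [%d, %d], replacing [%d, %d] (%d bp) with %d bp\n",
              x$excised_interval[1L], x$excised_interval[2L],
              x$replace_interval[1L], x$replace_interval[2L],
              x$replace_interval[2L] - x$replace_interval[1L] + 1L,
              nchar(x$replacement)))
  cat("  insert top    5'-", x$insert_top, "-3'\n", sep = "")
  cat("  insert bottom 5'-", x$insert_bottom, "-3'\n", sep = "")
  cat(sprintf("  overhangs: left %s / right %s\n", x$left_overhang,
              x$right_overhang))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Simulate ligation of a CAPR insert into the doubly cut locus
#'
#' Verifies both insert overhangs against the genomic fragment overhangs
#' (ligation-incompatible error on mismatch), checks the two insert strands
#' are mutually consistent, and returns the repaired top-strand sequence —
#' which for a well-formed design equals the locus with the replacement
#' applied.
#'
#' @param x the [locus()] the design was built against.
#' @param design a [design_capr()] result.
#' @return the repaired top-strand sequence.
#' @export
simulate_capr_ligation <- function(x, design) {
  loc <- as_locus(x)
  stopifnot(inherits(design, "capr_design"))
  c_tA <- design$left_cut$cut_left; c_bA <- design$left_cut$cut_right
  c_tB <- design$right_cut$cut_left; c_bB <- design$right_cut$cut_right
  L <- nchar(loc$seq)
  ov_left_len <- c_bA - c_tA
  ov_right_len <- c_bB - c_tB
  if (!identical(substr(design$insert_top, 1L, ov_left_len),
                 substr(loc$seq, c_tA + 1L, c_bA)))
    stop("ligation-incompatible: insert left overhang does not match the ",
         "left genomic fragment", call. = FALSE)
  if (!identical(substr(design$insert_bottom, 1L, ov_right_len),
                 revcomp(substr(loc$seq, c_tB + 1L, c_bB))))
    stop("ligation-incompatible: insert right overhang does not match the ",
         "right genomic fragment", call. = FALSE)
  # the top strand protrudes only at the left end, the bottom strand only at
  # the right end, so past its 5' protrusion each strand must complement the
  # other over the full double-stranded core
  core_top <- substr(design$insert_top, ov_left_len + 1L,
                     nchar(design$insert_top))
  core_bottom <- substr(design$insert_bottom, ov_right_len + 1L,
                        nchar(design$insert_bottom))
  if (!identical(revcomp(core_bottom), core_top))
    stop("insert strands are not mutually complementary over the ",
         "double-stranded core", call. = FALSE)
  paste0(substr(loc$seq, 1L, c_tA), design$insert_top,
         substr(loc$seq, c_tB + 1L, L))
}

#' Emit orderable oligos for a template
#'
#' Returns the exact 5'->3' single-stranded DNA strings to synthesize; the
#' duplex (including overhangs) is reconstituted by annealing the pair, as in
#' the wet-lab workflow of annealing two complementary ssDNA oligos.
#'
#' @param template a `lahr_template` or `capr_design`.
#' @return named character vector `c(top = ..., bottom = ...)`.
#' @export
template_to_oligos <- function(template) {
  if (inherits(template, "lahr_template"))
    return(c(top = template$top_strand, bottom = template$bottom_strand))
  if (inherits(template, "capr_design"))
    return(c(top = template$insert_top, bottom = template$insert_bottom))
  stop("template must be a lahr_template or capr_design", call. = FALSE)
}
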