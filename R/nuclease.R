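# Target-site scanning and staggered-cut geometry.
#
# Geometry conventions used throughout:
#  * base coordinates are 1-based inclusive on the locus top strand;
#  * a nick is a boundary coordinate: the number of bases 5' of the nick on the
#    top strand (nick between top positions b and b+1 is stored as b);
#  * the "site frame" is the strand on which PAM + protospacer read 5'->3'
#    (the non-target strand); minus-strand sites are computed in their own
#    frame and mirrored back, so all reports carry top-strand coordinates plus
#    a strand.
# For every 5' overhang the top-strand nick lies left of the bottom-strand
# nick, whichever strand the site is on.

#' Nuclease cut-geometry profile
#'
#' Describes where a nuclease nicks each strand relative to its PAM.
#' For AsCas12a the PAM (TTTV) lies 5' of a 23-nt protospacer and the
#' non-target strand is nicked after the 18th or 19th protospacer base while
#' the target strand is nicked after the 23rd, yielding a 5-nt or 4-nt
#' 5' overhang. The target-strand nick position is not printed anywhere as a
#' base index; 23 is the unique value consistent with the published nick
#' options (18/19) and overhang lengths (5/4), and it remains a parameter.
#' For SpCas9 the cut is blunt, 3 bp 5' of the NGG PAM (standard convention).
#'
#' @param nick_nontarget default non-target-strand nick (protospacer base index
#'   after which the nick falls); 19 by default because the 4-nt overhang
#'   template matched the PAM-distal sticky end best.
#' @param nick_target target-strand nick index (default 23).
#' @param nick_options allowed non-target nick choices.
#' @param protospacer_len protospacer length in bases.
#' @param spacer_len crRNA spacer length emitted (PAM-proximal bases of the
#'   protospacer), 18-25.
#' @param seed_region PAM-proximal protospacer base indices treated as the seed.
#' @return an object of class `nuclease_profile`.
#' @export
cas12a_profile <- function(nick_nontarget = 19L, nick_target = 23L,
                           nick_options = c(18L, 19L), protospacer_len = 23L,
                           spacer_len = 21L, seed_region = 1:6) {
  new_profile(
    name = "AsCas12a", pam = "TTTV", pam_side = "5prime",
    protospacer_len = as.integer(protospacer_len),
    nick_nontarget = as.integer(nick_nontarget),
    nick_target = as.integer(nick_target),
    nick_options = as.integer(nick_options),
    spacer_len = as.integer(spacer_len),
    seed_region = as.integer(seed_region)
  )
}

#' @rdname cas12a_profile
#' @export
cas9_profile <- function(protospacer_len = 20L, spacer_len = 20L) {
  new_profile(
    name = "SpCas9", pam = "NGG", pam_side = "3prime",
    protospacer_len = as.integer(protospacer_len),
    nick_nontarget = 17L, nick_target = 17L, nick_options = 17L,
    spacer_len = as.integer(spacer_len), seed_region = integer(0)
  )
}

new_profile <- function(name, pam, pam_side, protospacer_len, nick_nontarget,
                        nick_target, nick_options, spacer_len, seed_region) {
  if (!spacer_len %in% 18:25 && name == "AsCas12a")
    stop("spacer_len must be between 18 and 25", call. = FALSE)
  if (!nick_nontarget %in% nick_options)
    stop("default nick_nontarget must be one of nick_options", call. = FALSE)
  if (nick_target < max(nick_options))
    stop("nick_target must not lie 5' of any non-target nick option ",
         "(overhangs are 5' overhangs)", call. = FALSE)
  if (nick_target > protospacer_len)
    stop("nick_target beyond the protospacer", call. = FALSE)
  structure(list(name = name, pam = pam, pam_side = pam_side,
                 protospacer_len = protospacer_len,
                 nick_nontarget = nick_nontarget, nick_target = nick_target,
                 nick_options = nick_options, spacer_len = spacer_len,
                 seed_region = seed_region),
            class = "nuclease_profile")
}

#' @export
print.nuclease_profile <- function(x, ...) {
  cat(sprintf("<nuclease_profile> %s: PAM %s (%s of protospacer), protospacer %d nt,\n",
              x$name, x$pam, if (x$pam_side == "5prime") "5'" else "3'",
              x$protospacer_len))
  cat(sprintf("  nicks: non-target after base %s (default %d), target after base %d\n",
              paste(x$nick_options, collapse = "/"), x$nick_nontarget,
              x$nick_target))
  invisible(x)
}

# Map a site-frame boundary/base coordinate to the top-strand frame.
sf_boundary_to_top <- function(b, strand, L) if (strand == "+") b else L - b
sf_base_to_top     <- function(p, strand, L) if (strand == "+") p else L + 1L - p
top_base_to_sf     <- sf_base_to_top

#' Locate nuclease target sites on both strands
#'
#' Scans a locus for PAM matches on both strands and returns every site whose
#' full protospacer fits inside the sequence, sorted by top-strand PAM start
#' then strand (+ before -). Intervals are 1-based inclusive top-strand
#' coordinates; `pam_seq`, `protospacer_seq` and `spacer_seq` are given in the
#' site's own frame (5'->3' on the PAM-carrying, non-target strand).
#'
#' @param x a [locus()] or DNA string.
#' @param profile a [cas12a_profile()] or [cas9_profile()].
#' @return list of `target_site` objects (class `target_site_list`).
#' @export
find_sites <- function(x, profile = cas12a_profile()) {
  loc <- as_locus(x)
  L <- nchar(loc$seq)
  plen <- nchar(profile$pam)
  sites <- list()
  for (strand in c("+", "-")) {
    sf_seq <- if (strand == "+") loc$seq else revcomp(loc$seq)
    for (pstart in iupac_find(profile$pam, sf_seq)) {
      if (profile$pam_side == "5prime") {
        proto <- c(pstart + plen, pstart + plen + profile$protospacer_len - 1L)
      } else {
        proto <- c(pstart - profile$protospacer_len, pstart - 1L)
      }
      if (proto[1L] < 1L || proto[2L] > L) next
      pam_sf <- c(pstart, pstart + plen - 1L)
      proto_seq <- substr(sf_seq, proto[1L], proto[2L])
      spacer <- if (profile$pam_side == "5prime") {
        substr(proto_seq, 1L, profile$spacer_len)
      } else {
        substr(proto_seq, profile$protospacer_len - profile$spacer_len + 1L,
               profile$protospacer_len)
      }
      to_top <- function(iv) {
        if (strand == "+") iv else c(L + 1L - iv[2L], L + 1L - iv[1L])
      }
      sites[[length(sites) + 1L]] <- structure(list(
        profile = profile, locus_name = loc$name, locus_len = L,
        strand = strand,
        pam_interval = to_top(pam_sf), protospacer_interval = to_top(proto),
        pam_interval_sf = pam_sf, protospacer_interval_sf = proto,
        pam_seq = substr(sf_seq, pam_sf[1L], pam_sf[2L]),
        protospacer_seq = proto_seq, spacer_seq = spacer
      ), class = "target_site")
    }
  }
  ord <- order(vapply(sites, function(s) s$pam_interval[1L], 1L),
               vapply(sites, function(s) s$strand, "") != "+")
  structure(sites[ord], class = "target_site_list")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s %s strand %s  PAM %s [%d,%d]  protospacer [%d,%d]\n",
              x$profile$name, x$locus_name, x$strand, x$pam_seq,
              x$pam_interval[1L], x$pam_interval[2L],
              x$protospacer_interval[1L], x$protospacer_interval[2L]))
  cat("  spacer 5'-", x$spacer_seq, "-3'\n", sep = "")
  invisible(x)
}

#' @export
print.target_site_list <- function(x, ...) {
  cat("<target_site_list> ", length(x), " site(s)\n", sep = "")
  for (s in x) print(s)
  invisible(x)
}

#' Compute the staggered-cut geometry of a target site
#'
#' Places the non-target-strand nick after the chosen protospacer base (18 or
#' 19 for AsCas12a) and the target-strand nick after the profile's
#' target-strand base (default 23), giving a 5-nt or 4-nt 5' overhang
#' respectively. For SpCas9 both nicks coincide (blunt, overhang length 0).
#' `overhang_seq` is the single-stranded 5' overhang read 5'->3' on the site's
#' non-target strand, i.e. the protospacer bases strictly between the two
#' nicks.
#'
#' @param site a `target_site` from [find_sites()].
#' @param nick_choice non-target-strand nick (protospacer base index); must be
#'   one of the profile's `nick_options`. Defaults to the profile default.
#' @return an object of class `cut_geometry` with top-strand boundary
#'   coordinates `nick_nontarget_coord` / `nick_target_coord` (and the
#'   left/right convenience boundaries `cut_left` <= `cut_right`).
#' @export
staggered_cut <- function(site, nick_choice = NULL) {
  stopifnot(inherits(site, "target_site"))
  prof <- site$profile
  if (is.null(nick_choice)) nick_choice <- prof$nick_nontarget
  nick_choice <- as.integer(nick_choice)
  if (!nick_choice %in% prof$nick_options)
    stop("nick choice ", nick_choice, " not in the profile's allowed set {",
         paste(prof$nick_options, collapse = ", "), "}", call. = FALSE)
  L <- site$locus_len
  sf_start <- site$protospacer_interval_sf[1L]
  b_nt_sf <- sf_start - 1L + nick_choice        # non-target strand nick
  b_t_sf  <- sf_start - 1L + prof$nick_target   # target strand nick
  overhang_len <- b_t_sf - b_nt_sf
  overhang_seq <- if (overhang_len > 0L) {
    substr(site$protospacer_seq, nick_choice + 1L, prof$nick_target)
  } else ""
  nick_nt <- sf_boundary_to_top(b_nt_sf, site$strand, L)
  nick_t  <- sf_boundary_to_top(b_t_sf, site$strand, L)
  structure(list(
    site = site, nick_choice = nick_choice,
    nick_nontarget_coord = nick_nt, nick_target_coord = nick_t,
    nick_nontarget_sf = b_nt_sf, nick_target_sf = b_t_sf,
    cut_left = min(nick_nt, nick_t), cut_right = max(nick_nt, nick_t),
    overhang_len = overhang_len, overhang_seq = overhang_seq
  ), class = "cut_geometry")
}

#' @export
print.cut_geometry <- function(x, ...) {
  cat(sprintf("<cut_geometry> %s %s strand, nick choice %d\n",
              x$site$profile$name, x$site$strand, x$nick_choice))
  cat(sprintf("  non-target nick after top position %d; target nick after %d\n",
              x$nick_nontarget_coord, x$nick_target_coord))
  if (x$overhang_len > 0L) {
    cat(sprintf("  5' overhang: %s (%d nt)\n", x$overhang_seq, x$overhang_len))
  } else cat("  blunt cut\n")
  invisible(x)
}

#' Signed distance from an edit to the non-target-strand nick
#'
#' Counts the bases strictly between the edited base and the non-target-strand
#' nick, in the site's frame, signed so that a nick lying downstream
#' (PAM-distal) of the edit is positive. Equivalently, for an edit at
#' protospacer base m with nick choice k the distance is k - m, so the
#' published worked geometry (mutation 14 bases after the PAM, 18th-base nick)
#' gives +4. Edits at or beyond the nick give 0 or negative values.
#'
#' @param cut a [staggered_cut()] geometry.
#' @param edit an [edit_spec()] (top-strand position).
#' @return signed integer distance in bp.
#' @export
mutation_cut_distance <- function(cut, edit) {
  stopifnot(inherits(cut, "cut_geometry"), inherits(edit, "edit_spec"))
  if (edit$position > cut$site$locus_len)
    stop("edit lies outside the locus", call. = FALSE)
  e_sf <- top_base_to_sf(edit$position, cut$site$strand, cut$site$locus_len)
  as.integer(cut$nick_nontarget_sf - e_sf)
}

#' Export target sites as BED and TSV tables
#'
#' BED intervals are 0-based half-open per the BED convention (converted at
#' this interface only). The TSV carries the spacer sequences and nick
#' boundary coordinates for the default nick choice.
#'
#' @param sites a `target_site_list`.
#' @return list with `bed` and `tsv` data.frames.
#' @export
sites_to_tables <- function(sites) {
  stopifnot(inherits(sites, "target_site_list"))
  rows_bed <- list(); rows_tsv <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    id <- sprintf("%s_site%02d", s$profile$name, i)
    rows_bed[[length(rows_bed) + 1L]] <- data.frame(
      chrom = s$locus_name, start = s$pam_interval[1L] - 1L,
      end = s$pam_interval[2L], name = paste0(id, "_pam"), score = 0L,
      strand = s$strand, stringsAsFactors = FALSE)
    rows_bed[[length(rows_bed) + 1L]] <- data.frame(
      chrom = s$locus_name, start = s$protospacer_interval[1L] - 1L,
      end = s$protospacer_interval[2L], name = paste0(id, "_protospacer"),
      score = 0L, strand = s$strand, stringsAsFactors = FALSE)
    cut <- staggered_cut(s)
    rows_tsv[[i]] <- data.frame(
      site = id, locus = s$locus_name, strand = s$strand, pam = s$pam_seq,
      spacer = s$spacer_seq, nick_choice = cut$nick_choice,
      nick_nontarget = cut$nick_nontarget_coord,
      nick_target = cut$nick_target_coord,
      overhang = cut$overhang_seq, stringsAsFactors = FALSE)
  }
  list(bed = do.call(rbind, rows_bed), tsv = do.call(rbind, rows_tsv))
}
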