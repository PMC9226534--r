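params_arm <- function(n, ...) {
  p <- design_params(...)
  p$arm_len <- as.integer(n)  # sub-20 bp arms only for compact worked examples
  p
}

test_that("LAHR template anatomy: PAM-proximal arm plus sticky end complementary to the distal overhang", {
  loc <- demo_locus()
  cut <- staggered_cut(find_sites(loc)[[1L]], 19)
  tpl <- build_lahr_template(loc, cut, NULL, params_arm(6))
  expect_identical(tpl$top_strand, "ACCTTG")
  expect_identical(tpl$bottom_strand, "ATTGCAAGGT")
  expect_identical(tpl$overhang_seq, "ATTG")  # revcomp of genomic "CAAT"
  expect_identical(tpl$overhang_seq, revcomp(cut$overhang_seq))
  # bottom strand = top + overhang for 5'-overhang end types
  expect_identical(nchar(tpl$bottom_strand),
                   nchar(tpl$top_strand) + cut$overhang_len)
  # blunt variant has equal strand lengths and no overhang
  bl <- build_lahr_template(loc, cut, NULL, params_arm(6, end_type = "blunt"))
  expect_identical(nchar(bl$bottom_strand), nchar(bl$top_strand))
  expect_identical(bl$overhang_seq, "")
  # an 80-bp arm with the default matched 4-nt end gives an 84-nt bottom oligo
  syn <- make_locus(locus_spec(length = 200,
                               pams = list(list(pos = 90, strand = "+")),
                               seed = 5))
  cut80 <- staggered_cut(find_sites(syn$locus)[[1L]], 19)
  tpl80 <- build_lahr_template(syn$locus, cut80, NULL, design_params())
  expect_identical(nchar(tpl80$top_strand), 80L)
  expect_identical(nchar(tpl80$bottom_strand), 84L)
})

test_that("end-type variants alter only the sticky end", {
  loc <- demo_locus()
  cut <- staggered_cut(find_sites(loc)[[1L]], 19)
  base <- build_lahr_template(loc, cut, NULL, params_arm(6))
  for (et in c("5nt", "3nt", "mismatched", "blunt", "3prime")) {
    v <- build_lahr_template(loc, cut, NULL, params_arm(6, end_type = et))
    if (et != "3prime") expect_identical(v$top_strand, base$top_strand)
    ov_len <- switch(et, "5nt" = 5L, "3nt" = 3L, mismatched = 4L,
                     blunt = 0L, "3prime" = 0L)
    expect_identical(nchar(v$bottom_strand), 6L + ov_len)
  }
  mm <- build_lahr_template(loc, cut, NULL, params_arm(6, end_type = "mismatched"))
  d <- mapply(function(a, b) a != b,
              strsplit(mm$overhang_seq, "")[[1]],
              strsplit(base$overhang_seq, "")[[1]])
  expect_identical(sum(d), 1L)  # exactly one substituted overhang base
  tp <- build_lahr_template(loc, cut, NULL, params_arm(6, end_type = "3prime"))
  expect_identical(nchar(tp$top_strand), 6L + 4L)  # overhang moved to top 3'
})

test_that("perfect-repair simulation equals applying the carried edits, and incompatible ends fail strict ligation", {
  loc <- demo_locus()
  cut <- staggered_cut(find_sites(loc)[[1L]], 19)
  # no-edit template restores the original locus
  tpl0 <- build_lahr_template(loc, cut, NULL, params_arm(10))
  expect_identical(simulate_perfect_lahr(loc, cut, tpl0), loc$seq)
  # one substitution in the arm
  e <- edit_spec(25, substr(loc$seq, 25, 25),
                 setdiff(c("A", "C", "G", "T"), substr(loc$seq, 25, 25))[1])
  tpl <- build_lahr_template(loc, cut, e, params_arm(10))
  expect_identical(simulate_perfect_lahr(loc, cut, tpl),
                   apply_edits(loc, e))
  # blunt or mismatched ends are ligation-incompatible under strict mode
  for (et in c("blunt", "mismatched", "3nt"))
    expect_error(
      simulate_perfect_lahr(loc, cut,
        build_lahr_template(loc, cut, NULL, params_arm(10, end_type = et))),
      "ligation-incompatible")
  # edits inside the overhang are rejected unless overridden
  e_ov <- edit_spec(29, substr(loc$seq, 29, 29), "G")
  expect_error(build_lahr_template(loc, cut, e_ov, params_arm(10)),
               "overhang")
  expect_silent(build_lahr_template(loc, cut, e_ov,
                                    params_arm(10, allow_overhang_edit = TRUE)))
})

test_that("LAHR round trip holds on random fixtures on both strands and both nick choices", {
  set.seed(515)
  for (i in 1:40) {
    fx <- random_lahr_fixture()
    loc <- fx$syn$locus
    sites <- find_sites(loc)
    s <- Filter(function(z) z$strand == fx$strand, sites)[[1L]]
    cut <- staggered_cut(s, fx$nick)
    p <- design_params(arm_len = fx$arm_len, nick_choice = fx$nick)
    tpl <- build_lahr_template(loc, cut, fx$syn$edit, p)
    expect_identical(simulate_perfect_lahr(loc, cut, tpl),
                     apply_edits(loc, fx$syn$edit))
  }
})

test_that("designing against the reverse-complemented locus yields the mirrored template", {
  set.seed(525)
  for (i in 1:10) {
    fx <- random_lahr_fixture()
    loc <- fx$syn$locus
    L <- nchar(loc$seq)
    s <- Filter(function(z) z$strand == fx$strand, find_sites(loc))[[1L]]
    cut <- staggered_cut(s, fx$nick)
    p <- design_params(arm_len = fx$arm_len, nick_choice = fx$nick)
    tpl <- build_lahr_template(loc, cut, fx$syn$edit, p)
    locm <- locus(revcomp(loc$seq))
    e <- fx$syn$edit
    em <- edit_spec(L + 1L - e$position, revcomp(e$ref), revcomp(e$alt))
    mstrand <- chartr("+-", "-+", fx$strand)
    sm <- Filter(function(z) z$strand == mstrand, find_sites(locm))[[1L]]
    tplm <- build_lahr_template(locm, staggered_cut(sm, fx$nick), em, p)
    expect_identical(tplm$top_strand, tpl$top_strand)
    expect_identical(tplm$bottom_strand, tpl$bottom_strand)
  }
})

test_that("ssODN length always equals the sum of the arms and uses the preferred strand", {
  syn <- make_locus(locus_spec(length = 260,
                               pams = list(list(pos = 100, strand = "+")),
                               snv = list(pam = 1, proto_base = 14), seed = 9))
  cut <- staggered_cut(find_sites(syn$locus)[[1L]])
  s160 <- design_ssodn(syn$locus, syn$edit, cut, c(80, 80))
  expect_identical(nchar(s160$seq), 160L)
  s100 <- design_ssodn(syn$locus, syn$edit, cut, c(50, 50))
  expect_identical(nchar(s100$seq), 100L)
  # Cas12a: non-target strand = substring of the edited top strand (+ site)
  expect_identical(s160$strand_used, "non-target")
  expect_true(grepl(s160$seq, apply_edits(syn$locus, syn$edit), fixed = TRUE))
  # asymmetric arms
  set.seed(535)
  for (i in 1:10) {
    arms <- sample(20:60, 2, replace = TRUE)
    expect_identical(nchar(design_ssodn(syn$locus, syn$edit, cut, arms)$seq),
                     sum(arms))
  }
  # edit outside the span is a placement error
  expect_error(design_ssodn(syn$locus, syn$edit,
                            cut, c(1, 1)), "outside the ssODN span")
  # SpCas9 emits the target strand
  loc9 <- locus(paste0(strrep("A", 4), "ACTGAACCTTGGAACCTTGC", "AGG",
                       strrep("C", 24)))
  s9 <- Filter(function(z) z$strand == "+", find_sites(loc9, cas9_profile()))[[1L]]
  e9 <- edit_spec(15, substr(loc9$seq, 15, 15),
                  setdiff(c("A", "C", "G", "T"), substr(loc9$seq, 15, 15))[1])
  sso9 <- design_ssodn(loc9, e9, staggered_cut(s9), c(10, 10))
  expect_identical(sso9$strand_used, "target")
  expect_identical(sso9$seq,
                   revcomp(substr(apply_edits(loc9, e9),
                                  staggered_cut(s9)$nick_nontarget_sf - 9L,
                                  staggered_cut(s9)$nick_nontarget_sf + 10L)))
})

test_that("candidate enumeration filters by distance window and orders deterministically", {
  syn <- make_locus(locus_spec(length = 220,
                               pams = list(list(pos = 80, strand = "+")),
                               snv = list(pam = 1, proto_base = 17), seed = 21))
  rep <- enumerate_designs(syn$locus, syn$edit)  # distance 19 - 17 = 2
  expect_length(rep$candidates, 1L)
  expect_identical(rep$candidates[[1L]]$distance, 2L)
  # an edit > 20 bp from every nick gives an empty list with a diagnostic
  far <- edit_spec(10, substr(syn$locus$seq, 10, 10),
                   setdiff(c("A", "C", "G", "T"),
                           substr(syn$locus$seq, 10, 10))[1])
  rep_far <- enumerate_designs(syn$locus, far)
  expect_length(rep_far$candidates, 0L)
  expect_true(length(rep_far$diagnostics) > 0L)
  # relaxing the window can only add candidates
  ed25 <- local({
    # edit 25 bp upstream of the nick: outside [0,20], inside [0,30]
    cut <- staggered_cut(find_sites(syn$locus)[[1L]])
    pos_sf <- cut$nick_nontarget_sf - 25L
    edit_spec(pos_sf, substr(syn$locus$seq, pos_sf, pos_sf),
              setdiff(c("A", "C", "G", "T"),
                      substr(syn$locus$seq, pos_sf, pos_sf))[1])
  })
  expect_length(enumerate_designs(syn$locus, ed25)$candidates, 0L)
  wide <- design_params(distance_window = c(0, 30))
  expect_gte(length(enumerate_designs(syn$locus, ed25, wide)$candidates), 1L)
})

test_that("scores are products of [0,1] components, monotone in distance and extra-edit placement", {
  syn <- make_locus(locus_spec(length = 220,
                               pams = list(list(pos = 80, strand = "+")),
                               snv = list(pam = 1, proto_base = 17), seed = 21))
  rep <- enumerate_designs(syn$locus, syn$edit)
  cand <- rep$candidates[[1L]]
  expect_true(all(cand$components >= 0 & cand$components <= 1))
  expect_equal(cand$score, prod(cand$components))
  # distance component decreases beyond the window
  c10 <- cand; c10$distance <- 10L
  c30 <- cand; c30$distance <- 30L
  s10 <- score_candidate(c10)$components[["distance"]]
  s30 <- score_candidate(c30)$components[["distance"]]
  expect_identical(s10, 1)
  expect_lt(s30, s10)
  # arm prior peaks at 80 bp
  arm_score <- function(a) {
    cc <- cand; cc$template$arm_len <- a
    score_candidate(cc)$components[["arm"]]
  }
  expect_identical(arm_score(80L), 1)
  expect_lt(arm_score(20L), arm_score(80L))
  expect_lt(arm_score(200L), arm_score(80L))
  # extra silent edit near the blunt end scores below one near the nick
  near <- cand; near$extra_fracs <- 0.1
  blunt_end <- cand; blunt_end$extra_fracs <- 0.95
  expect_lt(score_candidate(blunt_end)$components[["mid_arm"]],
            score_candidate(near)$components[["mid_arm"]])
  # all-maximal configuration: distance in window, 80-bp arm, no extras,
  # exactly one disruption
  best <- cand; best$n_disruptions <- 1L
  expect_identical(unname(score_candidate(best)$components),
                   rep(1, 5))
})

test_that("silent disruption candidates preserve the protein and break PAM or touch seed, never both modes", {
  # CDS frame 0 from position 1; PAM at 4-7 puts codon 2 = TTT (Phe) so the
  # synonymous TTT->TTC change at codon offset 3 (locus position 6) breaks TTTV
  seqs <- paste0("ATG", "TTTC", DEMO_PROTO, "CCCCC")  # 35 bp, CDS 1..33
  loc <- locus(seqs, cds = cds_annotation(1, 33, "+", 0))
  site <- find_sites(loc)[[1L]]
  pam_cand <- silent_disruption_candidates(loc, site, "pam")
  expect_true(length(pam_cand) >= 1L)
  for (e in pam_cand) {
    expect_true(e$position >= site$pam_interval[1L] &&
                e$position <= site$pam_interval[2L])
    edited <- apply_edits(loc, e)
    # PAM no longer matches TTTV at the original location
    expect_false(4L %in% brute_iupac_find("TTTV", edited))
    # protein unchanged
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(substr(edited, 1, 33)))),
      as.character(Biostrings::translate(Biostrings::DNAString(substr(seqs, 1, 33)))))
  }
  expect_error(silent_disruption_candidates(loc, site, "both"), "both")
  # seed region made of ATG and TGG codons admits no synonymous change
  seq2 <- paste0("C", "TTTC", "ATGTGG", substr(DEMO_PROTO, 7, 23), "CCCCC")
  loc2 <- locus(seq2, cds = cds_annotation(3, 32, "+", 0))
  site2 <- find_sites(loc2)[[1L]]
  expect_length(silent_disruption_candidates(loc2, site2, "seed"), 0L)
  # no CDS -> refuse unless the non-coding override is set
  loc3 <- locus(seqs)
  expect_error(silent_disruption_candidates(loc3, site, "pam"), "CDS")
  nc <- silent_disruption_candidates(loc3, site, "pam", allow_noncoding = TRUE)
  expect_true(length(nc) > 0L)
})

test_that("CAPR insert ligation reproduces the intended replacement exactly", {
  syn <- make_locus(locus_spec(length = 140,
                               pams = list(list(pos = 11, strand = "+"),
                                           list(pos = 95, strand = "+")),
                               seed = 7))
  repl <- strrep("ACG", 5)
  des <- design_capr(syn$locus, c(60, 70), repl)
  want <- paste0(substr(syn$locus$seq, 1, 59), repl,
                 substr(syn$locus$seq, 71, 140))
  expect_identical(simulate_capr_ligation(syn$locus, des), want)
  # identity replacement reproduces the wild type
  wt_repl <- substr(syn$locus$seq, 60, 70)
  des_wt <- design_capr(syn$locus, c(60, 70), wt_repl)
  expect_identical(simulate_capr_ligation(syn$locus, des_wt), syn$locus$seq)
  # insert overhangs complement the genomic fragment overhangs
  expect_identical(des$left_overhang,
                   substr(syn$locus$seq, des$left_cut$cut_left + 1L,
                          des$left_cut$cut_right))
  expect_identical(des$right_overhang,
                   revcomp(substr(syn$locus$seq, des$right_cut$cut_left + 1L,
                                  des$right_cut$cut_right)))
  # a corrupted insert no longer ligates
  bad <- des
  substr(bad$insert_top, 1, 1) <- next_base_chr(substr(bad$insert_top, 1, 1))
  expect_error(simulate_capr_ligation(syn$locus, bad), "ligation-incompatible")
  # no flanking pair
  expect_error(design_capr(syn$locus, c(3, 5), "AAA"), "no pair")
  # random-fixture round trips, including length-changing replacements
  set.seed(545)
  for (i in 1:15) {
    sy <- make_locus(locus_spec(length = 150,
                                pams = list(list(pos = 11, strand = "+"),
                                            list(pos = 100, strand = "+")),
                                seed = sample.int(1e6, 1)))
    rl <- sample(0:12, 1)
    rp <- if (rl == 0) "" else random_dna_str(rl)
    dd <- suppressWarnings(design_capr(sy$locus, c(62, 70), rp))
    want_i <- paste0(substr(sy$locus$seq, 1, 61), rp,
                     substr(sy$locus$seq, 71, 150))
    expect_identical(simulate_capr_ligation(sy$locus, dd), want_i)
  }
})

test_that("palindromic or identical CAPR overhangs raise the orientation warning", {
  # engineer both cuts to yield overhang AATT (self-reverse-complementary):
  # protospacer bases 20-23 = AATT at both sites
  proto <- paste0(substr(DEMO_PROTO, 1, 19), "AATT")
  seqs <- paste0(strrep("C", 6), "TTTC", proto,
                 strrep("G", 20), "TTTC", proto, strrep("C", 6))
  loc <- locus(seqs)
  mid <- 6 + 4 + 23 + 10
  expect_warning(design_capr(loc, c(mid, mid + 2), "ACGACG"),
                 "reverse-complementary")
  expect_error(design_capr(loc, c(mid, mid + 2), "ACGACG", strict = TRUE),
               "reverse-complementary")
})

test_that("templates emit exactly two 5'->3' oligos that anneal back to the duplex", {
  loc <- demo_locus()
  cut <- staggered_cut(find_sites(loc)[[1L]], 19)
  # blunt template -> two exact reverse complements
  bl <- build_lahr_template(loc, cut, NULL, params_arm(8, end_type = "blunt"))
  ob <- template_to_oligos(bl)
  expect_identical(ob[["bottom"]], revcomp(ob[["top"]]))
  # matched 4-nt overhang -> bottom oligo 4 nt longer; annealed duplex
  # reconstructs arm + overhang
  tpl <- build_lahr_template(loc, cut, NULL, params_arm(8))
  o <- template_to_oligos(tpl)
  expect_identical(nchar(o[["bottom"]]), nchar(o[["top"]]) + 4L)
  expect_identical(revcomp(substr(o[["bottom"]], 5, nchar(o[["bottom"]]))),
                   o[["top"]])
  # CAPR insert carries one 5' protrusion at each end
  syn <- make_locus(locus_spec(length = 140,
                               pams = list(list(pos = 11, strand = "+"),
                                           list(pos = 95, strand = "+")),
                               seed = 7))
  des <- design_capr(syn$locus, c(60, 70), "ACGTACGT")
  oc <- template_to_oligos(des)
  lo <- nchar(des$left_overhang); ro <- nchar(des$right_overhang)
  core_top <- substr(oc[["top"]], lo + 1L, nchar(oc[["top"]]))
  expect_identical(revcomp(substr(oc[["bottom"]], ro + 1L,
                                  nchar(oc[["bottom"]]))), core_top)
})

test_that("arm length and distance-window bounds are validated", {
  expect_error(design_params(arm_len = 10), "\\[20, 200\\]")
  expect_error(design_params(arm_len = 250), "\\[20, 200\\]")
  expect_error(design_params(distance_window = c(-5, 20)), "lower")
  expect_error(design_params(disruption_mode = "pam+seed"), "arg")
})
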