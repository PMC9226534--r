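# Fixtures and independent oracles used across the suite.

# 35-nt locus: 4-nt lead-in, TTTC PAM, a fixed 23-nt protospacer, C-rich tail
# chosen so no second TTTV arises on either strand.
DEMO_PROTO <- "ACTGAACCTTGGAACCTTGCAAT"
demo_locus <- function() {
  locus(paste0("AAAA", "TTTC", DEMO_PROTO, "CCCC"), name = "demo")
}

random_dna_str <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# brute-force window scan over every start position (oracle for iupac_find)
IUPAC_EXP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
brute_iupac_find <- function(pattern, seq) {
  np <- nchar(pattern); ns <- nchar(seq)
  if (ns < np) return(integer(0))
  pc <- strsplit(pattern, "")[[1L]]
  hits <- integer(0)
  for (st in 1:(ns - np + 1L)) {
    win <- strsplit(substr(seq, st, st + np - 1L), "")[[1L]]
    if (all(mapply(function(b, code) b %in% IUPAC_EXP[[code]], win, pc)))
      hits <- c(hits, st)
  }
  hits
}

# exhaustive-enumeration global alignment score (oracle for align_global)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a)) return(nchar(b) * gap)
  if (!nzchar(b)) return(nchar(a) * gap)
  sub <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
  max(nw_score_oracle(substring(a, 2), substring(b, 2), match, mismatch, gap) + sub,
      nw_score_oracle(substring(a, 2), b, match, mismatch, gap) + gap,
      nw_score_oracle(a, substring(b, 2), match, mismatch, gap) + gap)
}

# random locus with one planted Cas12a site and an SNV inside the arm,
# leaving room for a 20-40 bp arm on the PAM-proximal side
random_lahr_fixture <- function() {
  len <- sample(120:240, 1L)
  strand <- sample(c("+", "-"), 1L)
  nick <- sample(c(18L, 19L), 1L)
  pos <- if (strand == "+") sample(40:(len - 27L), 1L)
         else sample(24:(len - 45L), 1L)
  proto_base <- sample(1:nick, 1L)
  syn <- make_locus(locus_spec(
    length = len, pams = list(list(pos = pos, strand = strand)),
    snv = list(pam = 1L, proto_base = proto_base),
    seed = sample.int(1e6, 1L)))
  list(syn = syn, proto_base = proto_base, strand = strand, nick = nick,
       arm_len = sample(20:40, 1L))
}

next_base_chr <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
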