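# lahr

Design toolkit for precise genome editing with the staggered cut of
**AsCas12a**: LAHR (ligation-assisted homologous recombination) repair
templates, CAPR (cut-and-paste repair) replacement inserts, and comparison
ssODN donors — plus quantification of editing outcomes from amplicon reads.

## The problem and the model

SpCas9 leaves blunt double-strand breaks; AsCas12a recognises a T-rich PAM
(TTTV) 5′ of a 23-nt protospacer and nicks the **non-target strand after the
18th or 19th base behind the PAM** and the target strand after the 23rd,
leaving a **5-nt or 4-nt 5′ overhang** respectively. A LAHR template turns
this sticky end into a repair handle: it carries

* a 5′ overhang complementary to the PAM-distal fragment's overhang
  (ligated directly, MMEJ-style), and
* a homology arm matching the PAM-proximal side of the break (resolved by
  HDR), carrying the desired substitution.

For a site with non-target nick boundary *b* (top-strand bases 5′ of the
nick), target nick boundary *b′* and arm length *L*, the template is

```
top    = edited[b−L+1 … b]                      (the arm, 5′→3′)
bottom = revcomp(edited[b−L+1 … b′])            (arm complement + 5′ sticky end)
```

so the bottom oligo is `L + (b′−b)` nt — 84 nt for the default 80-bp arm and
4-nt overhang. The signed mutation-to-cut distance for an edit at
protospacer base *m* with nick choice *k* is *k − m*; designs are admitted
for distances in \[0, 20\] bp by default. Candidates are ranked by a product
of \[0, 1\] components (distance, arm-length prior peaking at 80 bp, total
length with a 120-bp threshold, mid-arm extra-edit placement, re-cut
avoidance via one silent PAM-or-seed disruption). Editing outcomes are
classified by global alignment inside a ±20-bp window around the nick, and

```
efficiency (%) = 100 × edited reads / (total − discarded) reads
```

See `vignettes/lahr-methods.Rmd` for the full account of conventions,
heuristics and limitations.

## Worked example

Generate a 200-nt locus with one planted TTTC PAM and a point mutation at
protospacer base 14, design a repair, and quantify a simulated read set:

```r
library(lahr)

syn  <- make_locus(locus_spec(length = 200,
                              pams = list(list(pos = 70, strand = "+")),
                              snv  = list(pam = 1, proto_base = 14),
                              seed = 42))
syn$edit
#> <edit> 87:C>G

site <- find_sites(syn$locus)[[1]]
staggered_cut(site, 19)
#> <cut_geometry> AsCas12a + strand, nick choice 19
#>   non-target nick after top position 92; target nick after 96
#>   5' overhang: CAAT (4 nt)

mutation_cut_distance(staggered_cut(site, 18), syn$edit)
#> [1] 4

rep <- enumerate_designs(syn$locus, syn$edit)
rep
#> <design_report> synthetic_locus, edit 87:C>G: 1 candidate(s)
#> <design_candidate> score 0.600  + strand, PAM at 70, distance 5 bp
#>   components: distance=1.00 arm=1.00 total_length=1.00 mid_arm=1.00 recut=0.60
```

The one admissible site sits 5 bp from the edit; distance, arm (80 bp) and
length components are maximal, and the re-cut component is 0.6 because no
silent PAM/seed disruption was requested (`disruption_mode = "pam"` would
lift it to 1 where the locus has a CDS annotation).
`template_to_oligos(rep$candidates[[1]]$template)` prints the two 5′→3′
strings to order — an 80-nt top oligo and an 84-nt bottom oligo whose first
four bases (`ATTG`) are the sticky end complementary to the genomic `CAAT`
overhang.

Simulated outcome quantification recovers a planted 25% edited fraction:

```r
refs  <- amplicon_refs(syn$locus$seq, apply_edits(syn$locus, syn$edit),
                       nick = staggered_cut(site, 19)$nick_nontarget_coord)
reads <- simulate_reads(read_sim_spec(refs, c(edited = 0.25, wt = 0.75),
                                      n_reads = 1000, error_rate = 0.001,
                                      seed = 42))
quantify_amplicons(reads, refs)
#> <amplicon_report> 1000 reads; window [73, 112]
#>   edited 227  wt 732  indel 0  discarded 41
#>   editing efficiency: 23.67% of retained reads
```

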