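---
title: "Models and methods behind traScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traScan)
```

## The biological system

In blowflies and several other dipterans, the *transformer* (*tra*) gene is
the switch of somatic sex determination, and the switch is thrown by
alternative splicing. Male and female transcripts differ only in which splice
donor joins the first intron's acceptor: females splice from a donor at the
end of exon 1, males from a donor several hundred nucleotides downstream, at
the 3' end of a male-specific exon that lies inside the regulated intron.
The male exon carries in-frame stop codons, so only the female mRNA encodes
full-length TRA protein. Splicing is thought to be autoregulated: TRA, with
TRA2 and RBP1, binds a cluster of degenerate 13-nt elements (TRA/TRA2 sites,
the *dsx*RE repeat class, consensus `(T/A)(C/A)(A/T)(A/T)CAATCAACA` in DNA
alphabet) in the intron plus one site in the male exon, and blocks the male
donor in females.

traScan packages the comparative analyses used to characterize this
architecture: gene models and isoform construction, degenerate and PFM motif
scanning, binding-site information-content profiles, splice-donor scoring
against U1 snRNA, and pairwise conservation analysis — together with a
synthetic-gene generator that plants the whole architecture so every stage
is testable without any sequence download.

## Gene models and isoforms

A `gene_model` is a sense-strand sequence plus typed features (`exon`,
`male_exon`, `female_intron_1`, `intron`, UTRs) in a single 0-based
half-open coordinate frame; GFF3 I/O converts to and from 1-based inclusive
coordinates, and minus-strand input is reverse-complemented at load because
every element modeled here acts on the pre-mRNA. Validation requires exactly
one male exon inside the single regulated intron. The male exon may begin
at the female donor junction itself (as it does in the real genes, where the
male exon immediately follows exon 1) but must end strictly before the
acceptor, since the male donor needs downstream intron to splice from.

`build_isoforms()` makes the two isoforms explicit: the female mRNA is the
exon chain; the male mRNA is exon 1 extended through the intron's 5' segment
and male exon to the male donor, then the remaining exons. In-frame stop
codons are reported in spliced coordinates with the frame anchored at the
first spliced base; a stop in the final codon terminates the ORF normally,
so the "female ORF is intact" guarantee is checked as *no premature stop*.

## Motif scanning

Degenerate IUPAC consensi are matched by sliding-window set membership:
position `j` of a window matches if its base is in the motif's allowed set,
an `N` in the sequence never matches, and a hit is any window with at most
`max_mismatch` violations. All hits are reported, including overlapping
ones — required because overlapping TRA/TRA2 matches occur in real genes and
both must be counted. The default allowance is 0 mismatches: site counts in
this system are conventionally reported as exact degenerate matches.

PFM scanning follows the liberal regex-expansion policy: a position
frequency matrix is collapsed to its per-column support (bases with nonzero
count), every matching window is reported, and each hit carries the
probability of its exact word under the column-independent PFM model
(product of observed-base frequencies). This is a match-probability
annotation, not a log-odds score against a background model; PWM scoring is
deliberately out of scope. `fragment_scan()` breaks a long degenerate motif
into overlapping k-mers (8 or 10 in typical use) and scans each, which
trades specificity for sensitivity to partial matches; fragments shorter
than 4 nt trigger a warning because expected random hit rates become
substantial.

The built-in library holds DNA renderings of the elements this analysis
needs: the 13-nt TRA/TRA2 core `WMWWCAATCAACA`, the `TACYA` 3' flank, the
18/19-nt extended site (core, then flank after a 0- or 1-nt spacer — two
library entries because a fixed-length IUPAC string cannot express the
variable spacer), the RBP1 type A site `DCADCTTA`, a T-rich run (`TTTTT`,
one mismatch allowed), the *Nasonia*-type `KGAAGATW` element and the
UNR-associated `ATGAATTT` element. The TRA2-ISS silencer consensus is not
built in: it is not public in a citable printed form here, so it must be
supplied through the YAML motif config if wanted.

## Site profiles and information content

Fixed-width windows (26 nt by default) are cut around hits so every motif
start lands on one anchor column. The PFM is pure counts (`N` excluded from
column totals) and per-column information content is computed against a
uniform background with no pseudocount:

$$ IC_j = 2 + \sum_b p_{bj} \log_2 p_{bj} \quad \in [0, 2] \text{ bits}, $$

with $0 \log 0 = 0$. The derived consensus uses, per column, the smallest
IUPAC code covering all bases at frequency at least `fraction_threshold`
(default 0.25; if no base reaches the threshold the code covers all observed
bases), and the core span is the longest contiguous column run with IC at
least `ic_threshold` (default 0.5 bits). Both defaults are explicit
because the source analyses derived the extended-site span "by inspection";
0.5 bits separates the planted-element columns from background columns at
the window counts used here, and 0.25 admits any base carried by at least a
quarter of the sites. No pseudocounts are added by default since the site
sets are small and the logo representation is count-based; `logo_matrix()`
exports the standard `p * IC` letter heights, and plotting is left to the
caller.

One measurement subtlety: windows are extracted unaligned, so the 1-nt
spacer variant of the extended site shifts its flank by one column. A
profile built from spacer-free extended sites shows the full 18-column
high-IC core; the 19-nt variant is established by scanning for it directly.
A profile pooling both variants shows only the 13-column core plus a
degraded flank — the column mixture, not a weaker signal.

## Splice-site scoring

`extract_splice_sites()` returns the female donor, male donor and shared
acceptor with exonic/intronic windows (donor −3..+6, acceptor −14..+2,
N-padded at sequence edges; all bounds configurable). Non-`GT` donors and
non-`AG` acceptors are flagged, not rejected. Consensus matching uses
junction-anchored split notation (`"AG/GTAAGT"`) and positionwise degenerate
counting, so statements like "6/8 match to the donor consensus" are direct
outputs.

Donor strength is proxied by the predicted hybrid with the 5' end of U1
snRNA. The U1 5' terminus defaults to the canonical metazoan sequence
`ACUUACCUGG` (config-overridable), and the register is fixed: the first
`w` bases of the U1 5' end pair antiparallel with the `w`-nt donor window,
i.e. donor position `i` against U1 position `w − i + 1`. Watson–Crick pairs
(G:C, A:U) are counted as `u1_pairs`; G:U wobble pairs are counted
separately and excluded by default, since the claim being modeled is a
Watson–Crick hybrid length and wobble policy is otherwise a free choice.
Under this register a consensus-matching male donor window (`NAGGTAAGT`)
forms 8–9 pairs and the invariant female donor window (`NTGGTAATT`) at most
7, so the male donor always outscores the female donor — the ordering that
motivates the model in which females must actively block the intrinsically
stronger male donor. Neural-network splice-site scores are a trained-model
output and are not reproduced here.

## Pairwise conservation

`global_align()` is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`, with EMBOSS-like DNA defaults (+5/−4, gap
open 10, extend 0.5) and BLOSUM62 for proteins; percent similarity adds
Clustal strong-group conservative substitutions. Percent identity divides
matches by *total alignment columns including gaps* — the convention that
makes heavily indel-diverged introns report the low identities they should.
Because co-optimal alignments are tie-broken differently depending on which
sequence is the pattern, the pair is aligned in a canonical (lexicographic)
order and swapped back, making identity exactly symmetric.

The dot matrix is the classic windowed comparison: point `(i, j)` iff the
two windows agree at `min_matches` of `window` positions (defaults 8 and 7;
the original plots' exact settings are unpublished, so only qualitative
structure — diagonals, insertion breaks, conserved ends — is claimed). The
sweep runs per diagonal with running window sums, so multi-kilobase introns
are cheap.

Conserved blocks are called greedily and deterministically: every alignment
window of `min_block_len` columns at identity ≥ `min_block_identity` seeds
coverage, covered regions are merged, ends are trimmed to matching columns,
and merged segments are re-checked against both thresholds. Insertions are
maximal gap runs in either aligned sequence, with same-host runs separated
by at most `merge_within` host nucleotides merged into one call — long
random-sequence insertions routinely align as a few gap runs broken by
short spurious matches, and the merged host span is the quantity of
interest. Cluster calling is single-linkage on same-motif hits with an
inter-hit gap ceiling (default 150 nt, matching the conserved inter-site
spacing of the TRA/TRA2 cluster), annotated with feature context and
distance to the acceptor.

## The synthetic generator

`generate_gene()` emits an iid background at the configured GC content
(default 0.35, AT-rich as dipteran introns are) and plants, at known
coordinates: the invariant female donor context `TG/GTAATTTT`; a
consensus-matching male donor `AG/GTAAGT` at the male exon's 3' end; the
acceptor with a polypyrimidine tract and the invariant downstream exon start
`GTGAAGGTTC`; one TRA/TRA2 core near the male exon 3' end and a cluster of
4–5 cores toward the intron 3' end with gaps drawn uniformly from 40–120 nt,
most followed by the `TACYA` flank after a 0–1 nt spacer; the UNR-like and
*Nasonia*-like elements flanking the most 5' site; the RBP1 type A site plus
a TRA/TRA2 half-site ending 100 nt before the acceptor; T-rich runs; and an
in-frame `TAA` in the male exon, while the female CDS is built stop-free
(internal stop codons are repaired at synonymous-wobble positions). With
five sites, the most 5' "site" is two overlapping core matches at offset
7 nt — the smallest offset at which two exact matches of the degenerate core
can coexist. Default sizes (exons 198/150/162/246, male exon 231 at intron
offset 80 — placing the male donor 311 nt downstream of the female donor, as
in the best-characterized gene of this family — intron 2.5 kb) are a
deliberately scaled-down but structurally faithful architecture; they keep
the full test suite and the acceptance analysis inside a few minutes of CPU.

`diverge_gene()` derives an ortholog by Jukes–Cantor-like substitution
(uniform among the three alternatives) at probability `d` outside planted
elements and `d × motif_conservation_factor` inside them, plus
geometric-length indels that never start in, or delete, planted elements or
the ±10 nt around any feature boundary (junction regions are invariant in
the system modeled). All coordinates are lifted through the edit trace. A
structural-variant option inserts a background segment of configurable
length (e.g. 1100 nt) between the cluster and the acceptor, mimicking the
large intron insertion observed in one of the real genes. One integer seed
drives every draw; identical configurations are bit-identical.

What the generator does *not* emulate: codon-usage and selection structure
inside exons (background conservation of coding sequence arises only from
the planted junction codons), transposon-like sequence in the structural
insertion, microsatellite/low-complexity tracts, and any correlated
substitution process. Passing recovery tests on this generator therefore
demonstrates correctness of the measurement machinery under a clean
divergence model, not performance on real genomic noise.

## Validation design

The test suite checks every scanning and comparison primitive against
independent oracles: a naive all-windows degenerate matcher, exhaustive PFM
window enumeration, an all-pairs dot-matrix checker, a hand-written Gotoh
affine-gap DP for optimal alignment scores, and closed-form information
content (2.0 / 1.0 / 0.0 bits). Recovery tests assert 100% planted-site
recall on undiverged orthologs, ≥95% recall with perfectly conserved motifs
in a `d = 0.3` background, substitution-divergence identity inside the 99%
binomial interval of `100(1 − d)` on a 10 kb sequence, and the male>female
donor ordering on 50 seeded genes.

For "conserved blocks land on planted motifs", the statistic is the coverage
Jaccard between blocks called at motif scale (`min_block_len` 12, identity
0.95) and *detectable planted islands*: planted intervals within 2 nt of
each other merged (a core and its flank, or the RBP1 site and its
half-site, are one contiguous conserved island) and kept only if at least
as long as the minimum block. Elements shorter than any callable block
(8-nt singletons, T-runs, the 3-nt stop) cannot contribute to block
coverage under any parameterization, so including them would measure a
detectability floor rather than localization accuracy.

`validate_accessions()` runs the full comparative battery on the three
deposited blowfly *tra* genes; it needs a network fetch
(`fetch_tra_accessions()`), so it is exercised on demand rather than in the
default suite. Its structural logic — re-deriving the splice architecture
from the invariant junction contexts with `infer_tra_architecture()` — is
tested offline on synthetic genes, where it recovers the planted
coordinates exactly.

## Known limitations

Pairwise only: no multiple alignment, no phylogeny. Sense strand only. PFM
probability, not log-odds. Two isoforms only (minor splice variants of this
gene family are noted but not modeled). Dot-matrix and block parameters for
the published figures are unknown, so comparisons to them are qualitative.
The U1 register at the donor −1 position is a documented convention, not a
thermodynamic computation.
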