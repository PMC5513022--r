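---
title: "Methods: qPCR quantification, miRNA target rules, motif scanning and co-expression clustering in lignoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR quantification, miRNA target rules, motif scanning and co-expression clustering in lignoreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoreg)
```

# Scope

`lignoreg` implements the computational core of a candidate-gene study of
lignin biosynthesis regulation: identifying which members of large
phenylpropanoid and laccase gene families are the *bona fide* lignin genes,
and how they are regulated by a laccase-targeting microRNA and by MYB
transcription factors. The package covers five analysis stages — qPCR
quantification with multi-reference normalization and nonparametric
differential calls, Pearson-distance k-means-medians co-expression
clustering, rule-based miRNA target prediction with RLM-RACE cleavage
validation, degenerate MYB cis-element scanning of proximal promoters, and
an evidence-combining prioritizer — plus a synthetic-data generator that
emits every input with a ground-truth manifest so that each stage is
testable end to end.

# qPCR quantification

## Efficiency estimation

`estimate_efficiency()` fits, per assay, the least-squares slope of Cq
against $\log_{10}$ relative input over a dilution series (at least three
points spanning at least two decades) and reports
$E = 10^{-1/\text{slope}}$, the fold amplification per cycle. A perfect
doubling assay has slope $-3.32$ and $E = 2$. Values outside $(1.6, 2.2]$
trigger a warning rather than an error: published assay panels report no
hard QC cutoff, and flagged assays remain inspectable.

## Normalization model

`normalize_cq()` follows the qBase relative-quantification scheme with the
across-sample mean Cq as calibrator:

$$\mathrm{RQ}_{g,s} = E_g^{\;\overline{Cq}_g - Cq_{g,s}}, \qquad
\mathrm{NF}_s = \Big(\prod_{r \in \mathrm{refs}} \mathrm{RQ}_{r,s}\Big)^{1/|\mathrm{refs}|}, \qquad
\mathrm{NRQ}_{g,s} = \mathrm{RQ}_{g,s} / \mathrm{NF}_s .$$

Three stable reference assays are the intended default, mirroring common
practice (e.g. *ETIF5A*, *UBI*, *EF1A* panels in flax). Two structural
invariants follow algebraically and are asserted in the test suite: the
geometric mean of the reference NRQs is 1 in every sample, and adding a
constant to every Cq of a sample (a global pipetting shift) leaves all NRQ
unchanged.

Undetected reactions (`ND`) are kept as missing and excluded — never
imputed to zero — and an assay undetected throughout a condition is marked
not-testable rather than given a fold change.

## Replicate handling

The default design is 3 biological samples × 3 technical replicates. The
package's default treats the nine values per condition as the test sample
(`n = 9`), matching how mean ± SD panels with $n = 9$ are usually
reported; `average_technical = TRUE` first averages technical replicates
and tests `n = 3` biological units. Because the Mann-Whitney test is
rank-based, the choice affects power but not the direction of any call.

## Differential calls

`condition_ratios()` reports $\log_2(\overline{\mathrm{NRQ}}_{cond} /
\overline{\mathrm{NRQ}}_{ctrl})$ per assay and comparison, with a
two-sided exact Mann-Whitney p-value at $\alpha = 0.01$ by default. The
test (`mann_whitney_exact()`) assigns mid-ranks to ties and computes the
exact permutation distribution of $U$ by a subset-sum dynamic program over
doubled mid-ranks, which is exact for tied and untied data alike; the
two-sided p-value counts label assignments whose $|U - n_1 n_2/2|$ is at
least the observed one. Up to 12 observations per group are handled
exactly (the 9-vs-9 design enumerates $\binom{18}{9} = 48\,620$
assignments implicitly); beyond that the tie-corrected normal
approximation is used and flagged. Since a rank test is invariant under
monotone transforms, testing NRQ or log2 NRQ gives identical calls.

## Noise propagation in the synthetic model

The generator plants $Cq = \mathrm{baseline} - \log_E(q) +
\mathcal{N}(0, \sigma)$, the standard cycle-scale Gaussian error model.
With $E = 2$, each sample's log2 NRQ then carries noise
$\sigma\sqrt{1 + 1/3}$ — the $1/3$ term because the normalization factor
is the geometric mean of three equally noisy references — so the planted
log2 fold estimate over two conditions of $n$ samples each has standard
deviation $\sigma\sqrt{4/3}\sqrt{2/n}$. The recovery tests bound the
maximum error over 50 simulations by three such standard deviations; at
$\sigma = 0.15$, $n = 9$ that is $0.245$ log2 units.

# Co-expression clustering

`kmedians_cluster()` reproduces the MeV-style k-means-medians procedure:
random seeded partition into $k$ groups, then alternate (a) centers =
element-wise median of members and (b) reassignment of every profile to
the nearest center under Pearson correlation distance $d = 1 - r$, with
emptied clusters refilled by the profile farthest from its own center and
nearest-center ties resolved toward the lowest cluster index for
determinism. Defaults $k = 10$ and `max_iter = 50` follow the MeV KMC
defaults; $k$ is data-dependent and deliberately exposed as a
first-class argument.

One convergence rule is the package's own: element-wise medians minimize
summed $L_1$ distance, not summed Pearson distance, so a center update can
in rare cases raise the total within-cluster distance. The iteration
therefore stops — keeping the previous assignment — whenever a full
iteration would increase the objective. This makes the objective trace
non-increasing by construction, which the test suite asserts on every run,
and on tiny instances ($n \le 7$, $k \le 3$) the best objective over all
initial partitions provably equals the exhaustive-search optimum.

Zero-variance profiles are excluded up front with a warning (Pearson is
undefined for them, and undetectable genes are likewise absent from
published cluster figures). A degenerate zero-variance *center* — possible
only on pathological data — is treated as uncorrelated ($d = 1$) rather
than erroring mid-iteration. `consensus_over_restarts()` guards against
local optima: it keeps the restart with the lowest objective and reports
the mean pairwise adjusted Rand index across restarts as a stability
score.

The profile generator builds cluster archetypes as centered condition
indicators scaled by `separation`, which makes distinct archetypes
negatively correlated for any positive separation, and adds i.i.d.
Gaussian noise per member. Defaults (`separation = 4` log2 units,
`noise_sd = 0.5`, 10 conditions) emulate a strongly structured
organ/stress expression panel; at these settings a single seeded run
recovers the planted 9-cluster structure with ARI 1.

# miRNA target prediction

Duplexes are ungapped and antiparallel: miRNA position $i$ (1 = 5' end)
pairs with window position $L - i + 1$. Each position is classed `M`
(Watson-Crick), `W` (G:U wobble) or `X` (mismatch); the penalty is
$1.0\,\#X + 0.5\,\#W$. A window is accepted iff

* at most one mismatch within miRNA positions 1–9 (`SEED`),
* no mismatch at positions 10–11 (`SITE`),
* no run of more than two consecutive mismatches after position 11
  (`RUN`),
* total penalty $\le 2.5$, boundary inclusive (`PENALTY`).

Wobbles count as pairs for the positional rules but still cost 0.5 —
the psRNATarget-style convention implied by a 0–2.5 penalty range; a
`strict_site` flag additionally rejects wobbles at 10–11, since published
rule statements leave that case open. No seed-region penalty doubling is
applied: the 0–2.5 range is read as a plain sum. Only consecutive
mismatches after position 11 are constrained; non-consecutive totals are
left to the penalty threshold, which bounds them anyway.

The predicted cleavage coordinate is the transcript nucleotide paired with
miRNA position 10 — the 5' nucleotide of the 3' cleavage fragment, i.e.
exactly the position that RLM-RACE sequencing of the ligated fragment
observes. The built-in example miRNA is the conserved 21-nt miR397, which
targets laccase transcripts.

The target generator works backwards from the miRNA: given a per-position
pair-class string it chooses target nucleotides realizing exactly that
pattern (erroring when a wobble is requested at a position whose miRNA
base cannot wobble), embeds the window in random flanks, and redraws
flanks that would create additional accepted windows. Decoy transcripts
are verified to contain no window of penalty $\le 2.5$. An independent
brute-force oracle in the test helpers re-derives every window's classes,
penalty and rule verdict from scratch.

# RACE cleavage validation

`map_fragments()` matches each adaptor-trimmed fragment by exact
full-length substring search; a fragment counts only if it occurs exactly
once across the transcript set (multi-locus fragments are ambiguous,
absent ones unmapped, and mapped + ambiguous + unmapped always equals the
input count). Exact matching is appropriate for Sanger-sequenced clones
mapped back to their own reference transcripts. `confirm_cleavage()`
reports the classic "$x/y$" statistic — clones whose 5' end falls exactly
on the predicted cleavage position over total clones for that transcript —
and makes an advisory VALIDATED call at `min_clones = 2`; the fraction,
not the call, is the primary output, since published figures report raw
fractions without a stated cutoff. Counting is positionally strict: the
tests shift all fragments by one nucleotide and require the at-site count
to collapse.

# Promoter motif scanning

Proximal promoters are anchored at the annotated translation start: 500 bp
immediately upstream of the CDS start (strand-aware, reverse-complemented
for minus-strand genes, truncated with a warning at scaffold edges). The
ATG anchor is the only reproducible choice when UTR/TSS annotation is
unavailable. Two degenerate MYB consensus elements are built in: MBS
`YAACWAMC` ((C/T)AAC(A/T)A(A/C)C) and MBSIIG/SMRE `YACCWAMC`
((C/T)ACC(A/T)A(A/C)C), each expanding to exactly 8 concrete words.
Both strands are scanned (minus-strand hits via the reverse complement of
the consensus, reported at their 5'-most plus coordinate), every
overlapping occurrence is kept, and positions are emitted both
promoter-local (1-based) and anchor-relative ($-500$ to $-8$), since
published position tables rarely state their convention. On uniform
background each motif matches a given position on one strand with
probability $8/4^8 = 2^{-13}$; the suite checks observed counts on
megabase-scale simulated sequence against this closed form within five
binomial standard deviations.

# Candidate prioritization

`call_candidates()` encodes the selection logic of the expression screen:
a gene is *bona fide* when all three lignin contrasts — stem vs leaf,
root vs leaf, inner (xylem-rich) vs outer (bast-fiber-rich) stem tissue —
are up at least `min_lfc` (default 1 log2 unit, an explicit, configurable
stand-in for the qualitative "several-fold higher" reasoning of such
screens) with Mann-Whitney $p < 0.01$. The IT/OT gate is what excludes
hypolignified-tissue genes that are stem-enriched but fiber- rather than
xylem-expressed. Co-clustering with the other candidates and MBSIIG
promoter presence are reported as corroborating evidence only; phylogenetic
placement can be supplied as an optional boolean column but is never
computed here. The gate is monotone: raising `min_lfc` or lowering
`alpha` can only remove candidates.

# Synthetic data: what it does and does not emulate

The generators are first-class, tested code and define the study
conditions: uniform-ACGT genomic background (under which accidental motif
or target matches are rare and computable, and all are scan-verified and
recorded in the manifest); planted fold changes with cycle-scale Gaussian
Cq noise (default $\sigma = 0.15$ cycles) and flat reference genes;
RACE reads as exact substrings concentrated at the planted cleavage
position; anti-correlated cluster archetypes. Identical seeds give
byte-identical outputs; all stage randomness derives from one root seed
through named substreams.

They do not emulate: non-uniform base composition or repeats, primer
cross-hybridization between close paralogs, inter-run calibration drift,
sequencing errors in RACE clones, bulged/gapped miRNA duplexes, or
stress-response time courses. Passing the planting contracts therefore
demonstrates correctness of the computations, not robustness to every
artefact of real data.

# Problem sizes and determinism

The shipped test and acceptance runs use deliberately compact sizes —
around 50 transcripts × 3 random miRNAs for the duplex oracle comparison,
$10^5$ bases for the motif oracle and ~$2\times10^6$ bases ($8\times10^6$
scanned motif-strand positions) for the background-rate check, 50
simulation seeds for fold-change recovery, 54 genes × 10 conditions for
cluster recovery, and a 15-assay × 5-condition cohort for the end-to-end
run — chosen so the full suite completes in a couple of minutes on a
single core while keeping every statistical check well-powered. The
end-to-end pipeline (`run_all()`) writes every intermediate as plain text
with md5 checksums and is byte-reproducible under a fixed seed.

# Known limitations

* The exact Mann-Whitney switches to a normal approximation above 12
  observations per group; tied extreme cases at those sizes are
  approximate (and flagged).
* k selection is not automated (no gap statistic or silhouette); $k$ is
  an explicit argument because published "default parameter" clusterings
  are not recoverable from text descriptions.
* Target prediction is ungapped by design; bulged sites are out of scope.
* RACE mapping is exact-match; a mismatch tolerance for real Sanger data
  is available but defaults off.
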