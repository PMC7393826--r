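---
title: "Reconstructing complex germline rearrangements from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complex germline rearrangements from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rearrangekit)
```

## The problem and the model

A germline structural rearrangement — however complex — obeys one simple
rule: every part of the derived (patient) sequence descends from a unique
part of an ancestral sequence, up to non-templated insertions.  Treating
the reference genome as a stand-in for the ancestor (false, but workable),
a long DNA read from a rearranged chromosome can be divided into parts,
each aligning to its own reference locus, strand, and order.  The novel
adjacencies between consecutive parts are *junctions*, described by two
*breakends* (a reference position plus the direction in which retained
sequence continues).  `rearrangekit` finds these junctions, filters the
benign and artifactual ones, and then solves the inverse problem: ordering
and orienting the surviving read groups into a minimal number of
derivative chromosomes.

The pipeline is staged exactly as its operations are exported:

1. **Error model** (`count_alignment_events`, `estimate_error_model`,
   `log_odds_scores`): substitution and affine indel rates between reads
   and genome are learned from alignments and converted to integer
   log-odds scores.  Deletions and insertions are parameterized
   separately because nanopore data shows a clear asymmetry.  The default
   pseudocount is 0.5 (a Jeffreys-style smoother: it prevents infinite
   log-odds without overwhelming small samples).
2. **Split alignment** (`find_candidate_alignments`, `split_read`,
   `estimate_mismap`): a seed-and-extend local aligner (exact k-mer seeds,
   banded affine extension) generates candidate alignments; a dynamic
   program over read positions chooses the most-likely division of the
   read, charging `jump_penalty` per additional part; a softmax over
   near-equal candidates yields a per-segment mismap probability, which is
   high exactly when part of a read fits several loci almost equally well
   (segmental duplications, retrotransposons).
3. **Junctions, subtraction, corroboration, grouping**
   (`extract_junctions`, `subtract_controls`, `require_corroboration`,
   `group_reads`): junctions are emitted for chromosome changes, strand
   switches, backward jumps, and forward gaps of at least `min_gap`;
   case reads sharing any junction with any control read are discarded;
   reads whose junctions are not seen in at least one other read are
   discarded as sporadic artifacts; the rest are grouped by the
   share-a-junction relation and groups of fewer than `min_group` reads
   are dropped.
4. **Consensus** (`merge_group`, `consensus_chain`): each group is merged
   by star alignment to a backbone read with weighted plurality calling,
   then refined by re-aligning the reads to the draft consensus; the
   consensus is split-aligned back to the reference, which tightens
   breakpoints to about a base.
5. **Parsimony linking** (`build_chain`, `link_chains`,
   `report_loss_gain`): each group's consensus becomes a chain of
   oriented reference segments with two free ends; chains are joined
   end-to-end into the smallest possible number of linear chromosomes.
   Sequence losses and gains are computed from the coverage of the
   reference by the final derivatives — losses in particular are
   *emergent*: invisible in any single group, certain once the whole
   rearrangement is assembled.
6. **Classification** (`classify_group`, `annotate_insertion_source`,
   `summarize_rearrangements`, `dotplot_data`): a small set of geometric
   rules names each group (tandem multiplication, deletion, inversion,
   non-tandem duplication, insertion from elsewhere, translocation,
   complex), with optional annotation-driven subtypes (repeat families,
   NUMT, processed pseudogenes).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_gap` | 10,000 bp | colinear forward gaps below this are ignored (plain small deletions are not "rearrangements"); 100 bp is the supported sensitive setting.  The threshold applies only to forward gaps: backward jumps (duplications) of any size are always reported. |
| `tol` | 2,000 bp | breakend tolerance when deciding whether two junctions describe the same rearrangement; absorbs alignment jitter at noisy read ends. |
| `min_support` | 2 reads | corroboration: every junction of a kept read must recur in at least one other read. |
| `min_group` | 3 reads | groups smaller than this are discarded as artifacts. |
| `max_mismap` | 0.5 | segments more likely misplaced than not are excluded from junction extraction. |
| `jump_penalty` | 30 score units | cost of an additional read part in the division DP. |
| `pseudocount` | 0.5 | smoothing for rate estimation. |

`tol`, the corroboration thresholds, and the grouping minimum follow the
method's published settings; the mismap cutoff of 0.5 is this package's
own default (the original does not state one), chosen as the point where
an alignment is more likely wrong than right.

## Design choices where the design was open

* **Read-level subtraction.**  A case read sharing *any* junction with
  *any* control read is dropped whole.  Ideally whole rearrangements
  would be dropped instead, but rearrangements have not been resolved at
  that stage; the `per-junction` mode of `require_corroboration` exposes
  the milder alternative for the corroboration step.
* **Junction equivalence, not fragment overlap.**  "Two rearranged
  fragments in common" is operationalized as junction equality within
  `tol`: agreeing on a junction implies agreeing on both flanking
  fragments, and a position tolerance absorbs end noise.
* **Star consensus instead of a partition-function multiple alignment.**
  The published pipeline uses lamassemble; this package merges each group
  by star alignment to a backbone read plus one refinement round.  The
  fidelity target is breakpoint accuracy (about a base after consensus
  re-alignment), not sequence-identity parity with lamassemble.  Column
  weights are `1 - p(error)` under the error model; gap-winning columns
  are deleted; ties keep the backbone base; insertions need more than
  half of the covering reads to agree.
* **Joinability rule of the linker.**  Two free ends may be joined only
  if they face each other on one chromosome with no other free end and no
  breakend of any chain strictly inside the connecting interval — a
  breakend in between would belong to the same derivative and must be
  linked through, not jumped over.  This rule is what makes realistic
  multi-group reconstructions unique.  Parsimony counts linear
  chromosomes only; copy number is deliberately not part of the
  objective, which restricts the method to germline (copy-balanced)
  genomes.  Optimal solutions are counted after canonicalization
  (derivative orientation and order); `unique = FALSE` means full
  characterization failed even though a reconstruction is returned.
  Self-joinable chains (rings) are reported and excluded, since the
  target is linear chromosomes.
* **Ties everywhere are broken deterministically** (fewer segments, then
  lexicographic order), so identical inputs give byte-identical output.

## The simulator and what it does (not) show

All tests and worked examples run on synthetic data, because the method's
inputs are whole-genome patient read sets that cannot ship with a
package.  `make_reference` draws i.i.d. bases (optionally with planted
exact repeats to stress mismap estimation); `apply_rearrangements`
applies deletions, inversions, tandem multiplications, copy-insertions
with target-site deletions, reciprocal translocations, and chromothripsis
(shatter, drop, permute, re-orient) while recording exact truth —
derivative structures, canonical junctions, and per-read source
intervals.  `simulate_reads` draws uniform starts, truncated log-normal
lengths, both strands, and errors from the error model (default: 5%
substitutions, 2%/1.2% deletion/insertion opens, 0.25 extension — about
10% total, nanopore-like).

Two anchored scenarios reproduce published worked examples at desk scale:

* `scenario_patient3()` builds five chromosomes whose derivative
  structure has 5 derivative chromosomes, 23 segments, and 18 junctions
  (a reciprocal translocation pair with inserted fragment runs, a second
  translocation, and an interleaved 11-segment derivative), decomposed
  into 15 truth chains whose linkage is unique.  Fragment sizes are in
  units of 1 kb times `scale`; reads default to 8 kb mean at 10x
  coverage, so every junction is covered by more than 6 reads.  At this
  scale read groups merge adjacent junction clusters (quiet intervals
  between chains are shorter than a read), so the 15-group decomposition
  is a property of the truth chains, not of the simulated read groups —
  the published group count arises from megabase-scale separations that
  would make the examples hours-slow to simulate.  The internal chr4
  deletion is 6 kb, so sequence-level runs use `min_gap = 100` (the
  sensitive setting) to see it.
* `scenario_chr11()` reproduces a three-chain single-chromosome topology
  whose unique linkage yields one linear derivative with three emergent
  losses; with `absolute_coords = TRUE` the chains carry the published
  chromosome-scale coordinates (treated as 1-based inclusive and
  converted to 0-based half-open), giving losses of 51,591, 17,337, and
  10,758 bp — printed as 51, 17, and 10 kb (floored).  The internal
  fragment layout between the fixed loss boundaries is this package's
  own synthetic construction.

What passing these tests shows: the geometry, filtering logic, parsimony
optimum, and breakpoint arithmetic are correct, and consensus breakpoints
are base-accurate under nanopore-like i.i.d. errors.  What they do not
show: performance on real base-caller error profiles (homopolymer
biases, context-dependent errors), centromeric/satellite breakpoints
(alignments there are low-confidence and filtered, as in the original),
or aneuploid cancer genomes (out of scope by design).

## Numerical choices and degenerate inputs

* Alignment uses integer log-odds scores (about 0.32 bits/unit by
  default, diagonal +6); the banded extension pads seed clusters by
  350 bp and the band by 60 diagonals (several times the expected indel
  diagonal drift of an 8-kb nanopore read); consensus bands double on
  edge hits up to 1,600.  Seed clusters need at least two exact 13-mers,
  which suppresses chance hits (about one per 10 kb of read against a
  0.3-Mb reference).
* The division DP may split one candidate around an error burst when the
  jump penalty is cheaper than the indel cost; the resulting colinear
  micro-gapped adjacencies emit no junctions and are harmless downstream.
* Junction canonicalization orders breakends by (chrom, pos, direction);
  matching also checks the swapped pairing, so reads traversing a
  junction in opposite directions agree.
* Empty inputs are legal everywhere downstream of parsing: zero
  candidates give an empty alignment, zero junctions give zero groups,
  and a single chain links to a single derivative.
* Random-sequence junctions carry occasional 1-2 bp microhomology, which
  makes breakend positions intrinsically ambiguous by that amount; this
  is why consensus breakpoints are validated as "about a base", not
  exact.

## Problem sizes used in the checks

The shipped checks run the five-chromosome scenario at `scale = 1`
(0.32 Mb reference, about 320 reads of 8 kb at 10x derived coverage,
five replicate seeds for the breakpoint-precision estimate), parameter
recovery on 0.2-0.3 Mb of simulated alignment columns, and exhaustive
oracle batteries on instances small enough to enumerate (divisions of a
9-position read among 3 candidates; matchings of up to 6 chains).  These
sizes keep the whole suite desk-scale while leaving every algorithmic
path exercised.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sc <- scenario_patient3(seed = 1)                    # genome + noisy reads
pl <- run_pipeline(sc$reads, sc$genome, min_gap = 100)
length(pl$groups)                                    # read groups found
pl$reconstruction                                    # linked derivatives
pl$loss_gain$losses                                  # emergent losses
types <- lapply(pl$consensus, function(cc)
  classify_group(build_chain(cc)))
summarize_rearrangements(types)
```

A chain-level run of the same topology (seconds, no reads):

```{r chains}
sc <- scenario_patient3(with_reads = FALSE)
res <- link_chains(sc$truth$chains, sc$chrom_lengths)
res
n_junctions(res)
```

## Known limitations

* The aligner is didactic: exact seeds plus banded extension.  It is
  adequate for desk-scale references; for real genomes, import MAF from a
  production long-read aligner via `read_maf()` — the rest of the
  pipeline is aligner-agnostic.
* Consensus quality degrades for groups whose reads barely overlap the
  backbone; reads sharing no seed with the backbone are excluded with a
  warning rather than assembled.
* The linker's exhaustive search is exponential in the number of
  *ambiguous* joins; published-scale inputs (tens of chains, mostly
  forced joins) are instantaneous, but adversarial inputs with many
  interchangeable ends are not the target.
* Breakpoint microhomology is reported only as non-templated insertion
  length per junction; sequence-context classification (blunt versus
  microhomology-mediated) is left to downstream analysis of the exported
  junctions.
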