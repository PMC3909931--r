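---
title: "Methods and design notes for txstratkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for txstratkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txstratkit)
```

txstratkit implements the analysis layer that sits between a de novo
transcriptome assembly and its biological interpretation: summary
statistics, saturation analysis, phylostratigraphy, ontology coverage,
gene-family recovery and pathway comparison. This vignette records how
each method works, the assumptions baked in, and the design choices made
where more than one defensible convention exists.

## Input model

All analyses run from plain-text files: FASTA contigs, a SAM alignment,
tab-separated homology hit tables (12-column BLAST tabular by default,
remappable via a column map), an OBO 1.2 ontology, and two-column
`contig_id → label` annotation tables. The SAM reader is minimal by
design: only QNAME, FLAG and RNAME are consumed, because the coverage
statistic needs nothing but per-contig aligned-read counts. Secondary
(0x100) and supplementary (0x800) records are excluded so each
sequencing read contributes at most once; this preserves
one-alignment-per-read semantics on inputs from aligners that report
more. CIGAR strings, positions and base qualities are ignored, and
BAM/CRAM are out of scope.

The OBO reader loads `is_a` edges only. Other relationship types
(`part_of`, `regulates`, ...) describe real biology but mix semantics
that a simple subtree-coverage tally should not traverse by default; an
allow-list argument (`relationships=`) admits them explicitly.
Acyclicity is verified at load time with igraph, and obsolete terms are
retained but flagged and stripped of edges so they can never contribute
to totals or recoveries.

Homology hits are E-value-filtered at read time (default 1e-3, the
conventional permissive cutoff for annotation screens). Whether such a
cutoff should apply to raw or database-size-adjusted E-values is a
judgment call that depends on how the searches were run, so the
threshold is an explicit parameter of `read_hits()` rather than a
constant. Downstream, the phylostratigraphy module sees only
presence/absence per bin — filtering belongs at the boundary, once.

## Assembly statistics

`n50()` uses the ≥ convention: sort lengths descending, accumulate, and
return the length at which the running sum first reaches half the total;
an exact half-total hit counts. This is the most common convention and
makes N50 always equal to the length of some actual contig. Histogram
bins are closed-open `[lower, upper)` with a closed last bin, stated so
counts are bit-reproducible across runs. The no-hit length profile
(`hit_rate_by_length()`) reports the fraction of no-hit contigs falling
in a caller-named bin; when every contig has a hit this fraction is
reported as `NA`, not zero — an undefined ratio should not masquerade as
a measurement.

## Saturation analysis

The subsampling pool is *all* sequencing records, aligned and unaligned
alike, because sequencing depth on the curve's x-axis means total reads
produced, not reads that happened to align. Reads are assumed
fixed-length (the 40 nt regime of early Illumina RNA-seq); mates of a
pair are counted as independent records. Nominal coverage
`r_i ℓ / L_i` is a depth proxy, not base-level coverage: it assumes
reads land roughly uniformly along the contig and will overstate
coverage for contigs with strong positional bias.

Replicate seeds are derived deterministically from the master seed and
the (subset size, replicate index) pair via a polynomial string hash
modulo 2^31 − 1, so any single point of a curve can be recomputed in
isolation and reruns are byte-identical. Subset sizes 0 and the full
pool are computed once (their replicates are necessarily identical) and
reported with sd 0. The sd is the sample standard deviation (n − 1
denominator) across replicates.

Two sampling paths exist. The reference path draws record indices
without replacement. The fast path draws per-contig aligned counts
directly from the equivalent multivariate hypergeometric (sequential
conditional univariate draws); it is distributionally identical — the
test suite compares the two paths' replicate means — and preferable when
pools reach tens of millions of records. The marginal distribution of
any contig's sampled count is hypergeometric, which yields the
closed-form expected fraction of contigs above threshold; the suite
checks Monte-Carlo means against this expectation within three standard
errors at 1,000 replicates.

## Phylostratigraphy

A `lineage_model` orders taxonomic bins from the closest relative of the
focal species outward and maps each to an ancestral-branch label.
Assignment is deepest-hit-wins: one hit in a distal bin sets the origin,
which is what a nested-search design implies — the method cannot
distinguish a single spurious distal hit from a genuinely ancient gene,
and the contamination flag exists precisely to mark the suspicious
subset of such patterns. The flag fires when the deepest hit bin is in a
configurable distal set (default: the prokaryote bins plus viruses) and
*no* hit exists in any configurable intermediate bin (default: the
eukaryote bins between the cnidarian bins and the prokaryotes). It is
advisory and never reassigns an origin: a distal-only pattern
*probably* indicates contamination, but removing those contigs is the
analyst's decision.

Three conventions worth stating:

* **Viruses are out-of-lineage.** A virus bin is not an ancestor on the
  descent path, so virus-only contigs get their own category
  (`out_of_lineage_only`) rather than a stratum, and virus hits are
  ignored entirely whenever any in-lineage hit exists. How contigs
  hitting both viruses and cellular bins should be classed is genuinely
  underdetermined; ignoring the virus hits in that case is the choice
  here, documented rather than hidden.
* **Archaea and Eubacteria carry distinct ancestor labels by default**
  ("ancestor of Archaea + Eukaryota", "ancestor of Eubacteria +
  Eukaryota"), with `merge_prokaryote_ancestors = TRUE` collapsing both
  onto a single cellular-ancestor label for summaries that pool the
  deepest strata.
* **Percentages are over hit-producing contigs.** Contigs with no hits
  carry no origin signal and belong in the denominator of nothing; the
  `out_of_lineage_only` class is included as its own row so stratum
  percentages always sum to 100.

## GO subtree coverage

The counting unit is the genuinely ambiguous design point. Reports of
this kind sometimes count *subcategories* (direct children of a
top-level term, with recovery propagated up from anywhere in the
child's subtree) and sometimes count *terms* (every subtree term,
recovered only if directly annotated). Both are implemented — modes
`"children"` (default) and `"terms"` — and the ambiguity is documented
rather than resolved; the children mode is the default because
subcategory totals in published two-species comparisons are small
integers consistent with child counts, not subtree sizes.

Annotations to the start term itself belong to no child unit and are
logged separately (`n_at_start`). Multi-parent terms may be counted
under multiple subcategories — no deduplication, since such a term
genuinely belongs to both. In the two-species comparison
(`compare_species()`), a subcategory is classified as recovered for a
species when the subcategory term or anything below it carries a direct
annotation; this matters for leaf subcategories, which have no child
units yet are recoverable in their own right.

## Gene family recovery

The protocol is the standard reciprocal-search design: forward
translated search from each reference protein, top-k candidate retention
(default k = 10), reverse search of each candidate against the full
reference set, verification iff the reciprocal best hit is the original
query. The strict top-1 criterion is the default; `relaxed = TRUE`
accepts any member of the query's declared family, which is the
appropriate reading when paralogs within a family are expected to
cross-rank.

The built-in backend makes the protocol self-contained: six-frame
translation (standard genetic code, ambiguous codons → X, stops kept as
`*`) followed by Smith–Waterman local alignment with affine gaps,
implemented in C++ with a traceback for span coordinates. Scoring
defaults are the protein-search conventions — BLOSUM62, gap open 11,
extend 1, a gap of length L costing 11 + L. Two deliberate deviations
from stock BLOSUM62: the stop symbol is re-scored to the matrix minimum
against everything (stock BLOSUM62 gives `*`/`*` a positive score, which
would let read-through alignments across stop codons win), and the
local-alignment score floors at 0, the empty alignment. E-values are not
computed: ranking is all the protocol needs, and raw scores rank.
Reciprocal ties break by score then lexicographic subject id, making
verdicts deterministic and order-independent.

`min_score` (default 50, raw score units) gates forward candidates. It
is a free parameter with no principled universal value — lower it to
chase weaker family members, raise it to cut noise; at BLOSUM62 scales,
50 roughly corresponds to a short confident local match.

## EC pathway comparison

EC normalisation strips an optional `EC:` prefix and pads partial
numbers to four fields with `-` (`1.2.3` → `1.2.3.-`). Comparison is
exact string equality after normalisation: no hierarchical matching of
partial ECs against their children, because any such rule (does
`1.2.3.-` "match" `1.2.3.4`?) embeds an interpretive decision that
should be the analyst's. The iPath selection dialect is
`<EC> <#RRGGBB> W<width>` with shared → green (#00ff00), reference-only
→ red (#ff0000), focal-only → yellow (#ffff00), width 10; ECs absent
from both sets are omitted and render in the viewer's default colours.
The emitted lines parse back losslessly (`parse_ipath_edgelist()`),
which the tests use as a round-trip check.

## The synthetic-data generators

Every generator is a pure function of its seed and emulates exactly the
statistical structure the corresponding analysis assumes:

* `gen_transcriptome()` — random-composition contigs, a stated fraction
  carrying an embedded ORF (ATG + ≥ 30 stop-free codons + stop) at a
  recorded forward-frame position.
* `gen_reads()` — fixed-length records, aligned ones landing on contigs
  with probability proportional to length (the uniform-sampling
  expectation), a stated fraction unaligned, true counts returned.
* `gen_hit_tables()` — each contig draws a true stratum and receives
  hits in its deepest bin *and every closer bin* (the consistent nested
  pattern of a real ancient gene); contaminants instead receive hits
  only in distal bins. Out-of-lineage bins are used only by the
  contamination channel, so in generated data the flagged set and the
  injected set coincide exactly — which is what makes exact-recovery
  testing possible.
* `gen_ontology()` — random DAGs with edges only from later to earlier
  terms (acyclic by construction), up to a stated number of parents.
* `gen_families()` — orthologs planted by protein-level point
  substitution to a stated identity, reverse-translated with uniformly
  random synonymous codons (identity is enforced where the translated
  search sees it), embedded at random offset and strand among random
  decoy contigs.

What the generators deliberately do not emulate: sequencing error and
quality strings, paired-end structure, positional read bias, homology
detection failure as a function of divergence, polymorphism, or real GO
term semantics. Passing tests therefore demonstrate that the algorithms
are correct on data satisfying their assumptions — not that those
assumptions hold for any particular real library. In particular, 100%
stratum recovery on fixtures reflects the generator's consistency, not
an expected field performance.

## Numerical and testing choices

Stochastic assertions use three Monte-Carlo standard errors at fixed
seeds throughout — tight enough to catch real defects, loose enough to
be stable across RNG streams. The Smith–Waterman kernel is checked two
independent ways: against exhaustive enumeration of every local
alignment (all start cells, all monotone extensions, affine gap states)
for short words over a 4-letter alphabet — enumeration is factorial, so
pairs are capped at combined length 11, which a desk machine enumerates
exactly in seconds — and against an established pairwise aligner under
identical scoring on longer peptides. Typical suite problem sizes
(1,000-gene hit tables, 100-node ontologies, 1,000-replicate saturation
runs on 20-contig pools, 5 families against 20 decoys) were chosen so
the statistical assertions have real power while the whole suite stays
interactive.

Degenerate inputs are contracts, not accidents: empty hit files parse to
empty collections; subset size 0 yields fraction 0 with sd 0; an empty
transcriptome yields a zero-candidate report; empty peptides score 0;
an all-hit contig set makes the no-hit fraction `NA`. Errors name the
offending entity (duplicate contig id, dangling ontology reference, line
number of a malformed record) because a toolkit meant for batch use
should fail diagnosably.

## Command-line layer

`txstratkit_main()` dispatches the seven subcommands and returns an exit
code (0 success, 1 input/module error with a one-line diagnostic, 2
usage error); the installed `inst/cli/txstratkit.R` wrapper is a
two-line shell around it. Every invocation writes a
`run_metadata.json` (subcommand, parameters, seed, toolkit version)
beside its outputs, and all randomness descends from the single
`--seed` flag through the documented (seed, purpose-string) derivation,
so deterministic subcommands rerun byte-identically.

## Known limitations

* Variable-length reads are unsupported in the saturation module; the
  nominal-coverage formula takes one global read length.
* The phylostratigraphic origin is only as good as the bin searches:
  database representation imbalances bias the deepest-hit rule, and the
  method inherits every limitation of homology detection at large
  divergences.
* The built-in search backend is O(mn) per alignment with no heuristic
  seeding; it is meant for desk-scale verification, not for searching
  millions of contigs — plug an external tool into the backend contract
  for that.
* Only `is_a` ontology edges participate by default; analyses that need
  `part_of` propagation must opt in and interpret the result
  accordingly.
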