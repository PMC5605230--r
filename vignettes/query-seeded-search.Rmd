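---
title: "Query-seeded iterative profile search: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-seeded iterative profile search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem: PSSM contamination by homologous over-extension

Iterative similarity searching alternates two steps: find statistically
significant homologs of a query, then build a position-specific scoring
matrix (PSSM) from their alignments and re-search with the profile. The
profile makes each round more sensitive — and more dangerous. When a genuine
homologous alignment extends past the end of the shared domain into adjacent,
non-homologous sequence ("homologous over-extension"), the over-extended
columns enter the next PSSM. In multi-domain proteins the adjacent sequence
is often another domain family, so the profile gradually *learns* a family
the query does not contain and starts reporting every carrier of that second
family. A single over-extension event can snowball into thousands of false
positives within a few iterations.

`seedsearch` implements the counter-measure of seeding query residues into
alignment gaps, together with the machinery needed to study it: local
alignment kernels, query-anchored MSA construction, PSSM estimation,
empirical E-value calibration, alignment-boundary control, an
embedded-domain benchmark, and a synthetic protein-family generator.

## The iteration cycle

`psisearch()` is the package's central fitting function:

1. **Iteration 1** — Smith–Waterman search of the query against every
   database sequence (BLOSUM62, gap open 11, gap extend 1; a gap of length
   $k$ costs $11 + k$). E-values use the published Karlin–Altschul gapped
   constants for this scoring system ($\lambda = 0.267$, $K = 0.041$),
   $E = K m n e^{-\lambda S}$.
2. **Selection** — hits with $E \le$ the inclusion threshold (default
   0.002) enter the model; per subject only the best-scoring alignment is
   kept. A more stringent threshold (0.0001) is available and propagates
   from the CLI flag `--evalue`.
3. **Boundary policy** — `current` keeps alignments as found; `history`
   clips each alignment to the span recorded the first time that subject
   was significant (a write-once registry); `domain` clips to the annotated
   query region with the highest sub-alignment score density.
4. **Query-anchored MSA** — columns are exactly the query positions; the
   query itself is always row 1. Subject residues aligned to query-gap
   columns (query-side insertions) are deleted from the row and recorded in
   row metadata; unaligned flanks are end gaps.
5. **Gap fill (seeding)** — the package default replaces every gap column
   of every subject row, internal *and* end gaps, with the query residue of
   that column. Alternatives: `none`, `x_fill` (`X` characters), and
   `random_fill` (background-composition draws, seeded).
6. **PSSM construction and re-search** — the profile is built from the
   filled MSA (below) and aligned against the whole database with the same
   affine-gap kernel; E-values are re-calibrated on that search's empirical
   score distribution.

The loop stops at `n_iterations` (default 10) or earlier at a fixed point:
the included-subject set *and* every included alignment's boundaries are
unchanged between consecutive iterations. Membership alone is not a fixed
point — alignment boundaries can keep creeping outward at stable
membership, which is precisely the over-extension process under study — so
convergence requires both.

```{r}
library(seedsearch)
cb <- contamination_benchmark(seed = 1)
fit <- psisearch(cb$query$sequence, cb$db,
                 gapfill = gapfill_policy("query_seed"))
summary(fit)
```

## PSSM model

For each column $j$ of the (filled) MSA, with Henikoff position-based
sequence weights $w$ over rows:

* observed frequencies $f_a$: weighted counts of residue $a$ (gap and `X`
  cells excluded), normalized;
* effective count $n_\mathrm{eff}$: the number of distinct residue types in
  the column;
* pseudocount frequencies $g_a = \sum_b f_b\, q(a \mid b)$, with
  $q(a \mid b) \propto p_a 2^{s_{ab}/2}$ the conditional target
  frequencies implied by the BLOSUM62 half-bit scores $s_{ab}$ and the
  Robinson–Robinson background $p$;
* the blend $Q_a = (\alpha f_a + \beta g_a)/(\alpha + \beta)$ with
  $\alpha = n_\mathrm{eff} - 1$ and $\beta$ the pseudocount weight
  (default 10);
* scores $2 \log_2 (Q_a / p_a)$, i.e. half-bit units like BLOSUM62 itself,
  rounded to integers for searching, with the unrounded values retained.

A column with a single row (the query) therefore reduces to the BLOSUM62
row of the query residue, up to the matrix's own rounding, and the whole
construction is an ordinary data-dependent pseudocount scheme rather than a
bit-exact clone of any particular search program.

Why seeding works, in this model: a gap column filled with query residues
gains observed mass at the query residue, which raises both $f$ and $g$
there and concentrates $Q$. `relative_entropy()` measures the effect as the
per-column Kullback–Leibler divergence of $Q$ from $p$ in bits; seeded
profiles built from gappy MSAs are never less informative than their
unseeded counterparts, which keeps sparsely observed columns anchored to
the query instead of to whatever single over-extended subject happens to
cover them.

## E-value calibration

Iterations after the first score with a profile, so no published constants
apply. `fit_evd()` fits a Gumbel law to the per-sequence best raw scores of
the search by maximum likelihood, then iteratively censors the homolog tail
(scores whose fitted $E < 1$) and refits, at most five rounds. Because a
heavy homolog tail can inflate the initial scale estimate so far that the
censor never engages, the *first* fit uses a robust pre-trim (scores at most
median $+\,5\cdot$MAD); the censor rounds always operate on the full score
set. $\lambda$ is the reciprocal fitted scale; $K$ follows from the fitted
location via $e^{\mu/\beta} = K m \bar n$ with $\bar n$ the mean subject
length. Constant score vectors are a fit error, and the driver falls back to
the previous iteration's parameters.

On 10,000 scores simulated from a known Gumbel, the fitted $\lambda$ is
within 5% of truth (typically well under 1%); the package asserts this in
its test suite.

## Sub-alignment scoring and boundary policies

`subalignment_scores()` walks an alignment column by column and charges each
column's contribution — substitution score, or gap penalty with the opening
cost charged to the gap run's first column — to the annotated region
containing it; the partition sums to the raw score exactly. Over-extended
segments betray themselves by low score density (score per column), which is
what the `domain` boundary policy maximizes when choosing the region to keep.
The `history` policy instead freezes, per subject, the first significant
alignment's span in a write-once registry and clips later alignments to it;
an empty clip excludes the hit from that iteration's MSA (reported, not
fatal).

## The benchmark

`make_embedded_query()` implements the embedded-domain evaluation design: a
domain of length $L$ flanked by $\lfloor L/2 \rfloor$ random residues on
each side (a 200-residue domain gives a 400-residue query with the domain
at 101..300). Flanks are random, so *any* alignment outside the domain
interval is non-homologous by construction. `classify_hit()` scores a
reported alignment as a true positive only if its query span overlaps the
embedded domain and the subject residues aligned to that overlap (via the
BTOP walk) overlap a subject annotation of the same family or clan;
everything else — including same-family alignments out in the flanks — is a
false positive. For full-length queries, alignments outside the scored
domain interval are ignored rather than counted. The minimum overlap is one
residue on each side by default (`min_overlap` raises it).

`evaluate_run()` aggregates per-query sensitivity $TP/(TP+FN)$ and FDR
$FP/(TP+FP)$ (0 when no hits) with equal per-query weight.
`overextension_stats()` is the median count of aligned query positions
outside the domain interval; `identity_q1()` the first quartile (linear
interpolation between order statistics — the estimator is declared here
because quartile conventions differ) of percent identity, both over
alignments with $E < 0.001$.

## The synthetic generator

`generate_database()` builds protein families with known ground truth: one
random ancestor per domain, members derived by BLOSUM62-exchangeability
point substitutions plus occasional indels (rate 0.01 per residue,
geometric lengths of mean 2), assembled into architectures with random
linkers, every domain instance annotated exactly. Because local alignment
trims mismatch-dense ends and thereby reports slightly higher identity than
the substitution count implies, each instance is calibrated by a
measure-and-correct loop against the package's own aligner until its
realized identity lands on the target (the contract is target $\pm 2\%$). A
length-2 identity target is a diversity range; members spread uniformly
across it, like the member spread of a real family.

`contamination_benchmark()` is the package's standard contamination
scenario: family A alone (30 sequences), A fused directly to family B (30 —
no linker, so over-extension past A lands in B), B alone (30, the decoy
set), and 200 unannotated random sequences; the query is an embedded,
N-terminally truncated distant A instance. Random sequence here uses the
Robinson–Robinson composition rather than the generator's uniform default:
BLOSUM62 is a log-odds matrix against real amino-acid frequencies, and
uniform flanks make chance matches of rare residues (W, C) several-fold too
likely, producing over-extension so aggressive that no construction scheme
contains it. Family identities (A: 35–75% range to the ancestor, B: 50–80%,
query at 50%) emulate the far-homolog regime in which iteration 1 finds
only part of the family and coverage grows over iterations.

What the generator does *not* emulate: tree-structured evolution (members
are independent draws around one ancestor), composition bias and
low-complexity regions, length variation beyond small indels, and
overlapping or nested domain annotations. Passing tests therefore show that
the machinery behaves as designed under idealized family structure, not
that the measured FDR values transfer to real databases.

## Numerical and design choices

* Alphabet: 20 standard residues plus `X`; `X` scores come from the
  matrix's `X` row in sequence searches and a flat −1 in profile searches;
  seeding never emits `X` unless `x_fill` is selected.
* External coordinates are 1-based inclusive everywhere on disk; internal
  conversions are centralized in the readers/writers.
* Traceback ties prefer diagonal, then gap-in-subject, then gap-in-query;
  the best cell is the first maximum in row-major scan order. Results are
  therefore bit-reproducible, and re-running any fit with the same seeds
  and inputs reproduces identical outputs.
* One alignment (the best-scoring HSP) per query–subject pair per
  iteration.
* BTOP is the canonical alignment encoding: match-run integers merged
  maximally, zero-length runs tolerated on input but never emitted.
* All-gap PSSM columns (impossible with the query row present, but
  reachable through the API) fall back to the substitution-matrix row of
  the query residue.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at sizes
a single core handles in minutes: databases of 90–290 sequences
(25,000–65,000 residues), queries of 60–400 residues, 10 iterations, five
replicate fixtures. The kernels are written in C++ and scale as the product
of query length, database residues, and iteration count; the design imposes
no further limits beyond memory for the hit lists.

## Limitations

* E-values are calibrated empirically per iteration; they are comparable
  within a run but not bit-compatible with any external program's E-values.
* The PSSM scheme is a standard pseudocount construction, not a
  reproduction of a specific tool's matrices; absolute profile scores
  differ even where the qualitative behavior matches.
* `random_fill` draws from a single global composition; it does not model
  position-specific background.
* The benchmark classifies at domain granularity; partially overlapping
  annotations on the same subject are resolved by the first matching
  region, and unannotated subjects count as false positives by definition.
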