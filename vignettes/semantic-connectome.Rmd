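---
title: "A semantic-network model of the connectome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semantic-network model of the connectome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomekb)
```

## The knowledge model

`connectomekb` stores brain data as a typed, directed semantic network.
Five static *object kinds* — ELEMENT, CONTEXT, EXPERIMENT, ONTOLOGY,
ANNOTATION — are the closed templates from which dynamic *object types*
(patient, measured brain coordinates, probe, an atlas, an ontology) are
derived at run time. Instances are keyed case-sensitively by
(type, identifier); free-text labels are matched case-insensitively in
queries, because anatomical labels vary in capitalization across sources.

*Relation classes* define directed links with a forward and a backward
traversal label ("connects to" / "is connected from"). Both labels must be
globally unique so that a label resolves to exactly one class and
direction — this is what lets path queries be written purely in traversal
vocabulary. Relation identity is (class, source, target): repeated
`kb_relate()` calls are idempotent, since nothing in the domain calls for
parallel edges of one class. Sources may be relation instances (a
connection can be the subject of further statements); targets are always
object instances — we saw no need for relation-valued targets and restrict
them deliberately.

*Experiments* are the measurement store. An experiment method fixes a
subject spec — an object type (patient, probe, coordinate) or a relation
class — and one or more formats with attribute ranges: normalized
correlation values in [−1, 1], normalized fiber density and tracking
probability in [0, 1], absolute fiber density ≥ 0, expression level as a
real log-intensity value plus a PACall flag. A data entry holds one
format's values for one subject; multi-format methods store parallel
entries, since the formats have disjoint attribute sets. Missing
measurements are *absent entries*, never sentinels: the cross-modal join
must distinguish "no DTI edge" from "zero correlation".

## Connectivity import

A symmetric n×n matrix is stored as one canonical directed relation per
unordered coordinate pair, with the canonical direction chosen by
ascending coordinate identifier. Semantic relations are inherently
directed, but doubling symmetric edges would double every join count;
traversal works in both directions regardless. Asymmetric matrices keep
one relation per ordered pair. Symmetry is auto-detected (tolerance 1e-9
against the transpose) and can be declared explicitly.

Exact-zero cells follow a per-format default: kept for correlation formats
(zero correlation is information), dropped for fiber density and tracking
probability (zero means no tract). Diagonal cells are always dropped;
connections between *distinct* coordinates that happen to share an
anatomical label are retained — published joined tables contain such
self-labelled pairs. Coordinates use exact-match identity on MNI
millimetre positions: the pipeline joins on atlas-provided coordinate
tables, so no spatial tolerance or nearest-neighbour matching is needed or
offered.

## Queries

Queries are existential: an instance satisfies `q_related(label, nested)`
iff *some* relation with that label connects it to an endpoint satisfying
the nested condition. Every prose query we model is existential; universal
quantification is not provided. Negation and disjunction are included as
standard logic although the modelled query language only illustrates
conjunction — they are flagged as an extension. `q_type_is()` is likewise
an engine convenience: prose queries name object types ("… which is an
rs-fMRI experiment"), and the condition makes that test explicit.
`q_ontology_within()` — membership of a term in the is-a transitive
closure of a root — is the engine's only built-in inference. Results are
deduplicated and sorted by (type, identifier); availability tables expand
one row per binding of result instance and path endpoints, with an empty
cell when a path has no match.

Ontologies support DAGs (multiple is-a parents), not just trees, because
real anatomical ontologies are not strictly trees. Acyclicity is verified
at load time by Kahn's algorithm, naming a cycle member on failure.

## The cross-modal join

For each connectivity relation, both endpoint coordinates are resolved
along coordinate → atlas entry → brain structure → ontology term. Each
term is expanded to its descendant set (including itself, so a structure
with a direct DEG link and no sub-regions still joins), descendants are
mapped back to structures, and every unordered structure pair with a known
DEG count contributes once to the arithmetic mean — the only aggregation
that reproduces published fractional DEG averages such as 271.6666667 and
7.75 from integer counts. Without descendant expansion the join of
gross-scale connectivity against sub-region expression statistics is
empty, which is precisely why the expansion exists. Connections with a
broken mapping chain are skipped with a warning rather than an error
(curated mappings are never complete); connections with no matched DEG
link are excluded from the join output but remain available through
`extract_fbn()`.

Filters follow the printed inequalities exactly, with no epsilon:
`min_struct` and `min_func` are inclusive (≥), `max_deg` inclusive (≤),
`min_deg` strict (>). Functional classification uses closed bins:
CORRELATED iff f ≥ 0.5, ANTICORRELATED iff f < 0, UNCORRELATED between.
Records lacking a filtered field fail that filter.

## The synthetic generator

`generate_kb()` builds the complete study configuration without downloads:
21 regions by default (210 connection pairs — the scale at which trend
recovery is assessed), one coordinate each, a flat atlas, a two-level
ontology (root → region terms → two sub-region terms each), canonical
structures and mappings, and both connectivity modalities imported as
experiments. DEG links are created *only at sub-region level*, so the
cross-modal join genuinely exercises ontology descent.

Draws, all deterministic per seed:

* structural connectivity: Beta(2, 5) scaled to [0, 0.6] for background
  pairs; hub-region edges boosted by +0.35 (clipped at 0.95) so the hub
  has strictly maximal weighted degree; exception-region edges uniform on
  [0.15, 0.65] so they all clear the 0.1 structural threshold;
* functional connectivity: truncated normal (inverse-CDF, so no boundary
  atoms) around −0.25 + 1.4·s with sd 0.12 — above s ≈ 0.4 essentially
  only positive correlations remain, mimicking the empirical
  structure–function trend. Exception edges are overridden to weak
  positive values U(0.02, 0.33): anatomically strong but functionally
  quiet, the putamen phenomenology;
* DEG counts: rounded log-normal scaled by (1 − f), i.e.
  `exp(log 25 + log(1 − f) + ε)`. The noise sd follows the attenuation
  identity sd(ε) = sd(u)·sqrt(1/r² − 1) with u = log(1 − f), but r is
  first passed through a linear calibration (r_eff = 1.05·r + 0.32,
  capped at 0.995, fitted by simulation at 210 pairs) because truncation
  of u, integer rounding, the cap described next and the anti-trend
  exception edges each attenuate the realized rank correlation.
  Associations requested near −1 therefore saturate around the strongest
  realizable value rather than reaching −1;
* caps and the exception: non-exception pairs with structural ≥ 0.1 have
  their counts capped at 200 (high DEG co-occurs only with weak structural
  connectivity), and sub-region counts — jittered by ±15% around the pair
  draw — are capped again, so a DEG average above 200 at structural ≥ 0.1
  is exclusive to the exception region. Exception pairs draw counts on
  [550, 950], the scale of the published putamen rows.

What the generator does *not* emulate: anatomical geometry (coordinates
are uniform in an MNI-sized box), BOLD time series, distance-dependent
connectivity, probe-level noise structure, or the curation errors of real
atlas mappings. Tests passing on synthetic data therefore validate the
machinery — imports, closure, join, filters, statistics — not the
neurobiology of any particular data set.

`generate_expression_fixture()` plants listed genes above the
localization threshold (values in (8.3, 10.5), PACall 1) at one hotspot
structure; background draws are normal around 6.5 (sd 0.8) and any
background value exceeding 8 has its PACall flag cleared, modelling signal
not significantly above background. The ">8" expression threshold is
applied on the data's native (log-intensity) scale.

## Numerical and interface choices

* Thresholds in the CLI and `filter_connections()` are validated against
  their modality ranges ([0, 1] structural, [−1, 1] functional, ≥ 0 DEG);
  an out-of-range threshold is a data error (exit code 1), an unknown
  option a usage error (exit code 2).
* Serialization is a single JSON document with canonically sorted
  instances, relations, memberships and entries, so equal knowledge bases
  export byte-identically regardless of creation order, and a save → load
  → save cycle is the identity.
* Graph exports (GraphML via igraph, and a JSON node-link dialect) sort
  nodes by coordinate identifier and edges by endpoints, so re-export is
  byte-stable. Node attributes are x, y, z in MNI millimetres plus the
  anatomical label; edge attributes are width (structural value),
  color_value (functional or DEG average) and, for functional coloring,
  the category bin.
* Tie-breaks: query results by (type, identifier); tabulation rows by
  subject reference; the unordered/directed distinction for pair counts is
  reported explicitly by `fbn_pair_counts()` because either convention is
  defensible for symmetric data stored canonically.

## Problem sizes

The test suite and the acceptance script run at desk scale by design: 42
published records, random knowledge bases of at most ~20 instances ×
600 queries for the engine-vs-oracle comparison, 30-term random DAGs for
the closure oracle, and 21-region synthetic networks (210 pairs) for trend
recovery. These sizes were chosen so each property is exercised far from
trivially (hundreds of pairs, thousands of random probes) while any single
check stays near-instant.

## Known limitations

* No RDBMS or client/server tier: the store is in-memory with JSON
  import/export, sized for desk-scale integration work.
* No volumetric parcellation (NIfTI label images) or voxel-wise
  assignment; atlases are consumed as coordinate/label tables.
* Atlas-to-ontology mappings are consumed as curated "best match" tables
  and never inferred automatically — term similarity across atlases is a
  curation problem, not a string-matching one.
* Differential expression is consumed precomputed; the package does not
  compute DEG statistics from raw microarray intensities, nor probe
  QC/normalization.
* Query planning is hash-lookup only; no cost-based optimization. At the
  intended scale this is irrelevant.
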