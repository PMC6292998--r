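# connectomekb

Semantic knowledge base for multimodal connectome and transcriptome
integration in R.

## The problem

Macroscale brain connectivity is usually handled as bare n×n connectivity
matrices — one per modality, per atlas, per study — which makes it hard to
ask questions that cut across modalities ("which strongly connected region
pairs also differ strongly in gene expression?") or across naming systems
(Craddock200 entries vs. Allen Human Brain Atlas ontology terms).
`connectomekb` represents brain data as a **semantic network** instead:

* every measured MNI coordinate, atlas entry, ontology term, brain
  structure, probe and gene is a typed semantic object;
* every structural or functional connection is a typed, directed relation
  ("connects to" / "is connected from") between coordinate objects;
* experiments store subject-indexed measurements where the subject may
  itself be a *relation* — so a DTI or resting-state fMRI experiment keys
  its values by connection, not by subject;
* atlases, a canonical brain-structure repository and is-a ontologies are
  joined by parcellation ("belongs to"/"parcellates") and mapping
  ("maps to"/"is mapped by") relations.

On top of that sit an existential path-query engine (with ontology
transitive closure as its single built-in inference), a functional brain
network (FBN) template extractor, localized gene-expression filters
(expression value > 8 with PACall = 1, Allen microarray style), and a
cross-modal join that annotates every connection with the average number of
differentially expressed genes (DEG) over all ontology-descendant structure
pairs. Audience: researchers integrating connectivity matrices
(USC Multimodal Connectivity Database style) with region-pair
transcriptome statistics.

## Core model

For a connection between coordinates with resolved ontology terms *O* and
*T*, the DEG annotation is

    deg_avg(O, T) = mean { deg(a, b) : a ∈ S(desc(O)), b ∈ S(desc(T)),
                           deg(a, b) known }

where `desc` is the is-a transitive closure (including the term itself) and
`S` maps terms to canonical brain structures; unordered structure pairs are
counted once, and connections with no matched DEG link are excluded.
Functional connectivity values f ∈ [−1, 1] are classified with closed
bounds: CORRELATED (f ≥ 0.5), UNCORRELATED (0 ≤ f < 0.5), ANTICORRELATED
(f < 0). Threshold filters follow the printed inequalities: structural and
functional minima and the DEG maximum are inclusive, the DEG minimum is
strict (> 200).

## Worked example

The package ships the 42 published connection records (25 putamen high-DEG
rows, 8 strong-functional/high-DEG rows, 9 strong/similar-expression rows).
Filtering them for structurally (≥ 0.5) and functionally (≥ 0.5) connected
pairs with nearly homogeneous expression (DEG ≤ 10):

```r
library(connectomekb)
rec  <- paper_tables_fixture()
nine <- filter_connections(rec, min_struct = 0.5, min_func = 0.5, max_deg = 10)
nine[, c("origin", "target", "structural", "functional", "deg_avg")]
```

```
                         origin                         target structural functional deg_avg
  left superior parietal lobule  left superior parietal lobule  0.5586699  0.7111254    3.00
  left superior parietal lobule  left superior parietal lobule  0.5586699  0.7111254    3.00
       right cingulate anterior       right cingulate anterior  0.6055006  0.5399742    0.00
   right juxtapositional lobule       right cingulate anterior  0.5962138  0.7152773    7.75
       right cingulate anterior       right cingulate anterior  0.6055006  0.5399742    0.00
   right juxtapositional lobule      right cingulate posterior  0.5215521  0.5579472    0.50
       right cingulate anterior      right cingulate posterior  0.6317353  0.5860230    1.50
 right superior parietal lobule right superior parietal lobule  0.6957586  0.6887208    3.00
 right superior parietal lobule right superior parietal lobule  0.6957586  0.6887208    3.00
```

Exactly nine pairs survive — short-range connections whose endpoints barely
differ in gene expression. The duplicate-looking rows are real: distinct
coordinate pairs sharing anatomical labels.

The synthetic generator builds a complete knowledge base (coordinates,
atlas, two-level ontology, mappings, both connectivity modalities,
sub-region DEG links) with planted statistical structure:

```r
kb   <- generate_kb(synth_config(seed = 7))      # 21 regions, 210 pairs
join <- crossmodal_join(kb, ontology = "synthonto")
nrow(join)                                            # 210
cor(join$functional, join$deg_avg, method = "spearman")  # -0.648
surv <- filter_connections(join, min_struct = 0.1, min_deg = 200)
Reduce(intersect, lapply(seq_len(nrow(surv)), function(i)
  c(surv$origin[i], surv$target[i])))                 # "region 02"
```

The join recovers the planted negative association between functional
connectivity and differential expression, and the planted exception region
(high structural connectivity *and* high DEG, the putamen phenomenology) is
the unique region common to all strong-DEG survivors.

A thin command-line interface wraps the same functions
(`inst/scripts/connectomekb`): `simulate`, `import-matrix`,
`import-expression`, `import-deg`, `load-atlas`, `load-ontology`,
`map-atlas`, `query`, `fbn`, `xmodal`, `filter`, `export-lattice`,
`tables-fixture`; every output carries a JSON run manifest.

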