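# litcooc

Dictionary-based mining of protein–protein co-occurrences from
PubMed/MEDLINE abstract collections, for systems-biology network building.

## The problem

Most described molecular interactions live in free text. A practical way to
seed or enrich an interaction network for an organism or a topic is to scan
every available abstract for pairs of protein/gene names mentioned
together, graded by how strongly the sentence suggests a real relation.
litcooc implements that pipeline end to end, self-contained and offline:

- **parse** NCBI-PubMed / MEDLINE XML into sentence-segmented records
  (PMID, title, abstract);
- **tag** bioentity names, biointeraction trigger terms and concept terms
  against fully in-memory lexicons (a single TSV "DB file" per run), or
  import an external tagger's output in a documented TSV interchange
  format;
- **classify** every co-mentioned pair of distinct protein/gene names into
  a reliability type:
  - type 1 — same sentence, exact trigger **between** the names,
  - type 2 — same sentence, exact trigger anywhere,
  - type 3 — same sentence, trigger matched only permissively (by stem),
  - type 4 — same abstract only
  (lower type = more likely a real interaction; curation still advised);
- **filter** by NCBI taxonomy id (e.g. 3847 = *Glycine max*) and by type;
- **report** summaries with absolute and non-redundant counts, a
  term-to-co-occurrence "extra section", and "poorly described" flags
  (items seen once or twice);
- **export** weighted co-occurrence networks (SIF, TSV, GraphML);
- **scale** by sharding input files across forked workers — output is
  byte-identical for any worker count;
- **simulate** seeded PubMed-XML corpora with planted, ground-truthed
  interactions for validation.

## Worked example

```r
library(litcooc)
lex <- demo_lexicon()   # small bundled plant lexicon (demonstration stand-in)

rec <- abstract_record(
  pmid  = "31456",
  title = "NPR1 and PR-1 in plant defense.",
  abstract = paste("NPR1 activates PR-1 during biotic stress in Glycine max.",
                   "PDF1.2 and MYC2 regulation was reported.",
                   "EDS1 was studied separately. PAD4 was studied separately."))

cooc <- mine_records(list(rec), lex)
cooc[c(12, 8, 2), c("entity_a", "entity_b", "type", "terms", "concepts")]
#>    entity_a entity_b type      terms      concepts
#> 12     NPR1     PR-1    1  activates biotic stress
#> 8      MYC2   PDF1.2    2 regulation              
#> 2      EDS1     NPR1    4            biotic stress
```

"NPR1 activates PR-1" puts an exact trigger between the two names → type 1,
with the trigger and the sentence's concept attached as evidence. "PDF1.2
and MYC2 regulation" has the exact trigger after both names → type 2. EDS1
and NPR1 never share a sentence → type 4, annotated with the abstract's
concepts. All six tagged names yield C(6,2) = 15 pairs; the summary shows
the absolute/non-redundant accounting (absolute proteins = 2 per record):

```r
compute_stats(cooc)
#> <cooc_summary> 15 co-occurrences (15 non-redundant), 30 proteins (6 non-redundant), 2 terms (2 non-redundant)
#>   per type: t1=1 t2=1 t3=0 t4=13

f <- filter_by_taxon(cooc, attr(cooc, "entities"), 3847, lex)  # Glycine max
nrow(f)
#> [1] 15   # the abstract mentions "Glycine max", so everything is kept

edges <- build_edges(cooc)
edges[edges$best_type == 1, c("entity_a", "entity_b", "weight", "best_type")]
#>    entity_a entity_b weight best_type
#> 12     NPR1     PR-1      1         1
export_network(edges, "defense.graphml", "graphml")
```

A corpus run over many XML files, 4 workers, soybean filter, type-1 only:

```r
cfg <- run_config(input_paths = list.files("xml/", full.names = TRUE),
                  lexicon_path = system.file("extdata",
                    "plant_demo_lexicon.tsv", package = "litcooc"),
                  output_dir = "results/", jobs = 4,
                  tax_id = 3847, max_type = 1)
run_pipeline(cfg)          # one <input>.cooc.tsv per XML + run_manifest.tsv
summarize_basic("results/")  # N + 1 .summary files incl. A.join.dataset.summary
```

The same stages are available from the shell via the wrapper in
`inst/cli/litcooc.R` (`parse`, `tag`, `mine`, `summarize`, `network`,
`simulate`, `run`; flags `-j/--jobs`, `--tax-id`, `--max-type`,
`--lexicon`, `--out`, `--seed`).

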