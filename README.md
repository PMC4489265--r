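# sansearch

Fast protein homology search in R by **suffix array neighborhood search**:
index a FASTA protein database into a suffix array, retrieve a query's
sequence neighbors by windowed suffix voting over diagonal bands, and rank
candidates by banded Smith–Waterman alignment with Karlin–Altschul
e-values. It is aimed at people who need approximate nearest-neighbor
retrieval of protein sequences — functional-annotation pipelines,
interactive exploration of a protein's relatives, database clustering —
where exhaustive alignment of the query against everything is too slow and
close homologs (roughly ≥ 50% identity) are the target.

## The method in brief

The database text (proteins joined by a sentinel) is indexed once into a
suffix array. For each query position, the suffix starting there is located
in the array by binary search; the `2W` lexicographically nearest database
suffixes each cast a **vote** for their protein if they share a common
prefix of at least `min_match` residues with the query suffix. Votes
accumulate per **diagonal band** `floor((q - t) / band_width)` — evidence
only counts when matches agree on an alignment register — and a protein's
vote is its best band. Top-voted candidates are aligned by Smith–Waterman
restricted to a band around the winning diagonal, and significance comes
from Karlin–Altschul statistics,

    E = K · m · n · exp(−λ · S)

with `m` the query length, `n` the total database residue count, and
(by default) BLOSUM62 with gap 11/1 and λ = 0.267, K = 0.041. Four
protocols trade depth for speed: `verifast` (top-H by vote, no alignments,
vote ≥ threshold), `fast` (top-H, aligned), `slow` (top-2H, re-sorted by
score), `verislow` (up to 4000 voted candidates). Aligning modes report
hits with e-value < 1. See the vignette
(`vignettes/suffix-array-neighborhood-search.Rmd`) for the full model,
parameter rationale and limitations.

## Worked example

Generate a small synthetic benchmark (200 random decoys plus homologs of 5
query proteins implanted at 50–100% identity), index it, and search with
one of the queries:

```r
library(sansearch)
bm  <- make_benchmark(benchmark_spec(n_decoys = 200, homologs_per_bin = 5,
                                     n_queries = 5, seed = 42))
idx <- sans_index(bm$db)
hits <- sans_search(bm$queries[1, ], idx, search_params(mode = "slow", H = 10))
hits
#> sans_hits: query 'Q0001', mode slow, 5 hit(s)
#>  rank         hit_id vote score   evalue identity
#>     1 HOM_90-100_001   88   778 2.01e-85    0.932
#>     2  HOM_80-90_001   40   678 7.91e-74    0.831
#>     3  HOM_70-80_001   34   603 3.93e-65    0.789
#>     4  HOM_60-70_001   14   495 1.31e-52    0.685
#>     5  HOM_50-60_001    3   367 9.13e-38    0.565
```

The five implanted homologs of `Q0001` — one per identity bin, and nothing
else — are retrieved and ranked by alignment score; `vote` is the
suffix-neighborhood evidence (best diagonal band), `score` the banded
local-alignment score in matrix units, `evalue` its Karlin–Altschul
significance against the whole database, and `identity` the fraction of
identical aligned columns. The 200 unrelated decoys score e-values far
above 1 and are filtered out. `write_tabular(hits)` renders the same table
as TSV (1-based inclusive coordinates), `write_report(hits)` a BLAST-like
pairwise report, and `write_fasta(hits, aligned = TRUE)` a stacked
alignment in which every row has exactly the query's length (insertions
relative to the query are omitted but counted).

## Command line

A thin launcher is installed with the package:

```sh
SANS=$(Rscript -e 'cat(system.file("cli", "sans", package = "sansearch"))')
Rscript $SANS generate --outdir bench --seed 42        # synthetic benchmark
Rscript $SANS index bench/db.fasta --out db.rds        # build + persist index
Rscript $SANS search db.rds bench/queries.fasta --mode slow -H 10 --out hits.tsv
Rscript $SANS bench db.rds bench/queries.fasta bench/meta.tsv --out recall.tsv
```

`search` accepts `--mode`, `-H`, `--window`, `--min-match`, `--band-width`,
`--half-band`, `--matrix` (bundled name or NCBI-format file, with
`--lambda`/`--K` for custom matrices), `--gap-open`, `--gap-extend`,
`--evalue`, `--vote-threshold`, `--stable-h` and
`--format tsv|report|fasta|stacked`. The index sidecar is a versioned RDS
file holding the record ids, offsets and suffix positions; rebuild it with
`index` whenever the FASTA changes.

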