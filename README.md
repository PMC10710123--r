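# phyloprior

Grid-based spatial conservation prioritization from phylogenetic diversity
computed over a **collection of independent phylogenies** plus species
occurrence records.

Richness-based priority maps ignore evolutionary history: ten close
congeners are not worth ten distantly related species. `phyloprior` ranks
0.25° grid cells by the evolutionary distinctness of their species and
packages the full decision workflow around that ranking. For a cell with
species set *S* and one tree *T*:

- **AvTD** (average taxonomic distinctness, Δ⁺): the mean patristic
  distance over all unordered pairs of *S* present on *T*; 0 when fewer
  than two species are present.
- **PD** (Faith phylogenetic diversity): the total branch length of the
  minimal subtree of *T* spanning *S* (unrooted variant by default).

Per-cell values are computed per tree and summed across trees — the trees
are independent and undated, so no cross-tree distance exists. The workflow
then:

1. selects the index least coupled to richness by Bayesian simple linear
   regression on standardized variables (smaller |posterior mean slope| wins);
2. classifies cells into rank quintiles Q1–Q5 (Q5 = priority);
3. quantifies robustness by jackknifing the tree set and estimating each
   cell's probability of keeping its label (exact binomial intervals);
4. maps sampling reliability with the half-ignorance index
   `O½/(N + O½)`;
5. flags endemic species (mean pairwise occurrence distance < 0.25° of
   arc) and measures their contribution by removal experiments;
6. clusters cells by phylogenetic beta diversity (1 − PhyloSor) with PAM +
   silhouette analysis;
7. accounts AvTD inside vs outside protected-area polygons
   (positive-area overlap rule).

A synthetic-data module generates trees, occurrences, exclusion lists and
protected-area polygons with the statistical structure the analysis
assumes (planted endemics, planted high-diversity cells), so the entire
pipeline runs and is tested end-to-end with no downloads.

## Worked example

```r
library(phyloprior)

sc   <- synthetic_scenario(seed = 7)          # 10 trees, 5x5 deg domain
ts   <- generate_trees(sc)
occ  <- generate_occurrences(sc, ts)
grid <- assemble_grid(occ, sc$domain, sc$cell_size)
print(grid)
#> grid_assembly: 20 x 20 cells of 0.25 deg; 400 occupied; 6218 records

scores <- score_cells(ts, grid)
sel <- select_index(scores, seed = 7)
print(sel)
#> index selection: slope(PDi) = 0.871, slope(AvTD) = 0.831 -> AvTD

q <- classify_quantiles(scores$avtd, scores$cell_id)
attr(occ, "hotspot_cells")                     # planted high-diversity cells
#> [1] 225 253 386
as.character(q[match(attr(occ, "hotspot_cells"), scores$cell_id)])
#> [1] "Q5" "Q5" "Q5"

en <- classify_endemics(occ)
length(en$endemic)                             # 16 of 113 species
#> [1] 16
imp <- endemic_impact(ts, grid, en, fractions = 1, seed = 7, scores = scores)
round(imp$full_removal$pct_decrease, 2)        # % of total AvTD lost
#> [1] 1.08
```

The slopes say both indices track richness here, AvTD less so — it is
selected. The three planted hotspot cells land in the top quintile, and
removing all endemic species costs ~1% of total AvTD even though endemics
are ~14% of the species list: their pendant branches are short.

`make_synthetic()` writes a complete input bundle (newick trees, Darwin-Core
style occurrence CSV, exclusion list, PA GeoJSON, config) and
`run_pipeline()` executes every stage and writes per-stage CSV tables plus
a JSON manifest. A thin command-line wrapper with verbs
`simulate` / `run` / `report` is installed under `inst/scripts/phyloprior`.

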