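# stmc — pseudo-3D spatio-temporal statistical model checking

`stmc` validates stochastic *spatial* computational models — growing
bacterial colonies, aggregating cell populations, and other multicellular
systems — against formal spatio-temporal specifications. Where classical
statistical model checking only handles scalar time courses, `stmc`
consumes **pseudo-3D traces**: per-timepoint m×n grids of non-negative
densities (2-D space plus a density axis). It is aimed at systems and
synthetic biologists who simulate spatial stochastic models and want an
automatic, quantitative answer to questions like *"do sectors keep their
triangular shape with probability at least 0.8?"*.

## What it does

1. **Detect** spatial entities in each trace:
   *regions* (connected above-threshold patches) via an image-processing
   pipeline — brightness/contrast, grayscale morphological closing,
   Gaussian blur, binary threshold, two-level contour extraction with
   holes, polygon approximation — and *clusters* of regions via an
   order-independent DBSCAN over the centroid-distance pseudometric.
2. **Measure** every entity with eleven spatial measures: clusteredness,
   density, area, perimeter, distance from the origin, subtended angle,
   triangular/rectangular/circular shape measures
   (area over minimum-area enclosing triangle / rotated rectangle /
   circle), and the centroid coordinates. Serialisation uses **STML**
   (Spatial Temporal Markup Language), an XML dialect with a shipped XSD
   schema.
3. **Specify** behaviour in **PBLSTL** — probabilistic bounded linear
   spatial temporal logic: statements `P >= 0.9 [ psi ]` where `psi`
   combines bounded temporal operators `F/G/U [a, b]`, `X [k]`, Boolean
   connectives, arithmetic, and statistics (`count`, `mean`,
   `percentile`, `covariance`, ...) over the dynamic collections
   `regions` and `clusters`, optionally restricted by
   `filter(collection, constraint)`. Example:

   ```
   P >= 0.9 [ F [0, 100] (({cAMP} < 20) ^ (count(clusters) > 0)) ]
   ```

4. **Decide** each statement over a collection of traces with one of five
   approximate probabilistic algorithms: Wald's sequential probability
   ratio test with an indifference region, Chernoff–Hoeffding fixed-sample
   estimation (n = ⌈ln(2/δ)/(2ε²)⌉), Bayesian sequential hypothesis
   testing (Bayes factor under a Beta prior), Bayesian credible-interval
   estimation, and black-box checking with an exact binomial-tail p-value.
   A whole specification is checked in a single pass over the traces, and
   sequential methods that run out of traces fall back to the black-box
   verdict on the observations gathered so far.

Synthetic generators for the two benchmark systems (sector patterning in a
growing colony; chemotactic aggregation toward a 2-D Gaussian attractant
on a 100×100 lattice with 100 cells) make the whole pipeline runnable with
no external simulator.

## Worked example

```r
library(stmc)
# simulate five chemotaxis traces and write them as STML
dir <- file.path(tempdir(), "stml")
generate_stml_dataset("chemotaxis", n = 5, dir = dir, seed = 7)

# check the shipped chemotaxis specification with the black-box method
spec <- parse_pblstl_file(system.file("extdata", "specs",
                                      "chemotaxis.pblstl", package = "stmc"))
results <- check_specification(spec, trace_provider_directory(dir),
                               checker_config(method = "black_box"))
```

which prints:

```
statement 1: TRUE  [black_box]  traces: 5 (5 true / 0 false)  confidence: 0.59049
statement 2: TRUE  [black_box]  traces: 5 (5 true / 0 false)  confidence: 0.32768
statement 3: TRUE  [black_box]  traces: 5 (0 true / 5 false)  confidence: 0.7737809
statement 4: TRUE  [black_box]  traces: 5 (5 true / 0 false)  confidence: 0.2373047
statement 5: TRUE  [black_box]  traces: 5 (5 true / 0 false)  confidence: 0.07776
statement 6: TRUE  [black_box]  traces: 5 (0 true / 5 false)  confidence: 0.59049
```

Statement 1 is the aggregation property (a cluster forms within distance 5
of the gradient centre and persists for 100 steps): all five traces
satisfy it, so the empirical probability 1 exceeds the threshold 0.9 and
the verdict is TRUE. The confidence column is the exact binomial-tail
p-value of an outcome at least this favourable under p = θ — smaller means
stronger support; with only five traces the evidence is naturally weak
(0.59 = 0.9⁵). Statements 3 and 6 are *rarity* statements (`P < θ [...]`):
zero true evaluations out of five supports them, hence TRUE with 0 true /
5 false. Sequential methods (`method = "sprt"` on the command line)
request exactly as many traces as the decision needs instead.

The same run from a shell:

```sh
stmc synthesize --case chemotaxis --out stml/ --n-traces 5 --seed 7
stmc check --spec chemotaxis.pblstl --stml-dir stml/ --method black-box
```

`stmc check --help` lists all flags, including on-demand trace generation
(`--generator SCRIPT`), the per-method error bounds, `--max-traces`,
`--max-seconds` and `--report json`.

## Layout

| Path | Contents |
| --- | --- |
| `R/` | STML data model and I/O, geometry, detectors, measures, BLSTL parser/evaluator, checkers, generators |
| `inst/extdata/STML_L1V1.xsd` | normative STML schema |
| `inst/extdata/pblstl_grammar.ebnf` | concrete PBLSTL grammar |
| `inst/extdata/specs/` | the two packaged case-study specifications |
| `exec/stmc` | command-line front end (`check`, `synthesize`) |
| `vignettes/` | methods vignette: models, conventions, design choices |
| `tests/testthat/` | unit, property and acceptance tests with independent oracles |
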