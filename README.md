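# ldenet

Logic-based differential equation (LDE) modeling of biological signaling
and gene-regulatory networks in R: build a network from a two-sheet
spreadsheet (or in code), simulate staged stimulation/washout protocols,
run systematic in-silico knockout screens, and export the network for
Cytoscape.

## The model

A network is a set of *species* (genes, proteins, processes), each with a
continuous normalized activity $y_i \in [0, y_{max,i}]$, connected by
activating/inhibiting *reactions*. Every species relaxes toward its
regulatory drive:

$$\frac{dy_i}{dt} = \frac{\phi_i(y)\,y_{max,i} - y_i}{\tau_i}$$

Each reaction contributes a flux $w \prod_j f_j(y_{s_j})$, where $f$ is a
normalized Hill activation $f(x) = \beta x^n/(K^n + x^n)$ — rescaled so
that $f(0)=0$, $f(EC_{50})=\tfrac12$, $f(1)=1$ — or its complement
$1 - f(x)$ for inhibiting terms (AND logic within a rule). Reactions
converging on one species combine with the fuzzy OR $a + b - ab$. Input
reactions (`=> A`) have no sources and inject their weight as a constant
environmental stimulus. A knockout is $y_{max} = 0$.

Defaults: $\tau = 1$, $y_{init} = 0$, $y_{max} = 1$, $w = 1$, $n = 1.4$,
$EC_{50} = 0.5$.

## Worked example

Two bundled models are built in code: `exampleNet()` (five species A–E,
six reactions, two switchable stimuli) and `cardiacDevNet()` (a
five-transcription-factor network of cardiac outflow-tract development:
GATA6, NKX25, TBX1, ISL1, PITX2).

```r
library(ldenet)

m <- exampleNet()
m
#> NetworkModel with 5 species and 6 reactions
#>   species: A, B, C, D, E
#>   r1: => A (w=0, n=1.4, ec50=0.5)
#>   r2: => B (w=0, n=1.4, ec50=0.5)
#>   r3: A => C (w=1, n=1.4, ec50=0.5)
#>   r4: B => D (w=1, n=1.4, ec50=0.5)
#>   r5: A & !B => E (w=1, n=1.4, ec50=0.5)
#>   r6: E => C (w=1, n=1.4, ec50=0.5)

# 10 time-units with all stimuli off, then 10 with stimulus A on
tc <- runProtocol(m, simulationProtocol(list(
  protocolStep(10),
  protocolStep(10, weights = c(r1 = 1)))))
round(finalState(tc), 4)
#>      A      B      C      D      E
#> 1.0000 0.0000 0.9999 0.0000 0.9996
```

Stimulus A drives A directly, C through `A => C` (reinforced by
`E => C`), and E through `A & !B => E`; with B silent the inhibition term
is 1, so A, C and E all saturate at activity 1 while B and D stay at 0.

A knockout screen against the stimulated baseline:

```r
scr <- knockoutScreen(cardiacDevNet(), targets = "NKX25")
round(screenDeltas(scr), 3)
#>       GATA6 NKX25 TBX1 ISL1 PITX2
#> NKX25     0    -1    0    1     0
```

Knocking out the repressor NKX25 de-represses ISL1 completely (delta +1):
the progenitor program stays on, the in-silico counterpart of the ISL1
increase seen experimentally when NKX2-5 is reduced.

## File formats

* **Model workbooks** (`readModelWorkbook()` / `writeModelWorkbook()`):
  XLSX with a `species` sheet (columns `module, ID, name, Yinit, Ymax,
  tau`) and a `reactions` sheet (`module, ID, Rule, Weight, n, EC50`).
  The header row is located by content, so decorative preamble rows are
  fine; blank cells take the defaults; extra columns (references, notes)
  round-trip verbatim; rule cells may carry a leading apostrophe to keep
  spreadsheets from treating `=>` as a formula. Rules follow
  `[!]SRC [& [!]SRC ...] => TARGET`; `=> TARGET` alone declares an input
  reaction.
* **Protocols** (`readProtocol()`): YAML or JSON,
  `steps: [{duration: 10, weights: {r1: 1}, species: {NKX25: {ymax: 0}}}]`
  plus optional `n_out_per_step`.
* **Cytoscape** (`exportCytoscapeEdges()`): a `.sif` file with one
  `SOURCE <TAB> activates|inhibits <TAB> TARGET` line per rule term (input
  reactions appear as `INPUT_<target>` pseudo-nodes) and a `_edges.tsv`
  attribute table (reaction id, weight, n, ec50).
* **Time courses** (`writeTimeCourse()`): tidy CSV, `time` plus one
  column per species, with segment boundaries in a `#` comment header.

## Command line

```sh
Rscript inst/cli/ldenet.R fixtures --dir models     # write bundled models
Rscript inst/cli/ldenet.R validate models/exampleNet.xlsx
Rscript inst/cli/ldenet.R simulate models/cardiacDevNet.xlsx \
    --out run --set r1=1 --knockout NKX25 --plot
Rscript inst/cli/ldenet.R screen models/cardiacDevNet.xlsx --out screen.csv
Rscript inst/cli/ldenet.R export models/exampleNet.xlsx --out net
```

Exit codes: 0 success, 1 domain/validation error, 2 I/O error. Logs go to
stderr, results to files/stdout.

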