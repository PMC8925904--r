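# hedlite

Hierarchical Event Descriptor (HED) annotation machinery for neuroimaging
event streams, in R.

## What problem this solves, and for whom

Event-related analysis of MEEG/fMRI data needs a machine-actionable record
of *what happened when*: stimulus presentations, participant actions, task
conditions, and recording-wide setup choices, with onsets, durations and
design roles.  HED provides a hierarchically organized controlled
vocabulary plus a small grammar for this; BIDS provides the file layout
(`events.tsv` tables annotated through JSON sidecars).  hedlite is a
compact, fully tested implementation of the third-generation HED core for
people who build or lint such annotations:

* **vocabulary** — a rooted forest of uniquely named terms with
  short↔long-form expansion (`Circle` ↔
  `Item/Object/Geometric-object/2D-shape/Ellipse/Circle`) and subsumption
  search (query `2D-shape`, find `Circle`);
* **grammar** — parse/serialize/search comma-separated annotations with
  arbitrarily nested parenthesized groups;
* **definitions** — `(Definition/Name, <body>)`, compact `Def/Name`
  references, `Def-expand` expansion, placeholder (`#`) substitution;
* **BIDS assembly** — events.tsv + sidecar (categorical vs `#`-templated
  value columns, inheritance merge) → one assembled HED string per event;
* **temporal semantics** — `(Def/X, Onset)` / `(Def/X, Offset)` groups
  resolved into event processes with durations, plus `Event-context`
  insertion for concurrent events;
* **design extraction** — `Condition-variable` definitions → factors,
  levels, and a per-event design matrix (column- and row/meta-event
  encoded conditions);
* **restructuring** — explicit-mapping conversion of by-trial event
  tables into by-event form;
* **simulation** — a generator of face-perception-style sessions
  (3×3 factorial, 6 runs of 140–150 presentations, exact repeat/sex
  balance, counterbalanced key assignment) used as the test-bed.

The core temporal model: a process named by definition `X` opens at an
event whose annotation groups `Def/X` with `Onset`, and stays in effect
until the next event grouping `X` with `Onset` or `Offset`; intervals are
half-open, and `duration = offset − onset`.

## Worked example

The packaged fixture reconstructs a published eight-row events excerpt
(a famous-face immediate repeat) plus its sidecar:

```r
library(hedlite)

tab     <- read_events_tsv(hedlite_wh_events_path())
sidecar <- read_sidecar(hedlite_wh_sidecar_path())
asm     <- assemble_events(tab, sidecar)
asm$events[[6]]   # the bold row at onset 26.940 s
#> AssembledEvent @ 26.940 s: Sensory-event, Experimental-stimulus,
#>   (Def/Face-image, Onset), (Def/Blink-inhibition, Onset),
#>   (Def/Cross-only, Offset), Def/Famous-face-cond,
#>   Def/Immediate-repeat-cond, (Face, Item-interval/1),
#>   (Image, Pathname/f032.bmp)
```

The five colored sidecar columns each contributed a fragment: the
`show_face` level opened the face-display and blink-inhibition processes
and closed the cross-only display; the `famous_face` and
`immediate_repeat` levels reference the design definitions; the `rep_lag`
cell `1` and the `stim_file` cell `f032.bmp` were substituted for the
templates' `#` placeholders.

Resolving temporal scope turns the Onset/Offset groups into processes:

```r
resolve_processes(asm)$processes
#>          definition onset offset duration       closed_by
#> 1     Left-sym-cond  0.40  27.99   27.590   end-of-record
#> 2  Blink-inhibition 23.87  24.75    0.880 explicit-offset
#> 3        Face-image 23.87  24.75    0.880 explicit-offset
#> 4     Fixation-task 23.87  24.75    0.880 explicit-offset
#> 5       Circle-only 24.75  26.46    1.707 explicit-offset
#> ...
```

The face display opening at 23.870 s closes at the circle presentation at
24.750 s: 24.75 − 23.87 = **0.88 s**, the printed worked computation.
The design matrix recovers the factorial structure, including the
row-encoded key assignment carried by the setup meta-event at the first
sample:

```r
dm <- design_matrix(asm, resolve_processes(asm),
                    extract_condition_variables(sidecar$definitions))
summarize_design(dm)$factors
#>              factor encoding n_levels
#> 1         Face-type   column        3
#> 2 Repetition-status   column        3
#> 3    Key-assignment      row        2
```

Synthetic sessions and whole datasets:

```r
ses <- generate_session(wh_session_spec(seed = 1))   # 6 runs, design-exact
generate_dataset("myds", n_participants = 19, wh_session_spec(seed = 1))
validate_dataset("myds")                              # zero-row issue frame
```

## Command line

`inst/scripts/hedlite` wraps `hedlite_main()`:

```sh
Rscript -e 'hedlite::hedlite_main()' schema-info
Rscript -e 'hedlite::hedlite_main()' expand --form long "Circle"
Rscript -e 'hedlite::hedlite_main()' validate <dataset-root>
Rscript -e 'hedlite::hedlite_main()' temporal <dataset-root>
Rscript -e 'hedlite::hedlite_main()' simulate --out myds --participants 2 --seed 3
```

## Documentation

`vignettes/hedlite-methods.Rmd` documents the models, the boundary-case
policies (end-of-record closure, context vs design interval conventions),
what the generator does and does not emulate, and known limitations.
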