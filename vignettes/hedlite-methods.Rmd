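---
title: "Annotating neuroimaging event streams with hedlite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating neuroimaging event streams with hedlite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedlite)
```

## The problem

Event-related analysis of MEEG and fMRI recordings stands or falls with the
quality of the event record: which sensory presentations, participant
actions, task conditions and setup choices occurred, exactly when, and for
how long.  Hierarchical Event Descriptors (HED) address this with a
hierarchically organized controlled vocabulary plus a small grammar:
annotations are comma-separated lists of vocabulary terms and parenthesized
tag groups, attached to the rows of a BIDS `events.tsv` file through a JSON
sidecar.  hedlite implements this machinery end to end -- vocabulary,
grammar, definitions, sidecar assembly, temporal scoping, design
extraction, by-trial restructuring -- together with a synthetic generator
of face-perception sessions used as a test-bed.

The running example throughout the package is a classic face-perception
experiment: participants judge the symmetry of famous, unfamiliar and
scrambled face images while fixating a cross, with every image shown twice
(half immediately, half after a 5--15 presentation gap) and a
counterbalanced response-key assignment.

## The vocabulary model

A `HedSchema` is a rooted forest of uniquely named terms.  Uniqueness is
the load-bearing property: because `Circle` occurs in exactly one place,
the short form `Circle` can be expanded mechanically to
`Item/Object/Geometric-object/2D-shape/Ellipse/Circle`, and a search for
the more general `2D-shape` can find events annotated only with `Circle`
(subsumption is long-path prefix testing on component boundaries).  Names
are case-insensitive with canonical capitalization preserved for output;
names never contain whitespace.  A term flagged as taking a value admits a
`/value` suffix (`Item-count/2`) and may not have children.

The full HED base vocabulary has thousands of terms; hedlite instead
packages a mini-schema (`inst/extdata/hed_mini_schema.txt`, ~110 nodes)
sufficient for the face-perception example.  The serialization format is
deliberately plain: one term per line, two-space indentation, descriptions
after `" ; "`, a lone `#` child marking a takes-value term.  The upstream
ecosystem's XML/mediawiki formats, schema versioning attributes, library
schemas, and annotator-driven schema extension are out of scope; unknown
tags are errors.  The seven root names (`Event`, `Agent`, `Action`,
`Item`, `Property`, `Task`, `Relation`) are a design choice of this
package: the source material states the root count and uses a set of
terms, but does not enumerate the roots, so the fixture declares a
consistent set of seven.

One deliberate relaxation: a takes-value term may appear *without* a value.
The strict reading ("value present iff the node takes values") would
forbid the bare `Condition-variable` tag, which the design-extraction
rules explicitly require for singleton factors.  Supplying a value to a
non-value term remains an error.

## Definitions and expansion

A definition is a group whose first tag is `Definition/Name`; the rest of
the group is the body.  `Def/Name` references it; at analysis time
`expand_defs()` rewrites each reference to `(Def-expand/Name, <body>)`, so
the defined tags become searchable while the reference remains
recoverable.  Bodies may not contain `Definition`, `Def` or `Def-expand`
(no nesting, to avoid circularity).  A placeholder definition carries
exactly one `#`, substituted from `Def/Name/value`; the one-`#` arity rule
is the minimal generalization of how `#` behaves in sidecar value columns.
Re-registration of an identical definition is a no-op, but two definitions
sharing a name with different bodies are a hard conflict rather than
last-wins, because definitions are the semantic anchor for temporal
scoping and design extraction -- silently replacing one would corrupt both.

In sidecars, definitions may live under dedicated top-level keys that are
not column names; such keys are recognized structurally (every annotation
in them is a definition group), not by naming convention.

## Assembly from BIDS files

Event files are TSV with required `onset`/`duration` columns and `"n/a"`
for missing cells.  hedlite stores cells as the exact text read, so
writing a table back is byte-stable and numeric value substitutions keep
`"1"` distinct from `"1.0"`.  A sidecar entry whose `HED` key is a mapping
makes its column categorical (one annotation per level); a single string
containing one `#` makes it a value column; no `HED` key means
unannotated.  Classification depends only on the entry shape, never on
cell contents.  Sidecars merge along the directory path from dataset root
to events file, deeper files overriding shallower ones per whole top-level
key (partial merges are not attempted, matching BIDS practice).

Assembly walks each row in events-file column order, concatenating level
annotations and substituted templates; missing cells and unannotated
columns contribute nothing.  Concatenation order is presentational:
`hed_equal()` compares annotations as multisets at each nesting level, and
all worked-example tests use that comparison.  A categorical cell without
a level annotation is a lint finding (`missing-level`), not an error --
assembly continues so that one typo does not hide every other problem.

The packaged fixture dataset reconstructs the face-perception annotations
from the printed excerpts of the source material: the events excerpt
(eight rows around a famous-face immediate repeat at 26.940 s) is
reproduced verbatim, while the sidecar bodies for `Face-image`,
`Cross-only`, `Circle-only`, `Press-left-finger`, `Press-right-finger`,
`Fixation-task`, `Blink-inhibition` and the two setup conditions are
reconstructed from prose (the complete originals live in supplementary
material that is not reproduced here).  The six design-encoding
definitions are exact as printed.  The fixture is therefore a synthetic
reconstruction, and tests that compare against "the printed assembled
string" freeze the reconstruction, not a scan of the original table.

## Temporal semantics

A group pairing `Def/X` with `Onset` opens an event process named `X` at
that marker's time; the process closes at the next event grouping `X`
with `Onset` or `Offset` (both close; re-`Onset` also reopens).  Intervals
are half-open `[onset, offset)`.  Three policies were genuinely open and
are fixed as follows:

* **End of record.**  Processes still open when the record ends close at
  the last event marker's time with `closed_by = "end-of-record"`.  This
  keeps durations finite and auditable.  It is *not* a validation issue:
  every recording of the running example necessarily ends with an open
  circle-display process, and flagging the inevitable would bury real
  problems.
* **Boundary exclusion for context.**  `insert_context()` adds an
  `(Event-context, Def/P, ...)` group to events strictly inside `P`'s
  interval.  A process's own opening and closing markers are excluded: the
  event that carries the face display's `Offset` is not "during" the face
  display.
* **Closed intervals for row-encoded design.**  Design assignment
  (below) deliberately uses the closed interval, so the setup meta-event
  and the final marker both carry the recording-wide condition.  Context
  answers "what was ongoing around this event", design answers "under
  which condition was this event recorded"; the boundary conventions
  differ accordingly.

An explicit `duration` column, when present, is informational; explicit
Onset/Offset groups take precedence for process extent.  The resolver is
verified against a brute-force oracle (an independent per-definition
left-to-right sweep) on random marker streams of up to 200 markers.

## Design extraction

Each definition whose body contains `Condition-variable/F` contributes its
name as a level of factor `F`; a bare `Condition-variable` makes the
definition its own singleton factor.  Factor names are matched
case-insensitively (the HED-side name is authoritative; event-file columns
such as `face_type` are aliases).  A level that opens timeline processes
marks its factor row-encoded; otherwise assignment is by reference: an
event carries a level if its assembled annotation references the level's
definition.  An event referencing two levels of one factor is a lint
conflict, not an error, so summaries still print.  On the fixture, the
column-encoded and row-encoded paths provably agree: rebuilding the key
assignment as a column yields the same design matrix.

`Item-count`/`Item-interval` inside the repetition-status definitions are
carried as inert tags; no operational semantics are attached to them.

## By-trial restructuring

Tables that store one row per trial embed the other trial events as
delays, and the reference point of each delay is frequently undocumented
-- the motivating example stores the pre-anchor cross display as a
*positive* duration.  `explode_trials()` therefore takes an explicit
mapping (`anchor_column`, per-event `source_column`/`sign`/`role`) and
never infers; the packaged mapping for the fMRI-style fixture documents
its one assumption, that response times are measured from the face onset
(the anchor).  Exploding is invertible (`fold_trials()`) given the same
mapping when no source cell is missing.  Negative onsets are legal but
flagged.

## The synthetic generator as a stated world

`wh_session_spec()` encodes the documented design directly: 6 runs of
140--150 face presentations, each identity shown exactly twice within its
run, half of the repeats immediate (positional lag 1) and half delayed
with lag uniform in [5, 15], face types drawn with uniform-thirds
probabilities (the source states only that scrambled faces were a
one-third minority), exactly half the identities female, and key
assignment counterbalanced across participants.  Two notes on exactness:

* "Half" statements are exact by construction, not binomial: the drawn
  trial count is restricted to values for which pairing, the
  immediate/delayed split and the sex split are all integral
  (multiples of 4 within [140, 150], i.e. 140/144/148 under defaults), and
  the splits are dealt, not sampled.  This makes every seed satisfy the
  design statements, which is what the property tests assert.
* The delayed-repeat lag is the positional difference between the two
  showings, uniform in [5, 15].  The source material is internally
  inconsistent ("5--15 intervening presentations" vs "seen 5 to 15 trials
  ago"); the `rep_lag` column convention (an immediate repeat has lag 1)
  fixes the positional-difference reading.

Timing is only fragmentarily documented upstream, so the defaults are
declared configuration, not claims: cross 0.4--0.6 s, face 0.8--1.0 s,
response latency 0.2--2.5 s after face onset (late responses may fall
after the circle onset, as in real data), circle fill 1.2--1.9 s, sampling
rate 1100 Hz (cosmetic, for the `sample` column).  Scheduling uses
randomized greedy pair placement with whole-run restarts on dead ends;
onsets are rounded to the millisecond and nudged by 1 ms in the rare case
rounding creates a tie, keeping within-run onsets strictly increasing.

What a green generator test does establish: the annotation pipeline --
sidecar reconstruction, assembly, temporal resolution, design extraction,
validation -- is exercised end to end on data with the documented design
statistics, at realistic volume (19 participants x 6 runs x ~590 markers).
What it does not establish: anything about real recordings.  The generator
emulates the event stream only -- no signals, no behavioral accuracy, no
post-session memory test, no session-splitting of identities across runs
(each run is self-contained, which still gives "twice per session").

## Numerical and degenerate-input choices

* All comparisons of printed times happen on millisecond-precision inputs;
  the one derived quantity asserted exactly (the 0.88 s face display) is
  the difference of two printed onsets.
* The empty annotation string parses to an empty `hed_string`; an empty
  group `()` is an error (a written group must have content).
* Equality of annotations is order-insensitive per nesting level and
  case-insensitive, implemented by sorting canonical serializations.
* `read_events_tsv` treats non-monotone onsets as a warning, not an error:
  the table is still usable, and the temporal resolver sorts defensively.

## Known limitations

* The mini-schema is not the HED base schema; annotations valid against
  the real vocabulary may use terms absent here.
* Tag attributes, unit classes, curly-brace column references and library
  schemas are not modeled.
* `participants.tsv`/`scans.tsv` HED columns are recognized in concept but
  not assembled; per-row `HED` columns in events files are out of scope.
* Preceding-event (as opposed to concurrent) context is not inserted.
* The validator covers the rules this package implements, not the full
  upstream specification.
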