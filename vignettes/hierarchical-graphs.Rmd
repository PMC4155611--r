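---
title: "Vertex-weighted hierarchical graphs of protein structure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-weighted hierarchical graphs of protein structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protier)
```

## The model

`protier` represents one chain of a protein as a nested, three-tier,
vertex-weighted graph. The motivation is scale: an all-atom graph of a
protein is too large to read, an amino-acid network hides chemistry, and
neither makes the global consequences of a one-residue change visible. The
hierarchy keeps all three resolutions and connects them through vertex
weights.

**Bottom.** Each canonical amino acid is a hydrogen-suppressed graph:
heavy atoms as vertices (weighted by standard atomic mass), covalent bonds
as edges, rooted at the backbone Cα. Residue graphs are independent of one
another — the peptide bond is deliberately *not* an edge, because each
graph describes the residue as a unit of chemistry, not the backbone
polymer; inter-residue relationships live one tier up, in the contact
maps. Topologies come from a bundled, editable table
(`residue_topology()`); aromatic systems are plain cycles (a graph model,
not a bond-order model), terminal forms (OXT) are not distinguished, and
protonation states are irrelevant once hydrogens are suppressed.

**Mid.** The chain is partitioned into substructures — contiguous residue
intervals each containing one helix or one strand (or a long loop),
supplied as a table (`parse_substructure_table()`). Adjacent intervals may
share their boundary residue; the shared residue is a vertex of *both*
midlevel graphs. Within an interval, two residues are adjacent when their
distance is at most a threshold; edges carry the number of atom contacts.

**Top.** One vertex per substructure. Two substructures are adjacent when
at least two residue pairs — one residue in each — lie within the
threshold. A residue shared by both intervals is excluded from their pair
count entirely: a boundary residue cannot witness contact between the two
substructures it belongs to. Edges are weighted by the summed contact
counts.

## Weighted invariants

For a graph with vertex weights $w$:

* *weighted degree* of $v$: $\sum_{u \in N(v)} w(u)$; maximum and average
  over vertices give graph-level summaries;
* *weighted lower domination*: the minimum of $w(S)$ over dominating sets
  $S$ (every vertex in $S$ or adjacent to it); *weighted upper domination*:
  the maximum of $w(S)$ over **minimal** dominating sets. Without the
  minimality restriction the full vertex set would always win and the
  invariant would be vacuous;
* *weighted distance*: the length of a path is the sum of the vertex
  weights along it **excluding the start vertex**, so with unit weights the
  length is the edge count and all classical definitions are recovered.
  This makes distance direction-dependent; eccentricity, diameter and
  periphery are therefore taken over ordered pairs. The periphery is a
  vertex set; as a numeric descriptor we store its cardinality;
* *circumference*: the number of vertices in a longest simple cycle (0 for
  forests). It is kept unweighted — a count, not a weighted sum.

The unit-weight reduction is the design principle: every weighted
definition collapses to its textbook counterpart when all weights are 1,
and the test suite asserts this against closed forms on paths, cycles and
stars (e.g. domination number $\lceil n/3 \rceil$ for $P_n$).

All algorithms are exact. Domination is computed by branch and bound
(branching over the closed neighborhood of an undominated vertex, weight
bounds, and a permanent-redundancy prune for the upper variant);
distances by Dijkstra on a directed expansion where the edge into $v$
costs $w(v)$; circumference by pruned depth-first cycle search. Worst
cases are exponential, which is acceptable and documented: bottom graphs
have ≤ 14 vertices and midlevel graphs a few dozen. Every invariant has an
*independent* exhaustive oracle (`brute_force_oracle()`: all $2^n$ subsets
for domination, all simple paths for distances, all simple cycles for
circumference) used as ground truth on random graphs; the agreement check
over 200 random weighted graphs with $n \le 10$ is part of the acceptance
suite. Domination and distance invariants require non-negative weights and
refuse negative descriptor columns explicitly; degree-based invariants
accept any sign, which is why the defaults for propagation are
`max_weighted_degree` and `average_weighted_degree` (hydropathy, the most
useful descriptor in practice, is signed).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `metric` | `"calpha"` | residue reference point for adjacency (also `centroid`, `center_of_mass`, `all_atom`) |
| `threshold` | 7 Å | contact threshold; 8 Å is the customary companion of `centroid` |
| `count_metric` | `"all_atom"` | atoms counted for edge weights; `side_chain` excludes N, Cα, C, O (glycine then contributes nothing) |
| `min_contacts_top` | 2 | residue pairs required for a top-level edge |
| `min_contacts_mid` | 1 | contact count required for a midlevel edge; 2 gives the stricter reading of the adjacency rule |
| `invariants` | degree-based pair | invariants propagated mid → top, one top attribute per `invariant:descriptor` |

The two-pair rule is read as a *top-level* requirement; midlevel adjacency
defaults to a single qualifying distance, with `min_contacts_mid = 2`
available because the stricter residue-level reading is defensible.

A stored contact-map pair always carries a count of at least 1: adjacency
is decided by `metric`/`threshold`, and the count metric then quantifies
it; a qualifying pair with no qualifying atom pairs under a *different*
count metric still exists as a contact.

## The descriptor table

Mid-level vertex weights come from a per-residue table of 21 named
descriptors: 15 physicochemical and 6 graph-derived
(`descriptor_names()`). The bundled default
(`aa_descriptor_table()`) compiles widely used published scales —
Kyte–Doolittle hydropathy, Grantham polarity, formal charge at pH 7 (0.1
for histidine), Chou–Fasman helix and sheet propensities for the two
stability columns, normalized van der Waals volume, Eisenberg consensus
hydrophobicity, Deléage–Roux coil propensity, isoelectric point, Levitt
side-chain radius of gyration, Veljković electron–ion interaction
potential, and 0/1 indicator columns for charge-transfer acceptor and
donor character. The Balaban J index and the Randić-connectivity shape
index are computed from the bundled residue graphs themselves
(`data-raw/make_descriptor_table.R`), as are the six graph-derived columns,
which are bit-identical to `compute_graph_descriptors()` on
`enumerate_bottom_level()` — a test asserts this. Users with a preferred
compilation supply their own CSV through `load_descriptor_table()`, which
validates completeness (all 20 residues, all 21 columns) and names exactly
what is missing.

## Mutations

Substitutions, deletions and insertions parse from compact text (`V51R`,
`F508del`, `508insG`). Two analysis modes exist, mirroring the two things
one can honestly claim about a mutant:

1. **Re-weighting** (`reweight_mutant()`): the structure is assumed
   unchanged; the mutated midlevel vertices swap descriptor vectors and the
   top weights are recomputed. Edge sets never change. Only substitutions
   are allowed here — an indel changes a midlevel vertex set, which *is* a
   structural change. Locality is a theorem of the construction: a single
   interior substitution alters one midlevel graph and at most its own
   top-level vertex (two, if the residue sits on a shared boundary), and
   applying a substitution followed by its inverse restores the hierarchy
   bit-exactly.
2. **Rebuilding** (`rebuild_mutant_from_structure()`): the user supplies an
   externally predicted mutant structure (the package never calls a
   prediction service), substructure ranges are shifted by the cumulative
   indel offset at their start, and a full hierarchy is rebuilt; top-level
   edge sets may then differ and `diff_top_graphs()` reports edges
   lost/gained, per-descriptor weight deltas, and simple cycles (bounded
   length, default ≤ 8) present in one graph and not the other.

## Spanning-tree analysis

Vertex weights induce edge weights — the sum (default) or average of the
two endpoint values. The two schemes differ by the constant factor 2, so
they order edges identically and produce identical minimum spanning trees;
this equivalence is asserted as a test rather than assumed.
`minimum_spanning_tree()` is Kruskal with deterministic tie-breaking
(weight, then lexicographic endpoints) and an exact uniqueness flag via
the cycle property: the tree is unique iff every non-tree edge is strictly
heavier than every tree edge on the cycle it closes. Both the total and
the flag are checked against exhaustive spanning-tree enumeration on
random graphs with ≤ 8 vertices and ≤ 12 edges (100 instances in the
acceptance suite). Minimization is the default throughout, with
`maximize = TRUE` exposed for exploration.

`mutation_resampling()` draws `sample_size` mutations uniformly **without
replacement** per resample (a mutation set, not a multiset), recomputes
the tree, and reports per-vertex mean and standard deviation of tree
degree; `resampling_design()` suggests `(samples, sample_size)` so that
`samples × sample_size / n_mutations` hits a stated expectation (2.5 by
default). The generator state is seeded and restored, so reports are
byte-reproducible; a single full-list resample degenerates to the
all-mutations tree with all standard deviations 0.
`stability_classification()` calls a vertex stable when its degree
standard deviation is at most a tolerance (default 0: the degree never
moved).

## Synthetic structures

`generate_synthetic_structure()` writes PDB-format chains whose geometry —
and therefore whose contact graph — is known in closed form: colinear Cα
traces at fixed spacing (a path for spacing ≤ threshold < 2·spacing),
ideal α-helices (radius 2.3 Å, rise 1.5 Å, 100°/residue, giving contacts
up to i ± 4 at 7 Å), and seeded random coils. Side chains reduce to an
optional Cβ placed 1.53 Å from Cα. This emulates exactly what the
contact-map and hierarchy code consumes — numbering, chains, element
fields, coordinate precision (3 decimals) — and nothing else: no realistic
backbone geometry (N, C, O atoms), no rotamers, no B-factors, no steric
self-avoidance in coils. Tests passing on these fixtures therefore
validate the graph pipeline's logic, not the biophysics of any real
protein; runs on real structures (e.g. a downloaded TIM PDB file with
`tim_substructures()`) use identical code paths but bring real-data
concerns — missing residues, alternate locations (only blank/"A" kept),
insertion codes — that the reader should audit in their input.

## Numerical and serialization choices

* GraphML is written with 17 significant digits (`%.17g`), making
  export → import the exact identity on vertex/edge sets and weights; keys
  are typed (`double`/`long`/`string`). A hierarchy serializes as one
  GraphML file per tier (mid and bottom as disjoint unions with qualified
  vertex names) plus a JSON manifest carrying the full build configuration
  and an md5 checksum of the descriptor table — enough to re-run the build
  bit-identically. No timestamps are written, so repeated runs produce
  identical bytes.
* Degenerate inputs: an empty substructure table parses to an empty set;
  a one-residue interval is a one-vertex midgraph; fewer than two residues
  give an empty contact map (not an error); a disconnected graph is an
  error naming its components wherever connectivity is required.
* The self-inconsistent row of the bundled TIM interval table (D10 prints
  an 11-residue sequence against the range 12–130) is *flagged*
  (`consistent = FALSE`, with a warning) and kept verbatim; silently
  repairing published inputs is worse than reporting them.

## Check sizes

The shipped checks run at desk scale by choice: invariant/oracle agreement
on 200 random graphs with 4–10 vertices; MST exactness and uniqueness
against full spanning-tree enumeration on 100 random graphs with ≤ 8
vertices and ≤ 12 edges; hierarchy and mutation properties on 15–55
residue synthetic chains; the 19-interval table exercised over a
247-residue synthetic coil. These sizes make every expected value
computable by an independent exhaustive method while covering every code
path the full-size model uses.

## Known limitations

Single chain, first model only; no mmCIF; no solvent, ligands or
post-translational modifications. Upper domination and circumference are
exponential-time and intended for substructure-scale graphs, not
whole-chain networks. Domination- and distance-based invariants reject
negative descriptor values rather than redefining them. The package
consumes predicted mutant structures; it never produces them.
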