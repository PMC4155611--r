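Package: protier
Title: Vertex-Weighted Hierarchical Graph Models of Protein Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents a protein three-dimensional structure as a three-tier
    vertex-weighted hierarchical graph: hydrogen-suppressed atom graphs for
    the twenty canonical amino acids at the bottom, contact-map graphs over
    residues of user-defined substructures (helices, strands, loops) in the
    middle, and a substructure-level graph at the top.  Vertex-weighted graph
    invariants (weighted degree, weighted domination, weighted diameter and
    periphery, circumference) propagate amino-acid descriptors up the
    hierarchy.  Tools are included to apply in-silico mutations
    (substitutions, insertions, deletions), to compare wild-type and mutant
    hierarchies, to analyse mutation impact through minimum spanning trees of
    the top-level graph with uniqueness detection and mutation resampling,
    and to export every tier as GraphML for network visualization tools such
    as Cytoscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
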