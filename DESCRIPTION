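Package: mazenet
Title: Network Analysis of Exploratory Trajectories in the Barnes Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent exploratory behaviour in the Barnes
    circular maze from tracked position sequences.  Computes the classical
    performance measures (errors, latency, travel distance, hole occupancy),
    assigns rule-based search-strategy labels (spatial, serial, random),
    detects stop episodes and clusters them into behavioural networks with
    the City Clustering Algorithm, builds fixed-zone planar networks, derives
    eight graph-theoretic features per trial, aggregates per-group global
    networks, and compares groups with a nonparametric test battery.  A
    synthetic-trajectory simulator generates arena trajectories with
    controlled strategy archetypes and stop structure so the whole pipeline
    can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
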