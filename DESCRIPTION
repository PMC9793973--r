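Package: pocketdesign
Title: Binding-Pocket Design by Pairwise Energy Decomposition and GMEC Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational design of small-molecule binding pockets in
    proteins. Given a prepared protein scaffold, a ligand conformer ensemble
    and a set of mutable pocket positions, the package samples side-chain
    rotamers from a backbone-dependent library and ligand poses on a rigid
    rotation/translation grid, decomposes the pocket energetics into self and
    pairwise interaction terms on two tracks (a Lennard-Jones/Coulomb packing
    track and an empirical Vina-style binding track), and finds the global
    minimum energy conformation (GMEC) by integer linear programming, with
    N-best enumeration, ranked design reports, structure output and
    evaluation operators (affinity-pair ranking, pocket and ligand RMSD).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    openssl,
    parallel,
    reticulate,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
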