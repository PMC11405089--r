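Package: moltri
Title: Triangle-Aware Multimodal Molecular Pretraining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining for molecules represented jointly as 2D
    topological graphs and 3D conformations. Implements graph encoders with a
    geometric triangle-awareness edge-update mechanism (multiplicative and
    attention-based edge-to-edge updates with the third edge as a bias),
    SE(3)-invariant 3D encoding over fully connected distance graphs,
    score-based diffusion objectives for cross-modal generation (2D to 3D and
    3D to 2D), node-level noise-contrastive and batch-level InfoNCE objectives,
    and cross-modal edge supervision (distogram prediction from 2D edge
    embeddings, bond-type prediction from 3D pair embeddings). Includes
    molecular file I/O (SDF, SMILES, XYZ), Bemis-Murcko scaffold splitting, a
    deterministic synthetic fixture generator in which bond type statistically
    determines bond length, and downstream finetuning, retrieval and
    fingerprint-similarity utilities, all runnable at desk scale on a single
    CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
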