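Package: gapcanal
Title: Gap Gene Circuit Dynamics and Canalization of the hunchback Border
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the gap gene network of the early
    Drosophila blastoderm reads out the Bicoid morphogen gradient and
    canalizes positional variation of the hunchback expression border.
    Implements the four-gene (hb, Kr, gt, kni) gene-circuit ODE model with
    nuclear divisions, mitotic gating and internuclear diffusion, together
    with its diffusionless per-nucleus reduction; multistart computation of
    equilibria, stability and symbolic 0/X/1 codes; scans of attractor
    existence domains on the Bcd-Cad plane; tracing of one-dimensional
    unstable manifolds of saddles; Monte-Carlo plus bisection estimation of
    attraction basins on the biological initial-condition segment; hb border
    extraction and Bcd response curves; classification of border-formation
    mechanisms, basin transitions and solution classes; and positional
    variance and filtration-rate summaries. Synthetic generators provide
    exponential Bicoid ensembles, maternal Hunchback gradients, Cad and Tll
    input tables, circuit parameter fixtures and analytically solvable toy
    systems for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
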