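Package: fastseqprop
Title: Fast Activation Maximization for Biological Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gradient-based design of discrete DNA, RNA and protein sequences
    by activation maximization against differentiable fitness oracles.
    Implements Fast SeqProp -- trainable logits passed through instance or
    layer normalization with learned scale/offset entropy parameters,
    categorical one-hot sampling, and straight-through gradient estimators --
    together with its predecessors (softmax-relaxed PWM optimization and
    non-normalized stochastic SeqProp), discrete-search baselines (greedy
    substitution search and simulated annealing with the Metropolis
    criterion), and regularized objectives: likelihood-margin penalties,
    probability-of-improvement acquisition, convolutional activity penalties
    and KL-divergence matching of residue distance/angle distributions.
    Ships self-contained toy oracles, FASTA and MEME-format export, a
    JSON-lines trajectory logger and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    Biostrings,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    dplyr
Config/testthat/edition: 3
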