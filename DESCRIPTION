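Package: simplerl
Title: Reward-Driven Text Simplification with Self-Critical Sequence Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paragraph-level medical text simplification driven by
    reinforcement learning. Implements deterministic readability and
    simplification metrics (Flesch-Kincaid Grade Level, Automated Readability
    Index, ROUGE-n, SARI), three simplification rewards (semantic relevance by
    embedding cosine, readability-gap reward, Zipf-frequency lexical-simplicity
    reward), the self-critical sequence training objective that optimizes their
    weighted sum on top of a maximum-likelihood loss, a closed-form toy
    conditional generator for desk-scale experiments, a synthetic paired-corpus
    generator with controllable readability gap and Zipf shift, and JSONL
    corpus input/output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
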