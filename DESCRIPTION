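Package: attapriori
Title: Prior-Guided Attractor Detection in Synchronous Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects point and periodic attractors in synchronous Boolean
    networks by enumerating candidate start states in order of plausibility
    under per-node a priori information (a guess bit and a confidence for
    every node), so that the expected number of simulation trials until a
    target attractor is found grows like f(p)^n with f(p) < 2 for any
    confidence p > 0.5.  Includes the closed-form expected-trial theory
    (exact expectation E(n, p), the exponential base f(alpha*) and its
    comparison against naive 2^n enumeration), a parser and writer for the
    BoolNet-style "targets, factors" network dialect, random N-K network
    generators with AND/OR functional mutants, benchmark harnesses for the
    trial-count, trajectory-length and guided-vs-random search experiments,
    and rules for biological interpretation of attractors (marker-signature
    behavior calls, validity and viability of bipartite-model attractors,
    and deletion-mutant identification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
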