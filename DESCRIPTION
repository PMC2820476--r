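Package: dupdist
Title: Duplication Distances for Segmental Duplication Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact dynamic-programming algorithms for the family of
    duplication distances between a fixed source string and a target
    string: the minimum-cost sequence of duplicate, duplicate-delete,
    duplicate-invert, duplicate-invert-delete, or
    duplicate-with-substring-inversion operations that builds the target
    from an initially empty string by copying substrings of the source.
    Supports signed (oriented) strings, affine operation costs, optimal
    scenario traceback, a brute-force oracle for validation on small
    instances, the equivalent context-free-grammar formulation with
    minimum-production parsing, and seeded generators of synthetic
    strings and scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
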