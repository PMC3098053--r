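Package: ssematch
Title: Fast Protein Structure Pre-Filtering with Reduced Secondary-Structure Vector Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces a protein chain to an ordered set of typed unit vectors,
    one per secondary-structure element (alpha-helix or beta-strand), and
    matches two such representations by minimizing a Gaussian angular match
    score over the rotation group, parameterized by unit quaternions.
    Candidate rotations are ranked by a rotational z-score, turned into an
    order-preserving element correspondence by dynamic programming, and
    scored by the total aligned similarity. Conformationally flexible
    (hinge-motion) relationships are detected as two complementary rotation
    minima. Includes database build/scan tools, a command-line interface,
    and synthetic-structure generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
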