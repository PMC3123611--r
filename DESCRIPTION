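Package: wsdbench
Title: Automatic Construction and Evaluation of Biomedical Word Sense
    Disambiguation Benchmarks from MeSH-Indexed Citations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sense-annotated word sense disambiguation (WSD)
    benchmarks for biomedical text without manual curation. Ambiguous
    terms whose candidate senses are MeSH main headings are mined from
    Metathesaurus-release-style tables (MRCONSO, MRDEF, MRREL, MRSTY),
    per-sense boolean queries are evaluated against MeSH-indexed MEDLINE
    citation corpora, three quality-assurance filters (minimum citation
    counts, cross-validated sense separability, single-letter removal)
    screen the candidates, and the survivors are balanced and serialized
    as ARFF data sets. The package also implements the disambiguation
    methods used to validate such benchmarks - supervised multinomial
    Naive Bayes, concept-profile cosine matching (MRD), second-order
    co-occurrence matching (2-MRD), and automatically extracted training
    corpora via monosemous relatives (AEC) - together with score-sum and
    voting combination, macro and micro accuracy reports, frequency-quartile
    and semantic-group breakdowns, and paired randomization significance
    tests. A seeded synthetic fixture generator emulates the release
    tables and citation corpora with tunable sense separability so the
    entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    digest,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    foreign,
    optparse,
    knitr
Config/testthat/edition: 3
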