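Package: sentrel
Title: Feature-Engineered Sentence Relatedness Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised semantic relatedness scoring for pairs of English
    sentences on the 1-5 scale used in sentence-similarity shared tasks, with
    an application focus on consolidating rhetorically typed statements
    (Population, Intervention, Background, Outcome, Study Design) from
    Evidence Based Medicine abstracts.  A pair of sentences is encoded as a
    34-dimensional vector of syntactic, structural and semantic similarity
    features (bag/set/window overlaps, skipped bigrams, negation polarity,
    clause and reduced-parse-tree structure, taxonomy-based Lin and
    Wu-Palmer similarities, frame overlap, Lesk best-sense features, and
    distributional term-vector features) and scored by an ensemble of three
    regressors: bagged regression trees, a random-subspace instance-based
    regressor, and regression by discretisation over a random-forest
    classifier.  Includes a deterministic offline mini-lexicon emulating the
    three knowledge backends (taxonomy with information content, frame
    lexicon, distributional term vectors), a synthetic pair-corpus
    generator, the full evaluation protocol (Pearson, MSE, error-bin and
    score-range analyses, annotator agreement), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
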