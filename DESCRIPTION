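Package: ncpart
Title: Nest-Centroid Clustering and Recursive Gap-Statistic Partitioning
    for Morphometric Species Delimitation
Version: 0.1.0
Authors@R:
    person("Morphometrics", "Lab", email = "dev@example.org", role = c("aut", "cre"))
Description: Automated species delimitation from continuous morphometric
    trait tables of nest-structured insect samples. Forms prior species
    hypotheses by linear discriminant analysis with nest samples as groups
    (nest-centroid clustering) followed by recursive Gap-statistic
    partitioning with 'hclust' and 'kmeans' base clusterers, confirms the
    hypotheses by leave-one-out cross-validated LDA with wildcard
    assignment of doubtful samples, and extracts diagnostic trait ratios
    and reduced discriminant functions for identification keys. Includes a
    nest-structured synthetic data generator so the full protocol can be
    exercised without measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
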