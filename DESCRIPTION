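Package: snpcluster
Title: Mutation Cluster Detection for SNP Genotyping Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for the existence of mutation clusters
    (kataegis-like spatial aggregation of SNP genotype differences) when
    mutations are observable only at the probe target loci of a genotyping
    array. Provides five neighborhood and gap statistics together with their
    Kolmogorov-Smirnov and Cramer-von Mises functional forms, Monte Carlo
    null inference under a homogeneous Poisson process conditional on the
    probe design, Neyman-Scott cluster-process simulators for power studies,
    probe-design summaries (inter-locus distances, probe deserts, rainfall
    points), and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
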