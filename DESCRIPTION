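Package: HartleyNet
Title: Multi-Organ Gene Regulatory Network Inference from qPCR Time Series
        via Hartley Modulating Functions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Tools for turning high-throughput qPCR time-series data collected
        across multiple organs into data-driven continuous-time gene
        regulatory network models. Provides quality control and
        median-reference -ddCt normalization of Ct matrices, principal
        component staging and per-gene factorial (age x strain, age x sex)
        ANOVA with Tukey HSD post hoc tests, identification of a sparse linear
        ODE interaction matrix by the Hartley Modulating Function method with
        elastic-net regularization and selection by simulation fit, forward
        simulation of the fitted network, peak-expression ordering, and
        network thresholding, comparison and export. A synthetic-data
        generator emulates the factorial study design (strains x ages x
        organs x replicates) from a known sparse stable network so the whole
        pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, tools, Matrix, S4Vectors,
        SummarizedExperiment, glmnet, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, NetworkInference, TimeCourse, qPCR, Normalization
RoxygenNote: 7.3.3
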