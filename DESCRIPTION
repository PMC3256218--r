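Package: tscotu
Title: Two-Stage Clustering of Amplicon Sequences into OTUs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters 16S/18S rRNA amplicon reads into operational
    taxonomic units (OTUs) with a two-stage strategy. Abundant unique tags
    are clustered hierarchically (complete, average or single linkage) on
    sparse pairwise Needleman-Wunsch distances after k-mer prescreening
    and a single-linkage denoising precluster; the rare majority of tags
    is then placed greedily with an alignment-free shortcut, a k-mer
    ordered batched alignment search and a five-case merge rule that lets
    rare tags group low-abundance OTUs but never merge high-abundance
    ones. Includes a mock-community read simulator with known templates
    for accuracy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, Biostrings, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, igraph, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
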