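Package: pericompart
Title: Pericentromeric Recombination Compartments and Gene Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a genome into low-recombining pericentromeric (LR-PC)
    and high-recombining (HR) compartments from a genetic-versus-physical gene
    map, and quantifies the consequences of compartment residency for gene
    evolution: nucleotide diversity (pi, pi_a/pi_s) from cDNA-mapped SNP
    panels, expression level and tissue specificity, retention of
    whole-genome-duplication ohnolog pairs detected by collinearity chaining
    with Nei-Gojobori Ka/Ks, and local (tandem) gene duplication. Includes a
    deterministic synthetic-data generator emulating an inbreeding cereal
    genome so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
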