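Package: haploseer
Title: Deducing Genotypes at Loci of Interest from Phased Haploblock Data via Haplotype Sharing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deduces genotypes at loci of interest (QTLs, Mendelian trait loci,
    SSR fingerprinting loci) from phased, haploblocked SNP-array data of
    pedigree-connected germplasm. Reference-panel locus alleles are associated
    with unique extended haplotype patterns flanking or containing each target
    locus; alleles are then propagated to the wider germplasm through
    identity-by-descent tracing along pedigree links, or through
    identity-by-state matching accepted above a shared-length threshold in
    centimorgans derived from the shortest observed IBD segment. Includes
    readers and writers for haploblock genetic maps, phased haplotypes,
    pedigrees and reference panels; validation of deduced genotypes against
    independently reported genotypes with pedigree-based mismatch triage; and
    a pedigree meiosis simulator (Poisson crossovers, founder-homolog
    bookkeeping) that produces fully ground-truthed synthetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Genetics, SNP, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
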