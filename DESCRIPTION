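Package: lethalscan
Title: Deficit-of-Homozygotes Scan for Embryonic-Lethal Recessive Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recessive embryonic-lethal haplotypes in artificial-
    insemination-structured livestock populations from phased SNP-array
    genotypes, by scanning sliding marker windows for haplotypes whose
    homozygote count falls short of the Mendelian expectation computed from
    sire and maternal-grandsire genotypes and the population haplotype
    frequency. Includes marker quality control (minor-allele-frequency and
    Hardy-Weinberg filters), a conception-rate contrast for matings at risk
    (carrier bull by daughter of carrier sire) against the analytic loss
    under complete lethality, a carrier/control variant filter to nominate
    candidate causative mutations within the detected region, and a pedigree
    gene-drop simulator that generates populations with embedded lethal
    haplotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
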