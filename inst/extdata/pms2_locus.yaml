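# PMS2/PMS2CL locus description for paralog-aware MLPA analysis.
#
# Probe complement of the redesigned PMS2 probemix: 24 gene-specific probes
# (exons 1-15), 5 pseudogene-specific probes (exons 11-15 region), 5
# nonspecific (universal) probes (exons 12-15), plus 11 off-locus reference
# probes used for intra-sample signal scaling.
#
# Published anchors honoured exactly: the first exon-11 gene-specific
# ligation site (c.1360_1361), the intron-12 paralog-discriminating sites
# (c.2174+1097_2174+1099), the intron-10 PSVs c.1145-942, c.1145-921,
# c.1145-886, c.1145-880_1145-879, c.1145-790, the exon-11 frameshift PSVs
# c.1730dupA and c.1863_1864delTA, the exon-14 missense PSV (p.N775S) and
# the 3'UTR PSV c.*92dupA. All other ligation positions, exon boundaries
# and the intron-10 flanking PSVs are SYNTHETIC placeholders chosen to be
# consistent with those anchors.
locus:
  gene: PMS2
  pseudogene: PMS2CL

geometry:
  exon10_span_kb: 2.7
  duplicon_inverted: true
  interduplicon_distance_mb: 0.7

exons:
  - {label: E1,  cds_start: 1,    cds_end: 163}
  - {label: E2,  cds_start: 164,  cds_end: 325}
  - {label: E3,  cds_start: 326,  cds_end: 453}
  - {label: E4,  cds_start: 454,  cds_end: 537}
  - {label: E5,  cds_start: 538,  cds_end: 705}
  - {label: E6,  cds_start: 706,  cds_end: 763}
  - {label: E7,  cds_start: 764,  cds_end: 803}
  - {label: E8,  cds_start: 804,  cds_end: 903}
  - {label: E9,  cds_start: 904,  cds_end: 988}
  - {label: E10, cds_start: 989,  cds_end: 1144}
  - {label: E11, cds_start: 1145, cds_end: 2006}
  - {label: E12, cds_start: 2007, cds_end: 2174}
  - {label: E13, cds_start: 2175, cds_end: 2275}
  - {label: E14, cds_start: 2276, cds_end: 2445}
  - {label: E15, cds_start: 2446, cds_end: 2589}

probe_sites:
  - {id: P_E1,       exon: E1,    specificity: gene,       ligation: c.80_81}
  - {id: P_E2,       exon: E2,    specificity: gene,       ligation: c.240_241}
  - {id: P_E3,       exon: E3,    specificity: gene,       ligation: c.390_391}
  - {id: P_E4,       exon: E4,    specificity: gene,       ligation: c.500_501}
  - {id: P_E5,       exon: E5,    specificity: gene,       ligation: c.620_621}
  - {id: P_E6,       exon: E6,    specificity: gene,       ligation: c.730_731}
  - {id: P_E7,       exon: E7,    specificity: gene,       ligation: c.780_781}
  - {id: P_E8a,      exon: E8,    specificity: gene,       ligation: c.830_831}
  - {id: P_E8b,      exon: E8,    specificity: gene,       ligation: c.880_881}
  - {id: P_E9,       exon: E9,    specificity: gene,       ligation: c.940_941}
  - {id: P_E10a,     exon: E10,   specificity: gene,       ligation: c.1020_1021}
  - {id: P_E10b,     exon: E10,   specificity: gene,       ligation: c.1100_1101}
  - {id: P_E11a,     exon: E11,   specificity: gene,       ligation: c.1360_1361}
  - {id: PP_E11,     exon: E11,   specificity: pseudogene, ligation: c.1700_1701}
  - {id: P_E11b,     exon: E11,   specificity: gene,       ligation: c.1820_1821}
  - {id: P_E12a,     exon: E12,   specificity: gene,       ligation: c.2030_2031}
  - {id: U_E12a,     exon: E12,   specificity: universal,  ligation: c.2060_2061}
  - {id: U_E12b,     exon: E12,   specificity: universal,  ligation: c.2100_2101}
  - {id: P_E12b,     exon: E12,   specificity: gene,       ligation: c.2130_2131}
  - {id: P_IVS12,    exon: IVS12, specificity: gene,       ligation: c.2174+1097_2174+1099}
  - {id: PP_IVS12,   exon: IVS12, specificity: pseudogene, ligation: c.2174+1097_2174+1099}
  - {id: P_E13a,     exon: E13,   specificity: gene,       ligation: c.2200_2201}
  - {id: PP_E13,     exon: E13,   specificity: pseudogene, ligation: c.2220_2221}
  - {id: U_E13,      exon: E13,   specificity: universal,  ligation: c.2240_2241}
  - {id: P_E13b,     exon: E13,   specificity: gene,       ligation: c.2250_2251}
  - {id: P_E14a,     exon: E14,   specificity: gene,       ligation: c.2310_2311}
  - {id: PP_E14,     exon: E14,   specificity: pseudogene, ligation: c.2350_2351}
  - {id: U_E14,      exon: E14,   specificity: universal,  ligation: c.2380_2381}
  - {id: P_E14b,     exon: E14,   specificity: gene,       ligation: c.2400_2401}
  - {id: P_E15a,     exon: E15,   specificity: gene,       ligation: c.2470_2471}
  - {id: PP_E15,     exon: E15,   specificity: pseudogene, ligation: c.2490_2491}
  - {id: P_E15b,     exon: E15,   specificity: gene,       ligation: c.2520_2521}
  - {id: U_E15,      exon: E15,   specificity: universal,  ligation: c.2540_2541}
  - {id: P_E15c,     exon: E15,   specificity: gene,       ligation: c.2560_2561}
  - {id: REF01, exon: REF, specificity: reference}
  - {id: REF02, exon: REF, specificity: reference}
  - {id: REF03, exon: REF, specificity: reference}
  - {id: REF04, exon: REF, specificity: reference}
  - {id: REF05, exon: REF, specificity: reference}
  - {id: REF06, exon: REF, specificity: reference}
  - {id: REF07, exon: REF, specificity: reference}
  - {id: REF08, exon: REF, specificity: reference}
  - {id: REF09, exon: REF, specificity: reference}
  - {id: REF10, exon: REF, specificity: reference}
  - {id: REF11, exon: REF, specificity: reference}

# Paralogous sequence variants. gene_allele / pseudogene_allele are the
# bases carried by PMS2 resp. PMS2CL at the position (PMS2 coordinates).
# The three *_flank_* intron-10 entries are SYNTHETIC context sites; the
# remaining intron-10 sites, the exon-11/14/3'UTR entries and their allele
# identities follow the published catalog.
psv_catalog:
  - {id: PSV_IVS10_1530, position: c.1145-1530, gene_allele: T,  pseudogene_allele: C,  kind: substitution, consequence: intronic, synthetic_flank: true}
  - {id: PSV_IVS10_1231, position: c.1145-1231, gene_allele: G,  pseudogene_allele: A,  kind: substitution, consequence: intronic, synthetic_flank: true}
  - {id: PSV_IVS10_942,  position: c.1145-942,  gene_allele: C,  pseudogene_allele: T,  kind: substitution, consequence: intronic}
  - {id: PSV_IVS10_921,  position: c.1145-921,  gene_allele: G,  pseudogene_allele: A,  kind: substitution, consequence: intronic}
  - {id: PSV_IVS10_886,  position: c.1145-886,  gene_allele: G,  pseudogene_allele: A,  kind: substitution, consequence: intronic}
  - {id: PSV_IVS10_880,  position: c.1145-880_1145-879, gene_allele: GC, pseudogene_allele: G, kind: insertion, consequence: intronic}
  - {id: PSV_IVS10_790,  position: c.1145-790,  gene_allele: C,  pseudogene_allele: A,  kind: substitution, consequence: intronic}
  - {id: PSV_IVS10_408,  position: c.1145-408,  gene_allele: A,  pseudogene_allele: G,  kind: substitution, consequence: intronic, synthetic_flank: true}
  - {id: PSV_E11_1730,   position: c.1730dupA,  gene_allele: A,  pseudogene_allele: AA, kind: duplication, consequence: frameshift}
  - {id: PSV_E11_1732,   position: c.1732C>T,   gene_allele: C,  pseudogene_allele: T,  kind: substitution, consequence: missense}
  - {id: PSV_E11_1863,   position: c.1863_1864delTA, gene_allele: TA, pseudogene_allele: T, kind: deletion, consequence: frameshift}
  - {id: PSV_E12_2050,   position: c.2050G>A,   gene_allele: G,  pseudogene_allele: A,  kind: substitution, consequence: synonymous}
  - {id: PSV_E13_2210,   position: c.2210T>C,   gene_allele: T,  pseudogene_allele: C,  kind: substitution, consequence: synonymous}
  - {id: PSV_E14_2324,   position: c.2324A>G,   gene_allele: A,  pseudogene_allele: G,  kind: substitution, consequence: missense}
  - {id: PSV_E15_UTR92,  position: c.*92dupA,   gene_allele: A,  pseudogene_allele: AA, kind: duplication, consequence: utr}

# Packaged in-silico allele-specific PCR assay for the intron-10 crossover
# hybrid. Primer 3'-end positions are SYNTHETIC placeholders flanking the
# published breakpoint region; product lengths are the published assay
# constants.
assays:
  - id: IVS10_crossover
    forward_pos: c.1145-1000
    forward_origin: gene
    reverse_pos: c.1145-700
    reverse_origin: pseudogene
    product_length_bp: 239
    control_length_bp: 696
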