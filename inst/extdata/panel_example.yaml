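# Example five-SNP risk panel for esophageal cancer.
#
# ORs and genetic models are the validated case-control estimates for the
# five susceptibility loci. Risk-allele frequencies (p) are ILLUSTRATIVE
# East-Asian-range values, not measured reference frequencies: substitute
# population-appropriate frequencies (e.g. CHB) for real analyses.
snps:
  - rsid: rs1042522
    gene: P53
    risk_allele: C
    p: 0.55
    or: 0.69
    model: recessive
  - rsid: rs1229984
    gene: ADH1B
    risk_allele: C
    p: 0.30
    or: 1.78
    model: recessive
  - rsid: rs1801133
    gene: MTHFR
    risk_allele: T
    p: 0.45
    or: 0.41
    model: dominant
  - rsid: rs2274223
    gene: PLCE1
    risk_allele: G
    p: 0.25
    or: 1.93
    model: dominant
  - rsid: rs671
    gene: ALDH2
    risk_allele: A
    p: 0.20
    or: 2.42
    model: dominant
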