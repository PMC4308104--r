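# CYP2D6 panel definition: the seven allele-defining positions assayed by
# allele quantification, the star-allele haplotypes resolvable on that panel,
# and the CPIC activity values used for phenotype translation.
#
# Haplotype contents are restricted to the panel; alleles outside the panel
# are not modelled.  *5 is the whole-gene deletion: it carries no sequence
# and contributes no signal.  *10 cannot be discriminated from *36 on this
# panel (both carry 100C>T only); *10 calls therefore mean "*10 or *36".
panel:
  - snp_id: rs16947
    label: 2850C>T
    ref_base: C
    var_base: T
  - snp_id: rs35742686
    label: 2549delA
    ref_base: A
    var_base: "-"
  - snp_id: rs3892097
    label: 1846G>A
    ref_base: G
    var_base: A
  - snp_id: rs5030655
    label: 1707delT
    ref_base: T
    var_base: "-"
  - snp_id: rs1065852
    label: 100C>T
    ref_base: C
    var_base: T
  - snp_id: rs28371706
    label: 1023C>T
    ref_base: C
    var_base: T
  - snp_id: rs28371725
    label: 2988G>A
    ref_base: G
    var_base: A
alleles:
  - name: "*1"
    variant_snps: []
    activity: 1
  - name: "*2"
    variant_snps: [rs16947]
    activity: 1
  - name: "*3"
    variant_snps: [rs35742686]
    activity: 0
  - name: "*4"
    variant_snps: [rs1065852, rs3892097]
    activity: 0
  - name: "*5"
    variant_snps: []
    activity: 0
    is_deletion: true
  - name: "*6"
    variant_snps: [rs5030655]
    activity: 0
  - name: "*10"
    variant_snps: [rs1065852]
    activity: 0.5
    note: indistinguishable from *36 on this panel
  - name: "*17"
    variant_snps: [rs28371706, rs16947]
    activity: 0.5
  - name: "*41"
    variant_snps: [rs16947, rs28371725]
    activity: 0.5
# Activity-score -> metabolizer phenotype bins: 0 PM; 0.5 IM; [1, 2] EM;
# > 2 UM.  A score of exactly 2 is EM; the UM cut-off is strictly above 2.
phenotype_bins:
  PM: [0, 0]
  IM: [0.5, 0.5]
  EM: [1, 2]
  UM: [2.0001, Inf]
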