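schema_version: '1.0'
tm_window_halfwidth: 1.5
channels:
- ATTO425
- FAM
- HEX
- CFR610
- Cy5
- Quasar705
shared_dye_pairs:
- - KRAS_WT_12_13
  - GNAS_WT
targets:
- genotype: KRAS_WT_12_13
  gene: KRAS
  locus_group: KRAS_12_13
  channel: ATTO425
  is_wt: yes
  tm: 58.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: GNAS_WT
  gene: GNAS
  locus_group: GNAS_201
  channel: ATTO425
  is_wt: yes
  tm: 61.0
  fwhm: 5.288241522117258
  amplicon_length: 96.0
- genotype: KRAS_G12D
  gene: KRAS
  locus_group: KRAS_12_13
  channel: FAM
  is_wt: no
  tm: 52.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G12R
  gene: KRAS
  locus_group: KRAS_12_13
  channel: FAM
  is_wt: no
  tm: 58.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G12V
  gene: KRAS
  locus_group: KRAS_12_13
  channel: FAM
  is_wt: no
  tm: 64.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G12A
  gene: KRAS
  locus_group: KRAS_12_13
  channel: FAM
  is_wt: no
  tm: 70.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G13D
  gene: KRAS
  locus_group: KRAS_12_13
  channel: HEX
  is_wt: no
  tm: 52.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G12S
  gene: KRAS
  locus_group: KRAS_12_13
  channel: HEX
  is_wt: no
  tm: 58.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_G12C
  gene: KRAS
  locus_group: KRAS_12_13
  channel: HEX
  is_wt: no
  tm: 64.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_WT_61
  gene: KRAS
  locus_group: KRAS_61
  channel: CFR610
  is_wt: yes
  tm: 55.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: KRAS_Q61H
  gene: KRAS
  locus_group: KRAS_61
  channel: CFR610
  is_wt: no
  tm: 62.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
- genotype: GNAS_R201H
  gene: GNAS
  locus_group: GNAS_201
  channel: Cy5
  is_wt: no
  tm: 55.0
  fwhm: 5.288241522117258
  amplicon_length: 96.0
- genotype: GNAS_R201C
  gene: GNAS
  locus_group: GNAS_201
  channel: Cy5
  is_wt: no
  tm: 62.0
  fwhm: 5.288241522117258
  amplicon_length: 96.0
- genotype: RPP30_WT
  gene: RPP30
  locus_group: RPP30
  channel: Quasar705
  is_wt: yes
  tm: 58.0
  fwhm: 5.288241522117258
  amplicon_length: 98.0
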