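{
  "template_id": "HsAQP4_syn",
  "note": "Synthetic human-AQP4 surrogate: random scaffold carrying the published annotation anchors at their published coordinates.",
  "version": "1.0",
  "template_peptide": "DAFQSSVFPKMYFSLGADQIEKMENVSDFVTGACHPSDPIKEDTALYGVLLVAAVTGLASFILQLYTVVSTGFGASFYAQISSPMGYRTHFSSILGNPAAVQALKFLAFSLLGPLIGSGLDVYIVKRNALFAVDHLTFIYYGKLEFAHLPTGLEREQVIQLSRAVITLSMWHEAKVISGGFISLFLSNSASTAALTLGAFHLWAGTLLVAVTNPARNSKFVVALTRLAIHRIVRQGGISWSPRINDTTFVMFPVENGFVKSLIFVSLLSKNWDSTSINRTSRTAKPALKLFIRLPGSPII",
  "npa1_pos": 97,
  "npa2_pos": 213,
  "arR_positions": {
    "TMD2_aromatic": 77,
    "TMD5": 201,
    "LE1": 210,
    "LE2": 216
  },
  "trim_range": [31, 258]
}
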