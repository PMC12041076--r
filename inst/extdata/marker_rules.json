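{
  "neuron_exclusion": ["Acta2", "Aldoc", "Aqp4", "Dcn", "Gfap", "Gja1", "Itgam", "Kcnj8", "Laptm5", "Mbp", "Plp1", "S1pr1"],
  "immature_positive": ["Dcx", "Ncam1", "Neurod1"],
  "immature_alt_positive": "Prox1",
  "immature_alt_negative": "Rbfox3",
  "pan_neuronal": ["Map2", "Prox1", "Rbfox3", "Syn1", "Tubb3"],
  "inhibitory_markers": ["Adarb2", "Arhgap36", "Calb1", "Calb2", "Cck", "Chodl", "Chrna2", "Cnmd", "Crh", "Crhr2", "Crispld2", "Gabra1", "Gabra2", "Gad1", "Gad2", "Hpse", "Igfbp4", "Krt73", "Lamp5", "Lhx6", "Lmo1", "Npy", "Nrtn", "Nts", "Plch2", "Pthlh", "Pvalb", "Rspo4", "Sema3e", "Sncg", "Sst", "Tac1", "Tac2", "Tafa1", "Tpbg", "Vip", "Vipr2"],
  "astro_positive": "Aldoc",
  "astro_negative": ["Laptm5", "Acta2", "Kcnj8"],
  "micro_positive": "Laptm5",
  "micro_negative": ["Aldoc", "Acta2", "Kcnj8"],
  "oligo_positive": "Mbp",
  "oligo_negative": ["Acta2", "Aldoc", "Kcnj8", "Laptm5"]
}
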