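name,turnover_median,turnover_factor,ploidy,shed_externally,fraction_median,fraction_factor
erythrocyte_progenitors,2e+11,1.2,2,FALSE,0.085,1.3
granulocytes,6e+10,1.6,2,FALSE,0.32,1.2
gut_epithelium,1e+10,1.4,2,TRUE,,
lymphocytes,1e+10,2,2,FALSE,0.12,1.3
monocytes_macrophages,7e+09,1.8,2,FALSE,0.1,1.3
skin_epidermis,1e+09,1.5,2,TRUE,,
lung_epithelium,5e+08,2,2,TRUE,,
hepatocytes,272500000,1.48,2.3853,FALSE,0.01,1.5
kidney_epithelium,2e+08,2,2,TRUE,,
skeletal_myocytes,2e+08,2.2,2,FALSE,,
endothelial_cells,1e+08,2,2,FALSE,0.044,1.4
breast_epithelium,1e+08,2.5,2,FALSE,,
bladder_epithelium,5e+07,2.2,2,TRUE,,
megakaryocytes,5e+07,1.81,16,FALSE,0.17,1.25
adipocytes,5e+07,2,2,FALSE,,
pancreatic_beta_cells,2e+05,2.5,2,FALSE,,
cardiomyocytes,80000,2.5,4,FALSE,,
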