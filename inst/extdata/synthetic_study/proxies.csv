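locus,sentinel_id,proxy_id,r2,chrom,pos,population,gwas_set
L01,rsS01,rsS01,1,chr2,280,EUR,DEXA
L02,rsS02,rsS02,1,chr2,3619,EUR,Both
L03,rsS03,rsS03,1,chr2,29143,EUR,DEXA
L03,rsS03,rsP03_1,0.87,chr2,29156,EUR,DEXA
decoy_rsDa01,rsDa01,rsDa01,1,chr2,19569,EUR,Heel
decoy_rsDb01,rsDb01,rsDb01,1,chr2,6982,EUR,Heel
decoy_rsDc01,rsDc01,rsDc01,1,chr2,5008,EUR,Heel
decoy_rsDd01,rsDd01,rsDd01,1,chr2,14165,EUR,Heel
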