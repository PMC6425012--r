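[{"locus":"L01","sentinel_id":"rsS01","proxy_id":"rsS01","r2":1,"gene_id":"G0010","symbol":"GENE10","gwas_set":"DEXA"},{"locus":"L02","sentinel_id":"rsS02","proxy_id":"rsS02","r2":1,"gene_id":"G0003","symbol":"GENE3","gwas_set":"Both"},{"locus":"L02","sentinel_id":"rsS02","proxy_id":"rsS02","r2":1,"gene_id":"G0004","symbol":"GENE4","gwas_set":"Both"},{"locus":"L03","sentinel_id":"rsS03","proxy_id":"rsS03","r2":1,"gene_id":"G0018","symbol":"GENE18","gwas_set":"DEXA"},{"locus":"L03","sentinel_id":"rsS03","proxy_id":"rsP03_1","r2":0.87,"gene_id":"G0018","symbol":"GENE18","gwas_set":"DEXA"}]
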