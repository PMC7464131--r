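7e09dcf61a8d587bd74dc2c157abc226  table1_bac_mapping.tsv
323e4fe25ae098feba92ec73575de918  table2_assembly_errors.tsv
8053328dd9259552dadd77390d6199b4  table3_sex_genes.tsv
0c3a74f2d3dc4bce970358d234f318de  table3_gene_orders.tsv
3d3b76906356413a8f68916417a9f8c8  table4_tse_tsc.tsv
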