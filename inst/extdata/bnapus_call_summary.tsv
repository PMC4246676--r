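# Dataset-level statistics of differential transcription calls (padj < 0.01 and
# more than 2-fold change) in the two-accession oilseed rape embryo comparison
# (3170 high lipid vs 3231 high starch), and their stringent aggregation to
# Arabidopsis gene identifiers and to model reactions.
statistic	value
transcripts_annotated	89315
gene_identifiers	19087
transcripts_per_gene	4.7
transcripts_T	2165
transcripts_S	1958
genes_T	1064
genes_T_sum_agrees	847
genes_S	911
genes_S_sum_agrees	717
model_genes_found	860
reactions_T	45
reactions_T_flux_T	23
reactions_S	82
reactions_S_flux_S	4
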