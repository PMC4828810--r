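category	F	M
raw_reads	9336830	14970830
adapter_short_removed	2430265	3237857
clean_reads	6906565	11732973
rrna_removed	2773246	5849934
final_clean_reads	4133319	5883039
unique_reads	1699714	2343563
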