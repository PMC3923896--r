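row	RR	RAD	RNA	Other	Total
total_candidates	73800	54197	156979	4714	286021
low_quality_clusters	9795	8192	21609	219	39429
monomorphic	9010	18157	83368	811	110910
high_quality_polymorphic	54995	27848	52002	3684	135682
mendelian_error	1292	756	1595	66	3649
final_filtered	53703	27092	50407	3618	132033
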