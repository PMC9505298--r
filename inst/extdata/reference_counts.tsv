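source	raw_reads	tailed_reads	mapped_reads	pa_clusters
EST	65423	35853	28931	10245
long_read	7510007630	375500381	10728582	40371
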