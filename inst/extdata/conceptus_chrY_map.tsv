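gene_id	chromosome
DDX3Y	Y
KDM5D	Y
ZFY	Y
EIF2S3Y	Y
EIF1AY	Y
LOC110255320	Y
LOC110257894	Y
LOC396706	Y
LOC100625207	Y
LOC110255257	Y
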