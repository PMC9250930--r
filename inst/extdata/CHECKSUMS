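0e5f7999eee468ce9bbc733527a817bb  nue_snp_proximity.tsv
2e5bac01e94e00c0a3f70b0e5ea0a52e  wheat_nt_grouping.tsv
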